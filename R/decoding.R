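#' Decoding configuration
#'
#' @param strategy `"greedy"`, `"sample"`, or `"beam"`.
#' @param temperature Sampling temperature (> 0).
#' @param beam_size Beam width (default 5; 10 is a documented alternative for
#'   higher-quality search).
#' @param length_penalty Exponent of the length normalization
#'   `score = logprob / n_codons^length_penalty` (default 1.0; 1.2
#'   documented alternative).
#' @param gc_lower,gc_upper Inclusive whole-sequence GC bounds for the
#'   constrained beam search (defaults 0.50 and 0.56, a tolerance band
#'   around the 52% E. coli optimum reflecting natural sequence variability).
#' @param seed Seed for sampling.
#' @export
decoding_config <- function(strategy = c("beam", "greedy", "sample"),
                            temperature = 1, beam_size = 5L,
                            length_penalty = 1.0,
                            gc_lower = 0.50, gc_upper = 0.56, seed = 1L) {
  stopifnot(temperature > 0, beam_size >= 1, gc_lower <= gc_upper)
  structure(list(strategy = match.arg(strategy), temperature = temperature,
                 beam_size = as.integer(beam_size),
                 length_penalty = length_penalty,
                 gc_lower = gc_lower, gc_upper = gc_upper,
                 seed = as.integer(seed)),
            class = "decoding_config")
}

# Per-position decoding tables: codons, GC nucleotide counts, log-probs.
# `fixed` is a named list position -> codon restricting that position.
position_tables <- function(backend, residues, fixed = NULL) {
  probs <- position_probs(backend, residues)
  out <- lapply(seq_along(residues), function(i) {
    p <- probs[[i]]
    info <- backend$fam_info[[residues[i]]]
    keep <- seq_along(info$codons)
    if (!is.null(fixed) && !is.null(fixed[[as.character(i)]])) {
      keep <- match(fixed[[as.character(i)]], info$codons)
      if (is.na(keep)) stop("fixed codon at position ", i,
                            " is not synonymous with residue ", residues[i])
    }
    list(codons = info$codons[keep], gc = info$gc_count[keep],
         logp = unname(log(pmax(p[keep], 1e-300))))
  })
  out
}

#' Greedy (deterministic) decoding
#'
#' Selects the highest-probability codon within each residue's synonymous
#' family; exact probability ties resolve to the lexicographically first
#' codon. No GC constraint is applied.
#'
#' @param protein Amino-acid string (optional trailing `*` decodes a stop
#'   codon).
#' @param backend A [reference_backend()].
#' @param fixed Optional named list position -> codon (e.g. a frozen start).
#' @return DNA string.
#' @export
greedy_decode <- function(protein, backend, fixed = NULL) {
  res <- protein_residues(protein)
  if (length(res) == 0L) return("")
  tabs <- position_tables(backend, res, fixed)
  paste(vapply(tabs, function(t) t$codons[which.max(t$logp)], character(1)),
        collapse = "")
}

#' Temperature sampling decode
#'
#' Per-position sampling from the family distribution with logits divided by
#' the temperature; as the temperature tends to 0 the sample concentrates on
#' the greedy choice. Seeded and reproducible.
#'
#' @inheritParams greedy_decode
#' @param temperature Positive scaling of the logits.
#' @param seed Integer seed.
#' @return DNA string.
#' @export
sample_decode <- function(protein, backend, temperature = 1, seed = 1L,
                          fixed = NULL) {
  stopifnot(temperature > 0)
  res <- protein_residues(protein)
  if (length(res) == 0L) return("")
  tabs <- position_tables(backend, res, fixed)
  set.seed(seed)
  paste(vapply(tabs, function(t) {
    z <- t$logp / temperature
    w <- exp(z - max(z))
    t$codons[sample.int(length(t$codons), 1L, prob = w)]
  }, character(1)), collapse = "")
}

# Comparison key for log-probabilities: quantized so that mathematically
# equal sums accumulated in different orders compare as ties (which then
# resolve lexicographically), keeping beam search and the exhaustive oracle
# bit-consistent.
lp_key <- function(lp) round(lp * 1e9)

infeasibility_report <- function(protein, bounds, achievable, reason) {
  structure(list(protein = protein, gc_lower = bounds[1], gc_upper = bounds[2],
                 achievable_gc = achievable, reason = reason),
            class = "infeasibility_report")
}

#' @export
print.infeasibility_report <- function(x, ...) {
  cat("infeasible: ", x$reason, " (achievable GC [",
      round(x$achievable_gc[1], 4), ", ", round(x$achievable_gc[2], 4),
      "], requested [", x$gc_lower, ", ", x$gc_upper, "])\n", sep = "")
  invisible(x)
}

#' GC-constrained beam search decoding
#'
#' Maintains up to `beam_size` partial sequences, each tracking its
#' cumulative GC nucleotide count. At every expansion the achievable final
#' GC interval (cumulative count plus the sum of per-remaining-residue
#' minimum/maximum family GC counts) is computed exactly, and expansions
#' whose interval cannot intersect the inclusive `[gc_lower, gc_upper]` band
#' are pruned — the exact interval makes pruning sound: no feasible
#' completion is ever discarded. Candidates with equal cumulative GC count
#' are merged keeping the higher-scoring prefix (the suffix search is
#' identical for both, so the lower one is dominated). The final answer is
#' the complete candidate with the highest length-normalized score
#' (`logprob / n^length_penalty`) whose realized GC lies within the bounds;
#' when no synonymous assignment can satisfy the bounds an explicit
#' [infeasibility_report()] is returned instead of a sequence.
#'
#' @inheritParams greedy_decode
#' @param config A [decoding_config()].
#' @return A `beam_result` list (`dna`, `logp`, `score`, `gc`,
#'   `n_expansions`) or an `infeasibility_report`.
#' @export
constrained_beam_search <- function(protein, backend, config = decoding_config(),
                                    fixed = NULL) {
  res <- protein_residues(protein)
  if (length(res) == 0L) stop("empty protein")
  tabs <- position_tables(backend, res, fixed)
  n <- length(tabs)
  nt <- 3L * n
  suff_min <- rev(cumsum(rev(vapply(tabs, function(t) min(t$gc), numeric(1)))))
  suff_max <- rev(cumsum(rev(vapply(tabs, function(t) max(t$gc), numeric(1)))))
  suff_min <- c(suff_min[-1], 0)
  suff_max <- c(suff_max[-1], 0)
  eps <- 1e-9
  lmin <- ceiling(config$gc_lower * nt - eps)
  umax <- floor(config$gc_upper * nt + eps)
  ach <- c(suff_min[1] + min(tabs[[1]]$gc), suff_max[1] + max(tabs[[1]]$gc)) / nt
  if (lmin > umax || ach[1] > config$gc_upper + eps || ach[2] < config$gc_lower - eps) {
    return(infeasibility_report(protein, c(config$gc_lower, config$gc_upper),
                                ach, "achievable GC interval misses the bounds"))
  }

  # beam entries: gc count, logp, DNA prefix (used for lexicographic ties)
  gc_cnt <- 0L
  logp <- 0
  dna <- ""
  n_expansions <- 0L
  for (i in seq_len(n)) {
    t <- tabs[[i]]
    nb <- length(gc_cnt)
    nc <- length(t$codons)
    n_expansions <- n_expansions + nb * nc
    new_gc <- rep(gc_cnt, each = nc) + rep(t$gc, nb)
    new_lp <- rep(logp, each = nc) + rep(t$logp, nb)
    new_dna <- paste0(rep(dna, each = nc), rep(t$codons, nb))
    ok <- (new_gc + suff_max[i] >= lmin) & (new_gc + suff_min[i] <= umax)
    if (!any(ok)) {
      return(infeasibility_report(protein, c(config$gc_lower, config$gc_upper),
                                  ach, "all expansions pruned"))
    }
    new_gc <- new_gc[ok]; new_lp <- new_lp[ok]; new_dna <- new_dna[ok]
    # dominance merge: candidates with equal GC count face identical suffix
    # searches, so only the best (tie: lexicographically first) survives;
    # then truncate to beam_size by prefix log-probability
    ord <- order(new_gc, -lp_key(new_lp), new_dna, method = "radix")
    sel <- ord[!duplicated(new_gc[ord])]
    if (length(sel) > config$beam_size) {
      sel <- sel[order(-lp_key(new_lp[sel]), new_dna[sel],
                       method = "radix")][seq_len(config$beam_size)]
    }
    gc_cnt <- new_gc[sel]
    logp <- new_lp[sel]
    dna <- new_dna[sel]
  }
  final_ok <- gc_cnt >= lmin & gc_cnt <= umax
  if (!any(final_ok)) {
    return(infeasibility_report(protein, c(config$gc_lower, config$gc_upper),
                                ach, "no complete candidate within bounds"))
  }
  score <- logp / (n^config$length_penalty)
  cand <- which(final_ok)
  best <- cand[order(-lp_key(logp[cand]), dna[cand], method = "radix")][1]
  structure(list(dna = dna[best], logp = logp[best], score = score[best],
                 gc = gc_cnt[best] / nt, n_expansions = n_expansions),
            class = "beam_result")
}

#' Exhaustive constrained argmax (test oracle)
#'
#' Enumerates every synonymous codon assignment, filters by the inclusive GC
#' bounds, and returns the maximum-log-probability survivor (ties broken by
#' lexicographic DNA order). Refuses instances whose enumeration exceeds
#' `cap`.
#'
#' @inheritParams greedy_decode
#' @param bounds Numeric length-2 inclusive GC bounds.
#' @param cap Maximum number of assignments to enumerate.
#' @return Same shape as [constrained_beam_search()] results.
#' @export
brute_force_constrained_argmax <- function(protein, backend,
                                           bounds = c(0.50, 0.56),
                                           cap = 1e5, fixed = NULL) {
  res <- protein_residues(protein)
  if (length(res) == 0L) stop("empty protein")
  tabs <- position_tables(backend, res, fixed)
  sizes <- vapply(tabs, function(t) length(t$codons), numeric(1))
  if (prod(sizes) > cap) {
    stop("enumeration size ", prod(sizes), " exceeds cap ", cap)
  }
  grid <- expand.grid(lapply(sizes, seq_len), KEEP.OUT.ATTRS = FALSE)
  nt <- 3L * length(tabs)
  lp <- rowSums(mapply(function(t, col) t$logp[col], tabs, grid))
  gc <- rowSums(mapply(function(t, col) t$gc[col], tabs, grid))
  eps <- 1e-9
  ok <- gc / nt >= bounds[1] - eps & gc / nt <= bounds[2] + eps
  if (!any(ok)) {
    ach <- range(gc) / nt
    return(infeasibility_report(protein, bounds, ach,
                                "no assignment within bounds"))
  }
  dna <- vapply(which(ok), function(rI) {
    paste(mapply(function(t, col) t$codons[col], tabs, grid[rI, ]),
          collapse = "")
  }, character(1))
  sub <- order(-lp_key(lp[ok]), dna, method = "radix")[1]
  best <- which(ok)[sub]
  structure(list(dna = dna[sub], logp = lp[best],
                 score = lp[best] / (length(tabs)^1.0),
                 gc = gc[best] / nt, n_expansions = nrow(grid)),
            class = "beam_result")
}

#' Optimize a coding sequence or protein
#'
#' Orchestrates decoding for one input. A DNA input is validated and
#' translated; its start codon is preserved verbatim at position 1 (start
#' identity governs initiation, not synonymy) and its stop codon is re-chosen
#' among TAA/TAG/TGA by backend score. A protein input is decoded across all
#' residues (with an appended stop when `add_stop`). Metrics are computed for
#' the emitted sequence when references are supplied.
#'
#' @param x DNA CDS or protein string.
#' @param backend A [reference_backend()].
#' @param config A [decoding_config()].
#' @param cai_reference,tai_weights,catalogue Optional metric inputs.
#' @param add_stop Append a stop codon to protein inputs (default TRUE).
#' @return List with `dna` (or `NA` when infeasible), `feasible`, `result`
#'   (decoder output), and `metrics` (one-row data frame).
#' @export
optimize_cds <- function(x, backend, config = decoding_config(),
                         cai_reference = NULL, tai_weights = NULL,
                         catalogue = default_cis_catalogue(),
                         add_stop = TRUE) {
  is_dna <- grepl("^[ACGTacgt]+$", x) && nchar(x) %% 3 == 0 &&
    validate_cds(x)$pass
  fixed <- NULL
  if (is_dna) {
    protein <- translate_cds(x)            # ends in "*"
    fixed <- stats::setNames(list(substr(toupper(x), 1, 3)), "1")
    original <- toupper(x)
  } else {
    protein <- toupper(x)
    if (add_stop && !endsWith(protein, "*")) protein <- paste0(protein, "*")
    original <- NA_character_
  }
  res <- switch(config$strategy,
    greedy = greedy_decode(protein, backend, fixed = fixed),
    sample = sample_decode(protein, backend, temperature = config$temperature,
                           seed = config$seed, fixed = fixed),
    beam = constrained_beam_search(protein, backend, config, fixed = fixed))
  feasible <- !inherits(res, "infeasibility_report")
  dna <- if (!feasible) NA_character_
         else if (is.character(res)) res else res$dna
  gc <- if (feasible) gc_content(dna) else NA_real_
  preserved <- feasible && identical(translate_cds(dna), protein)
  in_bounds <- feasible &&
    (config$strategy != "beam" ||
       (gc >= config$gc_lower - 1e-12 && gc <= config$gc_upper + 1e-12))
  metrics <- data.frame(
    gc = gc,
    cai = if (feasible && !is.null(cai_reference)) cai(dna, cai_reference)
          else NA_real_,
    tai = if (feasible && !is.null(tai_weights)) tai(dna, tai_weights)
          else NA_real_,
    mfe5 = if (feasible) mfe_5prime(dna) else NA_real_,
    delta_mfe5 = if (feasible && !is.na(original))
      delta_mfe_5prime(dna, original) else NA_real_,
    cis_count = if (feasible) count_negative_cis(dna, catalogue) else NA_integer_,
    success = preserved && in_bounds,
    stringsAsFactors = FALSE
  )
  list(dna = dna, feasible = feasible, result = res, metrics = metrics)
}
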