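#' Structural validation of a coding sequence
#'
#' A CDS passes when all of the following hold: the first codon is one of the
#' accepted bacterial starts (ATG, TTG, CTG, GTG), the last codon is a stop
#' (TAA, TAG, TGA), there is no internal stop codon, the length is divisible
#' by 3, and the alphabet is restricted to A/C/G/T (ambiguity codes are
#' rejected, not repaired). Failures are reported as flags, never raised.
#'
#' @param sequence DNA string (case-insensitive).
#' @return List with `pass` (logical) and `flags` (character vector drawn from
#'   `alphabet`, `length_mod3`, `bad_start`, `bad_stop`, `internal_stop`).
#' @examples
#' validate_cds("ATGTGGTAA")$pass          # TRUE
#' validate_cds("ATGTAATGGTAA")$flags      # "internal_stop"
#' @export
validate_cds <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  d <- toupper(sequence)
  flags <- character(0)
  if (grepl("[^ACGT]", d)) flags <- c(flags, "alphabet")
  if (nchar(d) %% 3L != 0L) flags <- c(flags, "length_mod3")
  if (length(flags) == 0L) {
    n <- nchar(d) %/% 3L
    cods <- substring(d, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    stops <- c("TAA", "TAG", "TGA")
    if (!cods[1] %in% c("ATG", "TTG", "CTG", "GTG")) flags <- c(flags, "bad_start")
    if (!cods[n] %in% stops) flags <- c(flags, "bad_stop")
    if (n > 1L && any(cods[-n] %in% stops)) flags <- c(flags, "internal_stop")
  }
  list(pass = length(flags) == 0L, flags = flags)
}

canonical_kmers <- function(seq, k = 8L) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Greedy redundancy reduction by k-mer identity estimate
#'
#' Stand-in for an external nucleotide clusterer: records are sorted longest
#' first; each record joins the first existing cluster whose representative
#' shares enough k-mers, otherwise it founds a new cluster. Identity between
#' a record and a representative is estimated mash-style as `C^(1/k)` where
#' `C` is the fraction of the shorter sequence's distinct k-mers found in the
#' longer one (so 5% point divergence gives `C ~ 0.95^k` and an estimate near
#' 0.95). Deterministic given the length-then-id sort.
#'
#' @param records Data frame with `id` and `sequence` columns.
#' @param identity_threshold Cluster when estimated identity exceeds this
#'   fraction (default 0.9).
#' @param k k-mer size for the identity estimate.
#' @return List with `representatives` (subset of `records`) and `clusters`
#'   (data frame `member_id`, `representative_id`, `est_identity`).
#' @export
reduce_redundancy <- function(records, identity_threshold = 0.9, k = 8L) {
  stopifnot(identity_threshold > 0, identity_threshold < 1, nrow(records) >= 0)
  ord <- order(-nchar(records$sequence), records$id)
  recs <- records[ord, , drop = FALSE]
  reps <- integer(0)                     # row indices into recs
  rep_kmers <- list()
  member_rep <- character(nrow(recs))
  member_ident <- numeric(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    seq_i <- toupper(recs$sequence[i])
    km_i <- canonical_kmers(seq_i, k)
    assigned <- FALSE
    for (j in seq_along(reps)) {
      shared <- sum(km_i %in% rep_kmers[[j]])
      containment <- shared / length(km_i)  # recs[i] is the shorter (or equal)
      est <- containment^(1 / k)
      if (est > identity_threshold) {
        member_rep[i] <- recs$id[reps[j]]
        member_ident[i] <- est
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      rep_kmers[[length(reps)]] <- km_i
      member_rep[i] <- recs$id[i]
      member_ident[i] <- 1
    }
  }
  list(
    representatives = recs[reps, , drop = FALSE],
    clusters = data.frame(member_id = recs$id,
                          representative_id = member_rep,
                          est_identity = member_ident,
                          stringsAsFactors = FALSE)
  )
}

#' Rank validated records by CAI and keep the top n
#'
#' Records are scored with [cai()] against `cai_reference`, sorted by
#' descending CAI with ties broken by id, and the first `top_n` returned.
#' The remainder is attached as the evaluation pool.
#'
#' @param records Data frame with `id`, `sequence`.
#' @param cai_reference A [cai_weights_from_reference()] object.
#' @param top_n Number of records to select.
#' @return List with `selected`, `evaluation_pool` (both data frames carrying
#'   a `cai` column) and `warning` (TRUE when `top_n` exceeded the input).
#' @export
rank_and_select <- function(records, cai_reference, top_n) {
  stopifnot(top_n >= 0)
  records$cai <- vapply(records$sequence, cai, numeric(1),
                        reference = cai_reference, USE.NAMES = FALSE)
  ord <- order(-records$cai, records$id)
  records <- records[ord, , drop = FALSE]
  warn <- top_n > nrow(records)
  if (warn) {
    warning("top_n (", top_n, ") exceeds available records (", nrow(records),
            "); returning all")
  }
  n_sel <- min(top_n, nrow(records))
  list(selected = records[seq_len(n_sel), , drop = FALSE],
       evaluation_pool = records[setdiff(seq_len(nrow(records)), seq_len(n_sel)),
                                 , drop = FALSE],
       warning = warn)
}

#' Seeded train/validation split
#'
#' @param records Data frame with an `id` column.
#' @param val_fraction Fraction assigned to validation, in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `validation` data frames; disjoint, union =
#'   input. The validation size is `round(n * val_fraction)` (ties toward
#'   even, the base-R rounding rule), so a single record with fraction 0.5
#'   lands deterministically in train.
#' @export
split_dataset <- function(records, val_fraction, seed = 1) {
  stopifnot(val_fraction > 0, val_fraction < 1)
  n <- nrow(records)
  n_val <- round(n * val_fraction)
  set.seed(seed)
  val_idx <- sort(sample.int(n, n_val))
  list(train = records[setdiff(seq_len(n), val_idx), , drop = FALSE],
       validation = records[val_idx, , drop = FALSE])
}

#' Run the full curation pipeline
#'
#' Validation, redundancy reduction, optional CAI ranking/selection, with a
#' conserved-count report: at every stage rejected + passed = input.
#'
#' @param records Data frame with `id`, `sequence`.
#' @param identity_threshold Redundancy threshold, see [reduce_redundancy()].
#' @param cai_reference Optional [cai_weights_from_reference()]; when given,
#'   together with `top_n`, the top-CAI subset is selected.
#' @param top_n Optional selection size.
#' @return List with `records` (curated data frame), `report` (a
#'   `curation_report` list: `n_input`, `n_after_dedup`, `n_valid`,
#'   `n_selected`, `rejections` per filter), and `clusters`.
#' @export
curate <- function(records, identity_threshold = 0.9,
                   cai_reference = NULL, top_n = NULL) {
  n_input <- nrow(records)
  red <- reduce_redundancy(records, identity_threshold)
  kept <- red$representatives
  n_after_dedup <- nrow(kept)

  vres <- lapply(kept$sequence, validate_cds)
  pass <- vapply(vres, `[[`, logical(1), "pass")
  rejections <- table(unlist(lapply(vres, `[[`, "flags")))
  valid <- kept[pass, , drop = FALSE]
  n_valid <- nrow(valid)

  if (!is.null(cai_reference) && !is.null(top_n)) {
    sel <- rank_and_select(valid, cai_reference, top_n)
    out <- sel$selected
  } else {
    out <- valid
  }
  report <- structure(list(
    n_input = n_input,
    n_after_dedup = n_after_dedup,
    n_valid = n_valid,
    n_selected = nrow(out),
    rejections = as.list(rejections)
  ), class = "curation_report")
  stopifnot(report$n_selected <= report$n_valid,
            report$n_valid <= report$n_after_dedup,
            report$n_after_dedup <= report$n_input)
  list(records = out, report = report, clusters = red$clusters)
}
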