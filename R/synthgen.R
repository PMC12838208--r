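#' Sample a synthetic codon-usage table
#'
#' Draws one categorical distribution over synonymous codons per amino-acid
#' family. Per-codon log-weights are standard-normal draws scaled by
#' `bias_strength` (0 gives exactly uniform families) plus `gc_shift` times
#' the codon's G+C count, so positive shifts tilt every family toward its
#' high-GC codons. The normal draws depend only on `seed`, so the same seed
#' with a different `gc_shift` retilts the same underlying table — this is
#' what makes [find_gc_shift()] a well-posed 1-D search.
#'
#' @param bias_strength Nonnegative scale of the random family bias.
#' @param gc_shift Log-linear tilt per G/C nucleotide (can be negative).
#' @param seed Integer seed.
#' @param vocab A [build_vocabulary()] object.
#' @return A `usage_table`: list with `probs` (named list, amino-acid letter ->
#'   named probability vector over that family's codons, summing to 1, all
#'   positive), and the generating parameters.
#' @export
sample_usage_table <- function(bias_strength = 1, gc_shift = 0, seed = 1,
                               vocab = build_vocabulary()) {
  stopifnot(bias_strength >= 0)
  fams <- vocab$families[setdiff(names(vocab$families), "*")]
  set.seed(seed)
  z <- lapply(fams, function(toks) stats::rnorm(length(toks)))
  probs <- lapply(names(fams), function(aa) {
    toks <- fams[[aa]]
    gc_cnt <- 3 * vocab$gc_fraction[toks]
    w <- exp(bias_strength * z[[aa]] + gc_shift * gc_cnt)
    stats::setNames(w / sum(w), unname(vocab$codon_of[toks]))
  })
  names(probs) <- names(fams)
  structure(list(probs = probs, bias_strength = bias_strength,
                 gc_shift = gc_shift, seed = seed,
                 label = sprintf("synthetic(bias=%g, gc_shift=%g, seed=%d)",
                                 bias_strength, gc_shift, seed)),
            class = "usage_table")
}

#' Expected body GC fraction of a usage table
#'
#' Closed-form expectation of the per-nucleotide GC fraction of codons drawn
#' from `table` under an amino-acid composition (uniform by default):
#' sum over residues of `f_aa * sum_c p(c) * gc(c) / 3`.
#'
#' @param table A [sample_usage_table()] object.
#' @param aa_freq Optional named amino-acid frequency vector (sums to 1).
#' @return Expected GC fraction in `[0, 1]`.
#' @export
expected_table_gc <- function(table, aa_freq = NULL) {
  aas <- names(table$probs)
  if (is.null(aa_freq)) aa_freq <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  per_aa <- vapply(aas, function(aa) {
    p <- table$probs[[aa]]
    gc <- vapply(strsplit(names(p), ""), function(x) sum(x %in% c("G", "C")), numeric(1))
    sum(p * gc) / 3
  }, numeric(1))
  sum(aa_freq[aas] * per_aa)
}

#' Solve for the gc_shift that reaches a target corpus GC
#'
#' One-dimensional root search on [expected_table_gc()] over `gc_shift`,
#' holding the seed (hence the random family bias) fixed.
#'
#' @param target_gc Target body GC fraction in (0, 1).
#' @param bias_strength,seed Passed to [sample_usage_table()].
#' @param aa_freq Optional amino-acid composition.
#' @return The `gc_shift` whose expected body GC equals `target_gc`.
#' @export
find_gc_shift <- function(target_gc, bias_strength = 1, seed = 1, aa_freq = NULL) {
  stopifnot(target_gc > 0, target_gc < 1)
  f <- function(s) {
    expected_table_gc(sample_usage_table(bias_strength, s, seed), aa_freq) - target_gc
  }
  stats::uniroot(f, lower = -12, upper = 12, tol = 1e-8)$root
}

#' Generator configuration for synthetic coding sequences
#'
#' Start/stop codon frequencies default to the approximate natural E. coli
#' usage (ATG-dominated starts; TAA-dominated stops). Lengths (in codons,
#' including start and stop) are drawn from a geometric distribution shifted
#' to `min_len` with mean `mean_len`, truncated at `max_len`.
#'
#' @param n_genes Number of sequences.
#' @param usage_table A [sample_usage_table()] object.
#' @param min_len,max_len,mean_len Length distribution in codons (`min_len >= 2`).
#' @param start_freq,stop_freq Named frequency vectors over start/stop codons.
#' @param aa_freq Optional amino-acid composition for body residues.
#' @param seed Integer seed.
#' @export
generator_config <- function(n_genes = 100,
                             usage_table = sample_usage_table(),
                             min_len = 30, max_len = 500, mean_len = 150,
                             start_freq = c(ATG = 0.83, GTG = 0.14,
                                            TTG = 0.027, CTG = 0.003),
                             stop_freq = c(TAA = 0.63, TGA = 0.29, TAG = 0.08),
                             aa_freq = NULL,
                             seed = 1) {
  stopifnot(min_len >= 2, min_len <= mean_len, mean_len <= max_len,
            abs(sum(start_freq) - 1) < 1e-6, abs(sum(stop_freq) - 1) < 1e-6)
  structure(list(n_genes = n_genes, usage_table = usage_table,
                 min_len = min_len, max_len = max_len, mean_len = mean_len,
                 start_freq = start_freq, stop_freq = stop_freq,
                 aa_freq = aa_freq, seed = seed),
            class = "generator_config")
}

#' Generate synthetic coding sequences
#'
#' Each record is a sampled start codon, body codons drawn amino acid first
#' (per composition) then codon within the family (per usage table), and one
#' stop codon. Every output passes [validate_cds()] by construction.
#'
#' @param config A [generator_config()].
#' @param vocab A [build_vocabulary()] object.
#' @return A data frame with columns `id`, `sequence`, `length_nt`.
#' @export
generate_cds <- function(config, vocab = build_vocabulary()) {
  stopifnot(inherits(config, "generator_config"))
  aas <- names(config$usage_table$probs)
  aa_freq <- config$aa_freq
  if (is.null(aa_freq)) aa_freq <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  set.seed(config$seed)
  n <- config$n_genes
  if (n == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      length_nt = integer(0), stringsAsFactors = FALSE))
  }
  lens <- pmin(config$min_len +
                 stats::rgeom(n, 1 / (config$mean_len - config$min_len + 1)),
               config$max_len)
  seqs <- vapply(seq_len(n), function(i) {
    L <- lens[i]
    start <- sample(names(config$start_freq), 1, prob = config$start_freq)
    stopc <- sample(names(config$stop_freq), 1, prob = config$stop_freq)
    body_aa <- sample(names(aa_freq), L - 2L, replace = TRUE, prob = aa_freq)
    body <- vapply(body_aa, function(a) {
      p <- config$usage_table$probs[[a]]
      sample(names(p), 1, prob = p)
    }, character(1))
    paste0(start, paste(body, collapse = ""), stopc)
  }, character(1))
  data.frame(id = sprintf("synth_%04d", seq_len(n)), sequence = seqs,
             length_nt = nchar(seqs), stringsAsFactors = FALSE)
}

#' Generate random protein queries
#'
#' Uniform amino-acid composition, uniform lengths in `len_range` (residues).
#' Used to exercise decoding on inputs the backend was not trained on.
#'
#' @param n Number of proteins.
#' @param len_range Length range in residues, inclusive.
#' @param seed Integer seed.
#' @param aa_freq Optional named amino-acid frequency vector.
#' @return Character vector of protein sequences.
#' @export
generate_random_proteins <- function(n, len_range = c(10L, 300L), seed = 1,
                                     aa_freq = NULL) {
  aas <- setdiff(names(build_vocabulary()$families), "*")
  if (is.null(aa_freq)) aa_freq <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  set.seed(seed)
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(names(aa_freq), L, replace = TRUE, prob = aa_freq), collapse = "")
  }, character(1))
}

#' Generate a labeled high/low-expression corpus
#'
#' Merges two generated sets with distinct usage tables. Scoring the merged
#' corpus against CAI weights derived from the high-expression table's output
#' separates the two groups by construction.
#'
#' @param config_high,config_low [generator_config()] objects (typically with
#'   different usage tables and seeds).
#' @return Data frame of both sets with an `expression` label column.
#' @export
generate_expression_split <- function(config_high, config_low) {
  hi <- generate_cds(config_high)
  lo <- generate_cds(config_low)
  if (nrow(hi) > 0) hi$id <- paste0("hi_", hi$id)
  if (nrow(lo) > 0) lo$id <- paste0("lo_", lo$id)
  hi$expression <- rep("high", nrow(hi))
  lo$expression <- rep("low", nrow(lo))
  rbind(hi, lo)
}
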