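# Shared fixtures, all built in code.

VOCAB <- build_vocabulary()

# Random valid CDS built directly from the genetic code (independent of the
# package's generator): start ATG, uniform sense codons, one stop.
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  sense <- setdiff(sort(names(Biostrings::GENETIC_CODE)),
                   c("TAA", "TAG", "TGA"))
  body <- sample(sense, n_codons, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
}

random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(setdiff(names(VOCAB$families), "*"), n, replace = TRUE),
        collapse = "")
}

# Backend with reproducible non-uniform preferences (seeded logit noise), so
# decoding tests exercise non-trivial argmaxes.
noisy_backend <- function(seed, scale = 1, context_width = 0L) {
  b <- reference_backend(VOCAB, context_width = context_width)
  set.seed(seed)
  for (f in names(b$params)) {
    b$params[[f]]$base <- stats::rnorm(length(b$params[[f]]$base), sd = scale)
    if (context_width >= 1L) {
      b$params[[f]]$L[] <- stats::rnorm(length(b$params[[f]]$L), sd = scale / 2)
      b$params[[f]]$R[] <- stats::rnorm(length(b$params[[f]]$R), sd = scale / 2)
    }
  }
  b
}

# Build a full-vocabulary masked batch from per-position family probabilities.
toy_batch_acc <- function(probs, gold, vocab = VOCAB) {
  m <- matrix(0, length(gold), length(vocab$tokens),
              dimnames = list(NULL, vocab$tokens))
  for (i in seq_along(gold)) m[i, names(probs[[i]])] <- probs[[i]]
  list(distributions = m, gold = gold)
}

# Exhaustive enumeration of all nested secondary structures (hairpin loop
# >= 3), as explicit pair sets: independent oracle for the Nussinov fallback
# on short sequences. Returns the maximum pair-set size.
max_pairs_enum <- function(seq, min_loop = 3L) {
  s <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  n <- length(s)
  pairable <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  # enumerate every structure over the index vector `idx` (ordered, nested):
  # the first index is unpaired, or paired with a partner; nesting is kept by
  # splitting into the enclosed and following index sets.
  structures <- function(idx) {
    if (length(idx) == 0L) return(list(integer(0)))
    i <- idx[1]
    out <- lapply(structures(idx[-1]), identity)        # i unpaired
    for (jpos in seq_along(idx)[-1]) {
      j <- idx[jpos]
      if (j - i > min_loop && pairable(s[i], s[j])) {
        inside <- idx[idx > i & idx < j]
        after <- idx[idx > j]
        for (a in structures(inside)) {
          for (bset in structures(after)) {
            out[[length(out) + 1L]] <- c(i, j, a, bset)
          }
        }
      }
    }
    out
  }
  if (n < 2L) return(0L)
  max(vapply(structures(seq_len(n)), function(st) length(st) %/% 2L, integer(1)))
}
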