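codons_of <- function(dna) {
  d <- toupper(dna)
  n <- nchar(d) %/% 3L
  substring(d, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Codon adaptation index weights from a reference gene set
#'
#' Counts codon usage over a reference set of (highly expressed) coding
#' sequences and converts counts to relative adaptiveness: within each
#' synonymous family, `w_c = f_c / max(f)` where zero counts receive a
#' pseudocount of 0.5 before division, so all weights are positive and the
#' most-used codon of every family has weight 1.
#'
#' @param reference_cds Character vector of valid CDS.
#' @param vocab A [build_vocabulary()] object.
#' @return A `cai_reference`: list with `weights` (named numeric over the 61
#'   sense codons, in (0, 1]) and `source_counts`.
#' @export
cai_weights_from_reference <- function(reference_cds, vocab = build_vocabulary()) {
  if (length(reference_cds) == 0L) stop("empty reference set")
  all_cods <- unlist(lapply(reference_cds, codons_of))
  sense <- setdiff(unname(vocab$codon_of), STOP_CODONS)
  counts <- stats::setNames(numeric(length(sense)), sense)
  tab <- table(all_cods[all_cods %in% sense])
  counts[names(tab)] <- as.numeric(tab)
  fams <- vocab$families[setdiff(names(vocab$families), "*")]
  weights <- counts
  for (aa in names(fams)) {
    cods <- unname(vocab$codon_of[fams[[aa]]])
    f <- counts[cods]
    f[f == 0] <- 0.5
    weights[cods] <- f / max(f)
  }
  structure(list(weights = weights, source_counts = counts),
            class = "cai_reference")
}

#' Codon adaptation index
#'
#' Geometric mean of relative-adaptiveness weights over a gene's codons.
#' Following the standard Sharp--Li convention, ATG, TGG (single-codon
#' families) and stop codons are excluded from the product by default; with
#' no eligible codon the value is undefined and returned as `NA`.
#'
#' @param dna Valid CDS.
#' @param reference A [cai_weights_from_reference()] object.
#' @param exclude Codons excluded from the geometric mean (besides stops).
#' @return CAI in (0, 1], or `NA` when no codon is eligible.
#' @export
cai <- function(dna, reference, exclude = c("ATG", "TGG")) {
  cods <- codons_of(dna)
  cods <- cods[!cods %in% c(STOP_CODONS, exclude)]
  if (length(cods) == 0L) return(NA_real_)
  exp(mean(log(reference$weights[cods])))
}

#' tRNA adaptation index
#'
#' Geometric mean of tAI weights over the sense codons of a gene (stop codons
#' excluded). The weights reflect the abundance and wobble-decoding efficiency
#' of the cellular tRNA pool and are supplied as a table (see
#' [tai_weights_from_trna()] for a copy-number-derived table).
#'
#' @param dna Valid CDS.
#' @param weights A `tai_weights` object or named numeric over the 61 sense
#'   codons with values in (0, 1].
#' @return tAI in (0, 1], or `NA` when the gene has no sense codon.
#' @export
tai <- function(dna, weights) {
  w <- if (inherits(weights, "tai_weights")) weights$weights else weights
  cods <- codons_of(dna)
  cods <- cods[!cods %in% STOP_CODONS]
  if (length(cods) == 0L) return(NA_real_)
  exp(mean(log(w[cods])))
}

#' dos-Reis-style tAI weights from tRNA gene copy numbers
#'
#' Computes per-codon absolute adaptiveness within each four-codon box as the
#' copy number of the Watson--Crick-decoding tRNA plus the wobble-decoding
#' tRNA discounted by the standard selective constraints
#' (`s = 0.41` G:U, `0.28` I:C, `0.9999` I:A, `0.68` U:G), then normalizes so
#' the maximum sense-codon weight is 1. Codons with zero absolute weight
#' receive the geometric mean of the nonzero weights.
#'
#' @param copy_numbers Named numeric: codon -> gene copy number of the tRNA
#'   whose anticodon is the reverse complement of that codon (0 when absent).
#' @param s Wobble selective constraints, in the order G:U, I:C, I:A, U:G.
#' @return A `tai_weights` object.
#' @export
tai_weights_from_trna <- function(copy_numbers,
                                  s = c(gu = 0.41, ic = 0.28,
                                        ia = 0.9999, ug = 0.68)) {
  vocab <- build_vocabulary()
  sense <- setdiff(unname(vocab$codon_of), STOP_CODONS)
  tgcn <- stats::setNames(numeric(64), sort(names(Biostrings::GENETIC_CODE)))
  tgcn[names(copy_numbers)] <- copy_numbers
  p <- 1 - s
  boxes <- unique(substring(names(tgcn), 1, 2))
  W <- stats::setNames(numeric(length(tgcn)), names(tgcn))
  for (b in boxes) {
    t_ <- function(n3) tgcn[[paste0(b, n3)]]
    W[paste0(b, "T")] <- t_("T") + p[["gu"]] * t_("C")  # GNN anticodon wobbles NNT
    W[paste0(b, "C")] <- t_("C") + p[["ic"]] * t_("T")  # INN (from ANN) reads NNC
    W[paste0(b, "A")] <- t_("A") + p[["ia"]] * t_("T")  # INN reads NNA
    W[paste0(b, "G")] <- t_("G") + p[["ug"]] * t_("A")  # UNN anticodon wobbles NNG
  }
  W <- W[sense]
  w <- W / max(W)
  if (any(w == 0)) w[w == 0] <- exp(mean(log(w[w > 0])))
  structure(list(weights = w, provenance = "dos-Reis-style from tRNA copy numbers"),
            class = "tai_weights")
}

#' GC content of a nucleotide string
#'
#' @param dna A/C/G/T string (case-insensitive).
#' @return Fraction of G+C in `[0, 1]`; `NA` for the empty string.
#' @export
gc_content <- function(dna) {
  d <- toupper(dna)
  n <- nchar(d)
  if (n == 0L) return(NA_real_)
  (n - nchar(gsub("[GC]", "", d))) / n
}

#' Default catalogue of inhibitory cis elements
#'
#' Two motif classes known to repress expression in E. coli transcripts: the
#' internal Shine--Dalgarno consensus AGGAGG (which can occlude ribosomes when
#' it occurs downstream of the true RBS; counted with overlaps, restricted to
#' positions after codon 1) and premature poly-U tracts (a run of 5 or more
#' T's on the coding strand, counted once per maximal run).
#'
#' @return A `cis_catalogue` data frame with columns `name`, `pattern`,
#'   `scope` (`anywhere` / `internal`), `count_mode` (`overlap` / `run`).
#' @export
default_cis_catalogue <- function() {
  structure(data.frame(
    name = c("internal_SD", "polyU_tract"),
    pattern = c("AGGAGG", "TTTTT"),
    scope = c("internal", "anywhere"),
    count_mode = c("overlap", "run"),
    stringsAsFactors = FALSE
  ), class = c("cis_catalogue", "data.frame"))
}

#' Read a cis-element catalogue from TSV
#'
#' Expected columns: `name`, `pattern`, `scope`, `count_mode` (see
#' [default_cis_catalogue()]).
#' @param path TSV file path.
#' @return A `cis_catalogue` data frame.
#' @export
read_cis_catalogue <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "pattern", "scope", "count_mode") %in% names(df)),
            all(nchar(df$pattern) > 0), all(grepl("^[ACGT]+$", df$pattern)))
  structure(df, class = c("cis_catalogue", "data.frame"))
}

#' Count inhibitory cis-element occurrences in a CDS
#'
#' Overlapping matches are all counted for `overlap`-mode patterns; for
#' `run`-mode patterns (homopolymer tracts) each maximal run at least as long
#' as the pattern counts once. `internal` scope restricts matches to start
#' after the first codon (position >= 4).
#'
#' @param dna Valid CDS.
#' @param catalogue A `cis_catalogue` data frame.
#' @return Nonnegative integer count.
#' @export
count_negative_cis <- function(dna, catalogue = default_cis_catalogue()) {
  if (nrow(catalogue) == 0L) {
    warning("empty cis-element catalogue; count is 0")
    return(0L)
  }
  d <- toupper(dna)
  total <- 0L
  for (r in seq_len(nrow(catalogue))) {
    pat <- catalogue$pattern[r]
    if (catalogue$count_mode[r] == "run") {
      base <- substring(pat, 1, 1)
      rl <- rle(strsplit(d, "")[[1]])
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      hit <- rl$values == base & rl$lengths >= nchar(pat)
      if (catalogue$scope[r] == "internal") hit <- hit & starts >= 4L
      total <- total + sum(hit)
    } else {
      m <- gregexpr(paste0("(?=", pat, ")"), d, perl = TRUE)[[1]]
      pos <- m[m > 0]
      if (catalogue$scope[r] == "internal") pos <- pos[pos >= 4L]
      total <- total + length(pos)
    }
  }
  total
}
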