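#' Minimum free energy of the 5' window of a transcript
#'
#' Scores the folding propensity of the first `window_nt` nucleotides
#' (transcribed to RNA). Two backends:
#'
#' * `"nussinov"` (default, bundled): base-pair maximization by the Nussinov
#'   recursion with minimum hairpin loop length 3 and an energy of -1 per
#'   Watson--Crick or G:U pair. This is a structural proxy, not a
#'   thermodynamic energy; its values are in arbitrary units and are only
#'   comparable within the same backend.
#' * `"vienna"`: calls the external `RNAfold` program for thermodynamic
#'   kcal/mol values; an informative error names the bundled fallback when
#'   the binary is not on the PATH.
#'
#' @param dna A/C/G/T (or RNA) string.
#' @param window_nt 5' window size in nucleotides (default 50); truncated to
#'   the sequence length when shorter.
#' @param backend `"nussinov"` or `"vienna"`.
#' @return Energy score (<= 0): negative pair count (nussinov) or kcal/mol
#'   (vienna).
#' @export
mfe_5prime <- function(dna, window_nt = 50L, backend = c("nussinov", "vienna")) {
  backend <- match.arg(backend)
  stopifnot(nchar(dna) >= 1L)
  win <- substring(toupper(dna), 1L, min(window_nt, nchar(dna)))
  if (backend == "nussinov") {
    return(-nussinov_pairs(win))
  }
  rnafold <- Sys.which("RNAfold")
  if (!nzchar(rnafold)) {
    stop("backend 'vienna' requires the RNAfold binary on the PATH; ",
         "use backend = 'nussinov' for the bundled base-pair-maximization score")
  }
  out <- system2(rnafold, args = c("--noPS"), input = chartr("T", "U", win),
                 stdout = TRUE)
  # last line: "STRUCTURE ( -x.yz )"
  m <- regmatches(out[length(out)],
                  regexpr("\\(\\s*(-?[0-9.]+)\\s*\\)$", out[length(out)]))
  as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
}

# Maximum number of nested base pairs (Watson-Crick + GU), hairpin loop >= 3.
nussinov_pairs <- function(seq, min_loop = 3L) {
  s <- strsplit(toupper(seq), "")[[1]]
  s[s == "U"] <- "T"
  n <- length(s)
  if (n < min_loop + 2L) return(0L)
  can_pair <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  N <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- N[i, j - 1L]                       # j unpaired
      for (k in i:(j - min_loop - 1L)) {         # j paired with k
        if (can_pair(s[k], s[j])) {
          left <- if (k > i) N[i, k - 1L] else 0L
          best <- max(best, left + N[k + 1L, j - 1L] + 1L)
        }
      }
      N[i, j] <- best
    }
  }
  N[1L, n]
}

#' Change in 5' folding energy between an optimized and an original sequence
#'
#' `mfe_5prime(optimized) - mfe_5prime(original)` on a common backend and
#' window, so the original-vs-original value is 0 by construction and
#' `delta(a, b) = -delta(b, a)`.
#'
#' @param optimized,original DNA strings.
#' @inheritParams mfe_5prime
#' @return Signed energy difference.
#' @export
delta_mfe_5prime <- function(optimized, original, window_nt = 50L,
                             backend = c("nussinov", "vienna")) {
  backend <- match.arg(backend)
  mfe_5prime(optimized, window_nt, backend) -
    mfe_5prime(original, window_nt, backend)
}
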