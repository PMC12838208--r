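#' Multi-metric benchmark report with paired tests
#'
#' Computes CAI, tAI, GC content, 5' window MFE, the per-gene change in 5'
#' MFE versus the original, the inhibitory cis-element count, and a success
#' flag for every sequence of every method, then compares each method to the
#' original sequences with paired two-sided t-tests per metric over matched
#' ids, Bonferroni-adjusting p-values across the method comparisons of each
#' metric. Means are reported as mean +/- SD per method. Methods may cover a
#' subset of ids; the per-comparison `n` records the matched count.
#'
#' Degenerate cases are handled explicitly: with fewer than 2 matched pairs
#' the test is omitted with a reason; identical paired values give t = 0,
#' p = 1; a nonzero constant shift with zero variance is reported as
#' undefined (zero variance) rather than an arbitrary statistic.
#'
#' @param per_method_sequences Named list: method -> data frame with `id`,
#'   `sequence`.
#' @param original Data frame with `id`, `sequence` (the unoptimized genes).
#' @param cai_reference A [cai_weights_from_reference()] object.
#' @param tai_weights A `tai_weights` object or named weight vector (optional;
#'   tAI columns are `NA` when absent).
#' @param catalogue Cis-element catalogue (default [default_cis_catalogue()]).
#' @param window_nt 5' MFE window in nucleotides.
#' @param mfe_backend Folding backend passed to [mfe_5prime()].
#' @param gc_bounds Inclusive GC bounds used for the per-sequence success flag
#'   (protein preserved and GC within bounds).
#' @return A `metrics_report`: list with `per_sequence`, `summary`, `tests`
#'   data frames.
#' @export
benchmark_report <- function(per_method_sequences, original,
                             cai_reference, tai_weights = NULL,
                             catalogue = default_cis_catalogue(),
                             window_nt = 50L,
                             mfe_backend = "nussinov",
                             gc_bounds = c(0.50, 0.56)) {
  stopifnot(is.list(per_method_sequences), !is.null(names(per_method_sequences)),
            all(c("id", "sequence") %in% names(original)))
  orig_map <- stats::setNames(original$sequence, original$id)
  orig_prot <- vapply(original$sequence, translate_cds, character(1),
                      USE.NAMES = FALSE)
  names(orig_prot) <- original$id

  score_one <- function(id, seq, method) {
    o <- orig_map[[id]]
    mfe <- mfe_5prime(seq, window_nt, mfe_backend)
    gcv <- gc_content(seq)
    ok <- !is.null(o) &&
      identical(translate_cds(seq), orig_prot[[id]]) &&
      gcv >= gc_bounds[1] - 1e-12 && gcv <= gc_bounds[2] + 1e-12
    data.frame(
      id = id, method = method,
      cai = cai(seq, cai_reference),
      tai = if (is.null(tai_weights)) NA_real_ else tai(seq, tai_weights),
      gc = gcv,
      mfe5 = mfe,
      delta_mfe5 = if (is.null(o)) NA_real_ else
        mfe - mfe_5prime(o, window_nt, mfe_backend),
      cis_count = count_negative_cis(seq, catalogue),
      success = ok,
      stringsAsFactors = FALSE
    )
  }

  rows <- list()
  for (r in seq_len(nrow(original))) {
    rows[[length(rows) + 1L]] <-
      score_one(original$id[r], original$sequence[r], "original")
  }
  for (m in names(per_method_sequences)) {
    df <- per_method_sequences[[m]]
    keep <- df$id %in% original$id
    for (r in which(keep)) {
      rows[[length(rows) + 1L]] <- score_one(df$id[r], df$sequence[r], m)
    }
  }
  per_sequence <- do.call(rbind, rows)

  metrics <- c("cai", "tai", "gc", "mfe5", "delta_mfe5", "cis_count")
  summary_df <- do.call(rbind, lapply(split(per_sequence, per_sequence$method),
    function(d) {
      do.call(rbind, lapply(metrics, function(met) {
        v <- d[[met]]
        data.frame(method = d$method[1], metric = met,
                   mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
                   n = sum(!is.na(v)), stringsAsFactors = FALSE)
      }))
    }))
  rownames(summary_df) <- NULL
  rate <- vapply(split(per_sequence, per_sequence$method),
                 function(d) mean(d$success), numeric(1))
  success_rate <- data.frame(method = names(rate), success_rate = unname(rate),
                             stringsAsFactors = FALSE)

  orig_rows <- per_sequence[per_sequence$method == "original", , drop = FALSE]
  tests <- list()
  for (m in names(per_method_sequences)) {
    mrows <- per_sequence[per_sequence$method == m, , drop = FALSE]
    ids <- intersect(mrows$id, orig_rows$id)
    for (met in metrics) {
      x <- mrows[[met]][match(ids, mrows$id)]
      y <- orig_rows[[met]][match(ids, orig_rows$id)]
      keep <- !is.na(x) & !is.na(y)
      x <- x[keep]; y <- y[keep]
      n <- length(x)
      row <- data.frame(method = m, metric = met, n = n,
                        t = NA_real_, p = NA_real_, p_bonferroni = NA_real_,
                        note = "", stringsAsFactors = FALSE)
      if (n < 2L) {
        row$note <- "omitted: fewer than 2 matched pairs"
      } else {
        d <- x - y
        if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
          if (all(d == 0)) {
            row$t <- 0; row$p <- 1
            row$note <- "identical paired values"
          } else {
            row$note <- "undefined (zero variance)"
          }
        } else {
          tt <- stats::t.test(x, y, paired = TRUE)
          row$t <- unname(tt$statistic)
          row$p <- tt$p.value
        }
      }
      tests[[length(tests) + 1L]] <- row
    }
  }
  tests <- do.call(rbind, tests)
  if (!is.null(tests)) {
    for (met in metrics) {
      idx <- tests$metric == met & !is.na(tests$p)
      tests$p_bonferroni[idx] <- stats::p.adjust(tests$p[idx],
                                                 method = "bonferroni")
    }
  }
  structure(list(per_sequence = per_sequence, summary = summary_df,
                 success_rate = success_rate, tests = tests),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report:", length(unique(x$per_sequence$method)) - 1L,
      "method(s) vs original,", nrow(x$per_sequence), "scored sequences\n")
  print(utils::head(x$summary, 12))
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Per-sequence table as TSV, summary (means, SDs, success rates, paired
#' tests) as JSON.
#'
#' @param report A [benchmark_report()] object.
#' @param tsv_path,json_path Output paths.
#' @export
write_metrics_report <- function(report, tsv_path, json_path) {
  utils::write.table(report$per_sequence, tsv_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(summary = report$summary,
                            success_rate = report$success_rate,
                            tests = report$tests),
                       json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}
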