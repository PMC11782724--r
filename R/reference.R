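#' Published per-scan reference summary
#'
#' Per-scan lung medians and interquartile ranges (functional values and
#' bootstrap errors) from a published 10-scan repeatability study of
#' self-gated functional lung MRI in one healthy volunteer, at the printed
#' table precision, for averaging factors 6, 3 and 1.  Used to verify the
#' package's summary arithmetic (overall medians, precision of the median
#' error) against the published numbers.
#'
#' @return a tibble with columns `n_avg`, `kind`, `scan`, `median_value`,
#'   `iqr_value`, `median_error`, `iqr_error`.
#' @export
reference_scan_summary <- function() {
  path <- system.file("extdata", "reference_scan_summary.csv",
                      package = "lungboot", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

# report granularity per kind and summary row (decimals, half-up)
report_digits <- function(kind, row) {
  if (kind != "perfusion_timing") return(3)
  if (row %in% c("median_over_maps", "median_over_error_maps")) 0 else 2
}

#' Recompute the summary table from per-scan values
#'
#' Given per-scan median/IQR values (10 scans per kind and averaging
#' factor, in the layout of [reference_scan_summary()]), recomputes the
#' study-level summary rows: median over all maps, median over all IQRs,
#' median over all error maps, median over all error IQRs, and the
#' precision of the median error (Tukey-hinge IQR of the per-scan median
#' errors).
#'
#' @param per_scan data frame in the layout of [reference_scan_summary()].
#' @param rounded if `TRUE`, round each summary to the published table
#'   granularity (3 decimals for ventilation and perfusion amplitude;
#'   integer ms for timing medians, 2 decimals for timing IQR rows;
#'   half-up).  Internal computation is always full precision.
#' @return a tibble with one row per (kind, n_avg).
#' @export
recompute_summary_table <- function(per_scan = reference_scan_summary(),
                                    rounded = FALSE) {
  needed <- c("n_avg", "kind", "scan", "median_value", "iqr_value",
              "median_error", "iqr_error")
  if (!all(needed %in% names(per_scan)))
    stop("`per_scan` must have columns: ", paste(needed, collapse = ", "))
  groups <- split(per_scan, list(per_scan$kind, per_scan$n_avg), drop = TRUE)
  rows <- lapply(groups, function(g) {
    if (nrow(g) != 10)
      stop("expected 10 scans per (kind, n_avg); got ", nrow(g))
    out <- tibble::tibble(
      kind = g$kind[1], n_avg = g$n_avg[1],
      median_over_maps = median(g$median_value),
      median_over_iqrs = median(g$iqr_value),
      median_over_error_maps = median(g$median_error),
      median_over_error_iqrs = median(g$iqr_error),
      precision_of_median_error = precision_of_median(g$median_error))
    if (rounded) {
      for (rw in c("median_over_maps", "median_over_iqrs",
                   "median_over_error_maps", "median_over_error_iqrs",
                   "precision_of_median_error")) {
        out[[rw]] <- round_half_up(out[[rw]], report_digits(out$kind, rw))
      }
    }
    out
  })
  res <- do.call(rbind, rows)
  res[order(-res$n_avg, res$kind), ]
}
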