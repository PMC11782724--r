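#' Tukey-hinge quartiles
#'
#' Quartiles as medians of the lower and upper halves of the sorted sample
#' (for odd n the overall median belongs to both halves).  This is the
#' quartile convention whose interquartile range reproduces published
#' precision-of-the-median values recomputed from per-scan medians;
#' linear-interpolation quantile conventions do not.
#'
#' @param x numeric vector (non-finite values dropped).
#' @return named vector `c(q1, q3)`.
#' @examples
#' tukey_hinges(1:10)  # q1 = 3, q3 = 8
#' @export
tukey_hinges <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 1) stop("no finite values")
  if (n == 1) return(c(q1 = x, q3 = x))
  half <- ceiling(n / 2)
  c(q1 = median(x[seq_len(half)]), q3 = median(x[seq.int(n - half + 1, n)]))
}

map_values <- function(map) {
  if (inherits(map, c("param_map", "error_map", "ci_width_map"))) map$values
  else if (is.matrix(map)) map
  else stop("expected a param_map/error_map or a matrix")
}

#' Median and interquartile range over a masked map
#'
#' Standard sample median and Tukey-hinge IQR of the map values inside the
#' mask (non-finite values are dropped, e.g. voxels flagged invalid).
#'
#' @param map a `param_map`, `error_map`, `ci_width_map` or plain matrix.
#' @param mask logical mask of voxels to summarise (nonempty).
#' @return list with elements `median` and `iqr`.
#' @export
masked_median_iqr <- function(map, mask) {
  vals <- map_values(map)
  if (!is.logical(mask) || !identical(dim(mask), dim(vals)))
    stop("`mask` must be a logical mask matching the map shape")
  v <- vals[mask]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("mask selects no finite values")
  h <- tukey_hinges(v)
  list(median = median(v), iqr = unname(h["q3"] - h["q1"]))
}

#' Empirical cumulative distribution of a masked error map
#'
#' @param error_map an `error_map` (or any map/matrix).
#' @param mask logical mask (nonempty).
#' @return a tibble with ascending `value` and `cum_fraction` in (0, 1],
#'   nondecreasing and ending at 1.
#' @export
error_cdf <- function(error_map, mask) {
  vals <- map_values(error_map)
  if (!is.logical(mask) || !identical(dim(mask), dim(vals)))
    stop("`mask` must be a logical mask matching the map shape")
  v <- sort(vals[mask][is.finite(vals[mask])])
  if (length(v) == 0) stop("mask selects no finite values")
  tibble::tibble(value = v, cum_fraction = seq_along(v) / length(v))
}

#' Precision of the median error across repeated scans
#'
#' The Tukey-hinge interquartile range of the per-scan median error values:
#' how tightly the single-scan median errors cluster.
#'
#' @param median_errors numeric vector of per-scan median errors
#'   (length >= 2).
#' @return scalar IQR in the units of the error.
#' @export
precision_of_median <- function(median_errors) {
  if (length(median_errors) < 2) stop("need at least 2 median errors")
  h <- tukey_hinges(median_errors)
  unname(h["q3"] - h["q1"])
}

#' Accuracy of the median error against the gold standard
#'
#' The median, over scans, of `gse_median - boot_median_i`; the sign is
#' retained (positive means the bootstrap underestimates the repeated-scan
#' gold standard).
#'
#' @param gse_median median of the gold-standard error map over the lung.
#' @param boot_medians per-scan median bootstrap errors over the lung
#'   (length >= 1).
#' @return scalar in the units of the error.
#' @export
accuracy_of_median <- function(gse_median, boot_medians) {
  if (length(boot_medians) < 1) stop("need at least 1 bootstrap median")
  median(gse_median - boot_medians)
}
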