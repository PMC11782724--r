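#' Construct a cine series
#'
#' A cine series is a 2D image stack over one physiological cycle: a
#' `rows x cols x n_phases` array of real signal values (arbitrary units)
#' plus cycle metadata.  Phase 0 is expiration (signal maximum) for
#' respiratory series and the reference systole for cardiac series.
#'
#' @param data numeric 3D array, `rows x cols x n_phases`, all finite.
#' @param cycle_kind `"respiratory"` or `"cardiac"`.
#' @param cycle_duration_ms duration of one cycle in milliseconds.
#' @param n_avg averaging factor of the acquisition (noise SD of the series
#'   scales as `1/sqrt(n_avg)`); must be >= 1.
#' @param phase_zero label for the phase-0 convention; defaults per cycle
#'   kind.
#' @param lung_area optional numeric vector, per-phase 2D lung area (voxel
#'   count or mm^2) used by [breathing_depth()].  Phantom series carry it;
#'   for real data supply it from per-phase segmentations.
#' @return an object of class `cine_series`.
#' @examples
#' t <- 0:19
#' arr <- array(rep(2 + cos(2 * pi * t / 20), each = 4), c(2, 2, 20))
#' s <- cine_series(arr, "respiratory", 4000)
#' s
#' @export
cine_series <- function(data, cycle_kind = c("respiratory", "cardiac"),
                        cycle_duration_ms, n_avg = 1L, phase_zero = NULL,
                        lung_area = NULL) {
  cycle_kind <- match.arg(cycle_kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a rows x cols x phases 3D array")
  n_phases <- dim(data)[3]
  if (n_phases < 4L) stop("a cine series needs at least 4 phases")
  if (!all(is.finite(data))) stop("cine data contain non-finite values")
  if (!is.numeric(n_avg) || n_avg < 1) stop("`n_avg` must be >= 1")
  if (!is.numeric(cycle_duration_ms) || cycle_duration_ms <= 0)
    stop("`cycle_duration_ms` must be positive")
  if (!is.null(lung_area) && length(lung_area) != n_phases)
    stop("`lung_area` must have one entry per phase")
  phase_zero <- phase_zero %||%
    switch(cycle_kind, respiratory = "expiration-start",
           cardiac = "reference-systole-start")
  structure(
    list(data = data, cycle_kind = cycle_kind, n_phases = as.integer(n_phases),
         cycle_duration_ms = cycle_duration_ms, n_avg = n_avg,
         phase_zero = phase_zero, lung_area = lung_area),
    class = "cine_series")
}

#' @export
print.cine_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cine_series> %s, %dx%d voxels, %d phases, cycle %.0f ms, n_avg %s\n",
              x$cycle_kind, d[1], d[2], x$n_phases, x$cycle_duration_ms,
              format(x$n_avg)))
  invisible(x)
}

# Cheap content fingerprint tying residuals/fits to their source series.
series_fingerprint <- function(series) {
  d <- series$data
  dm <- dim(d)
  sprintf("%dx%dx%d|%s|%.12e|%.12e|%.12e",
          dm[1], dm[2], dm[3], series$cycle_kind,
          sum(d), sum(d * d), d[[1L]])
}

assert_cine <- function(series) {
  if (!inherits(series, "cine_series")) stop("expected a `cine_series`")
  if (!all(is.finite(series$data))) stop("cine data contain non-finite values")
  invisible(series)
}
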