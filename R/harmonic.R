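#' Voxel-wise first-harmonic fit of a cine series
#'
#' Fits, per voxel, the temporal Fourier model
#' `s(t) = a0 + |c1| * cos(2*pi*t/N + arg(c1))` by the discrete Fourier
#' transform along the phase axis: `a0 = (1/N) * sum_t s(t)` and
#' `c1 = (2/N) * sum_t s(t) * exp(-i*2*pi*t/N)`.  With this normalisation
#' `|c1|` is the physical cosine amplitude.  The DC term carries the static
#' tissue signal; the first harmonic carries the ventilation or perfusion
#' signal; everything above it is treated as residual (noise, artifacts,
#' model inaccuracy).
#'
#' @param series a [cine_series()].
#' @param n_harmonics number of harmonics in the model (default 1; must
#'   satisfy `2 * n_harmonics < n_phases`).  Maps always use the first.
#' @return an object of class `harmonic_fit`: matrices `a0` (real) and `c1`
#'   (complex) with the spatial shape of the series, optional `higher`
#'   harmonics, cycle metadata, and a fingerprint of the source series.
#' @examples
#' t <- 0:19
#' arr <- array(rep(2 + cos(2 * pi * t / 20), each = 1), c(1, 1, 20))
#' f <- fit_first_harmonic(cine_series(arr, "respiratory", 4000))
#' c(f$a0, f$c1)  # 2 and 1+0i
#' @export
fit_first_harmonic <- function(series, n_harmonics = 1) {
  assert_cine(series)
  N <- series$n_phases
  if (n_harmonics < 1 || 2 * n_harmonics >= N)
    stop("`n_harmonics` must be >= 1 and satisfy 2*n_harmonics < n_phases")
  d <- dim(series$data)
  V <- d[1] * d[2]
  X <- matrix(series$data, V, N)
  t <- 0:(N - 1)
  a0 <- rowMeans(X)
  harm <- function(k) {
    th <- 2 * pi * k * t / N
    ((X %*% cos(th)) - 1i * (X %*% sin(th))) * (2 / N)
  }
  c1 <- matrix(as.vector(harm(1)), d[1], d[2])
  higher <- if (n_harmonics > 1) {
    lapply(2:n_harmonics, function(k) matrix(as.vector(harm(k)), d[1], d[2]))
  } else NULL
  structure(
    list(a0 = matrix(a0, d[1], d[2]), c1 = c1, higher = higher,
         n_phases = N, n_harmonics = as.integer(n_harmonics),
         cycle_kind = series$cycle_kind,
         cycle_duration_ms = series$cycle_duration_ms,
         n_avg = series$n_avg, phase_zero = series$phase_zero,
         lung_area = series$lung_area,
         fingerprint = series_fingerprint(series)),
    class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf("<harmonic_fit> %s, %dx%d voxels, %d phases, %d harmonic(s)\n",
              x$cycle_kind, nrow(x$a0), ncol(x$a0), x$n_phases, x$n_harmonics))
  invisible(x)
}

#' Reconstruct the modelled cine series from a fit
#'
#' `model(v, t) = a0(v) + sum_k Re(ck(v) * exp(+i*2*pi*k*t/N))`.  The
#' temporal mean of the model equals `a0` at every voxel.
#'
#' @param fit a [fit_first_harmonic()] object.
#' @return a [cine_series()] holding the model data, with the metadata of
#'   the source series.
#' @export
reconstruct_model <- function(fit) {
  stopifnot(inherits(fit, "harmonic_fit"))
  N <- fit$n_phases
  d <- dim(fit$a0)
  V <- d[1] * d[2]
  t <- 0:(N - 1)
  dat <- matrix(as.vector(fit$a0), V, N)
  comps <- c(list(fit$c1), fit$higher %||% list())
  for (k in seq_along(comps)) {
    ck <- as.vector(comps[[k]])
    for (ti in seq_len(N)) {
      dat[, ti] <- dat[, ti] + Re(ck * exp(2i * pi * k * t[ti] / N))
    }
  }
  cine_series(array(dat, c(d[1], d[2], N)), fit$cycle_kind,
              fit$cycle_duration_ms, n_avg = fit$n_avg,
              phase_zero = fit$phase_zero, lung_area = fit$lung_area)
}

#' Residuals of a cine series with respect to its harmonic model
#'
#' `residual(v, t) = data(v, t) - model(v, t)`.  The residuals carry the
#' temporal-frequency content above the modelled harmonics; by construction
#' their per-voxel phase sum and first-harmonic DFT bin both vanish.  The
#' fit must have been computed from this series (fingerprint check),
#' preventing accidental mixing of model and data from different series.
#'
#' @param series the original [cine_series()].
#' @param fit the [fit_first_harmonic()] of that series.
#' @return an object of class `residual_series` with the residual array and
#'   the source fingerprint.
#' @export
compute_residuals <- function(series, fit) {
  assert_cine(series)
  stopifnot(inherits(fit, "harmonic_fit"))
  if (!identical(fit$fingerprint, series_fingerprint(series)))
    stop("fit does not belong to this series (fingerprint mismatch)")
  model <- reconstruct_model(fit)
  structure(
    list(data = series$data - model$data, n_phases = series$n_phases,
         fingerprint = fit$fingerprint),
    class = "residual_series")
}

#' @export
print.residual_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<residual_series> %dx%d voxels, %d phases, RMS %.4g\n",
              d[1], d[2], d[3], sqrt(mean(x$data^2))))
  invisible(x)
}
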