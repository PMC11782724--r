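#' Bootstrap configuration
#'
#' @param B bootstrap iterations per error map (default 2000).
#' @param R number of error-map recomputations for the reproducibility CI
#'   (default 1000).
#' @param shuffle_mode `"per-voxel"` (default; each voxel's phases get an
#'   independent permutation) or `"shared"` (one permutation applied to all
#'   voxels, preserving spatial noise correlation).
#' @param sampling `"permutation"` (default; shuffling without replacement,
#'   preserving each voxel's residual multiset) or `"with-replacement"`
#'   (classical residual resampling).
#' @param seed master seed; iteration seeds are derived via
#'   [derive_seeds()].
#' @param sd_ddof 0 or 1 (default 1, sample SD) for the per-voxel SD over
#'   the replicate stack.
#' @return an object of class `boot_config`.
#' @export
boot_config <- function(B = 2000, R = 1000,
                        shuffle_mode = c("per-voxel", "shared"),
                        sampling = c("permutation", "with-replacement"),
                        seed = 1L, sd_ddof = 1) {
  shuffle_mode <- match.arg(shuffle_mode)
  sampling <- match.arg(sampling)
  if (B < 2) stop("`B` must be >= 2")
  if (!sd_ddof %in% c(0, 1)) stop("`sd_ddof` must be 0 or 1")
  structure(list(B = as.integer(B), R = as.integer(R),
                 shuffle_mode = shuffle_mode, sampling = sampling,
                 seed = as.integer(seed), sd_ddof = sd_ddof),
            class = "boot_config")
}

#' @export
print.boot_config <- function(x, ...) {
  cat(sprintf("<boot_config> B=%d, R=%d, %s %s, seed %d, sd_ddof %d\n",
              x$B, x$R, x$shuffle_mode, x$sampling, x$seed, x$sd_ddof))
  invisible(x)
}

new_error_map <- function(values, kind, B_used, seed, boot_mean = NULL) {
  structure(list(values = values, kind = kind, B_used = as.integer(B_used),
                 seed = seed, boot_mean = boot_mean,
                 units = unname(map_units[kind])),
            class = "error_map")
}

#' @export
print.error_map <- function(x, ...) {
  cat(sprintf("<error_map> %s (%s), %dx%d, B=%d\n", x$kind, x$units,
              nrow(x$values), ncol(x$values), x$B_used))
  invisible(x)
}

#' Shuffle residuals along the phase axis
#'
#' Step 3 of the bootstrap: randomly permute each voxel's residual values
#' over the reconstructed phases.  In `"per-voxel"` mode every voxel gets
#' its own independent permutation; in `"shared"` mode one permutation is
#' applied to the whole image.  Permutation sampling preserves each voxel's
#' residual multiset (and hence the per-voxel sum, which stays 0).
#'
#' @param res a [compute_residuals()] object.
#' @param seed integer seed.
#' @param mode `"per-voxel"` or `"shared"`.
#' @param sampling `"permutation"` or `"with-replacement"`.
#' @return a new `residual_series` with shuffled phases (same source
#'   fingerprint).
#' @export
shuffle_residuals <- function(res, seed, mode = c("per-voxel", "shared"),
                              sampling = c("permutation", "with-replacement")) {
  stopifnot(inherits(res, "residual_series"))
  mode <- match.arg(mode)
  sampling <- match.arg(sampling)
  d <- dim(res$data)
  V <- d[1] * d[2]; N <- d[3]
  rm_t <- t(matrix(res$data, V, N))            # phases x voxels
  out <- shuffle_phases_cpp(rm_t, mode == "per-voxel",
                            sampling == "with-replacement", as.double(seed))
  structure(list(data = array(t(out), d), n_phases = N,
                 fingerprint = res$fingerprint),
            class = "residual_series")
}

boot_kind_cycle <- c(ventilation = "respiratory",
                     perfusion_amplitude = "cardiac",
                     perfusion_timing = "cardiac")

#' Bootstrap error map of a functional parameter
#'
#' The core routine: fit the first harmonic (step 1), compute residuals
#' (step 2), then `B` times shuffle the residuals, add them to the model
#' and recompute the functional map (steps 3-4); the per-voxel sample SD
#' over the `B` replicate maps is the error map.  Because a permutation
#' preserves the per-voxel mean, the DC term of every synthetic series
#' equals the original `a0` exactly and all variation enters through the
#' first harmonic.
#'
#' The default engine updates the fit coefficients directly from each
#' shuffled draw (the fit is linear, so this is algebraically identical to
#' refitting the synthetic series) and accumulates mean and SD in streaming
#' form (Welford), never storing the stack.  `engine = "reference"`
#' materialises each synthetic series and recomputes the map through
#' [fit_first_harmonic()] and the map functions; both engines use the same
#' draws and agree to float tolerance.
#'
#' @param series a [cine_series()].
#' @param kind `"ventilation"`, `"perfusion_amplitude"` or
#'   `"perfusion_timing"`; must match the series' cycle kind.
#' @param roi aorta ROI mask (required for the perfusion kinds).
#' @param cfg a [boot_config()].
#' @param keep_stack if `TRUE`, also return the full `B x voxels` replicate
#'   stack (for diagnostics and contract tests).
#' @param engine `"fast"` (default) or `"reference"`.
#' @return an `error_map`; its `boot_mean` field holds the per-voxel mean
#'   of the replicate maps, and `$stack` the stack when requested.
#' @export
bootstrap_error_map <- function(series, kind = names(boot_kind_cycle),
                                roi = NULL, cfg = boot_config(),
                                keep_stack = FALSE,
                                engine = c("fast", "reference")) {
  assert_cine(series)
  kind <- match.arg(kind)
  engine <- match.arg(engine)
  stopifnot(inherits(cfg, "boot_config"))
  if (boot_kind_cycle[[kind]] != series$cycle_kind)
    stop(sprintf("map kind '%s' requires a %s series", kind,
                 boot_kind_cycle[[kind]]))
  needs_roi <- kind != "ventilation"
  if (needs_roi) assert_roi(roi, dim(series$data)[1:2])

  fit <- fit_first_harmonic(series)
  res <- compute_residuals(series, fit)
  d <- dim(series$data)
  V <- d[1] * d[2]; N <- d[3]
  a0v <- as.vector(fit$a0)
  c1v <- as.vector(fit$c1)
  roi_idx <- if (needs_roi) which(as.vector(roi)) else NULL
  t_rr <- series$cycle_duration_ms
  seeds <- derive_seeds(cfg$seed, cfg$B)
  per_voxel <- cfg$shuffle_mode == "per-voxel"
  with_repl <- cfg$sampling == "with-replacement"

  mean_acc <- rep(0, V)
  m2_acc <- rep(0, V)
  stack <- if (keep_stack) matrix(NA_real_, cfg$B, V) else NULL

  if (engine == "fast") {
    rm_t <- t(matrix(res$data, V, N))
    th <- 2 * pi * (0:(N - 1)) / N
    wre <- cos(th); wim <- -sin(th)
    for (b in seq_len(cfg$B)) {
      dr <- boot_draw_cpp(rm_t, wre, wim, per_voxel, with_repl,
                          as.double(seeds[b]))
      x <- map_from_coeffs(kind, a0v + dr$meanr, c1v + dr$c1add,
                           roi_idx, t_rr)
      if (keep_stack) stack[b, ] <- x
      delta <- x - mean_acc
      mean_acc <- mean_acc + delta / b
      m2_acc <- m2_acc + delta * (x - mean_acc)
    }
  } else {
    model <- reconstruct_model(fit)
    for (b in seq_len(cfg$B)) {
      shuf <- shuffle_residuals(res, seeds[b], cfg$shuffle_mode, cfg$sampling)
      synth <- cine_series(model$data + shuf$data, series$cycle_kind,
                           series$cycle_duration_ms, n_avg = series$n_avg,
                           phase_zero = series$phase_zero,
                           lung_area = series$lung_area)
      sfit <- fit_first_harmonic(synth)
      pm <- switch(kind,
        ventilation = ventilation_map(sfit),
        perfusion_amplitude = perfusion_amplitude_map(sfit, roi),
        perfusion_timing = perfusion_timing_map(sfit, roi))
      x <- as.vector(pm$values)
      if (keep_stack) stack[b, ] <- x
      delta <- x - mean_acc
      mean_acc <- mean_acc + delta / b
      m2_acc <- m2_acc + delta * (x - mean_acc)
    }
  }

  sdv <- sqrt(pmax(m2_acc, 0) / (cfg$B - cfg$sd_ddof))
  out <- new_error_map(matrix(sdv, d[1], d[2]), kind, cfg$B, cfg$seed,
                       boot_mean = matrix(mean_acc, d[1], d[2]))
  if (keep_stack) out$stack <- stack
  out
}

new_ci_width_map <- function(values, kind, R_used, B_used, seed) {
  structure(list(values = values, kind = kind, R_used = as.integer(R_used),
                 B_used = as.integer(B_used), seed = seed,
                 units = unname(map_units[kind])),
            class = "ci_width_map")
}

#' @export
print.ci_width_map <- function(x, ...) {
  cat(sprintf("<ci_width_map> %s, %dx%d, R=%d, B=%d\n", x$kind,
              nrow(x$values), ncol(x$values), x$R_used, x$B_used))
  invisible(x)
}

#' Reproducibility confidence-interval width of the bootstrap error
#'
#' Recomputes the bootstrap error map `R` times with independent
#' permutation seeds and returns, per voxel, the width of the 95% CI of the
#' error (97.5th minus 2.5th percentile over the `R` error values).  Small
#' widths mean the chosen `B` gives reproducible error estimates; the
#' median width shrinks roughly as `1/sqrt(B)`.
#'
#' @inheritParams bootstrap_error_map
#' @return a `ci_width_map`.
#' @export
error_map_ci <- function(series, kind = names(boot_kind_cycle), roi = NULL,
                         cfg = boot_config()) {
  kind <- match.arg(kind)
  stopifnot(inherits(cfg, "boot_config"))
  if (cfg$R < 2) stop("`R` must be >= 2")
  sub_seeds <- derive_seeds(cfg$seed, cfg$R)
  d <- dim(series$data)
  V <- d[1] * d[2]
  errs <- matrix(NA_real_, cfg$R, V)
  for (r in seq_len(cfg$R)) {
    cfg_r <- cfg
    cfg_r$seed <- sub_seeds[r]
    em <- bootstrap_error_map(series, kind, roi, cfg_r)
    errs[r, ] <- as.vector(em$values)
  }
  width <- apply(errs, 2, function(col) {
    if (anyNA(col)) return(NA_real_)
    q <- quantile(col, c(0.025, 0.975), names = FALSE)
    q[2] - q[1]
  })
  new_ci_width_map(matrix(width, d[1], d[2]), kind, cfg$R, cfg$B, cfg$seed)
}
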