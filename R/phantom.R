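#' Digital lung cine phantom with known ground truth
#'
#' Builds a 2D coronal-slice phantom: two half-elliptical lungs inside a body
#' ellipse, with a small circular aorta ROI between them, plus per-voxel
#' ground-truth fields for the baseline (DC) signal, ventilation, perfusion
#' amplitude and perfusion phase.  The defaults calibrate the lung medians to
#' the magnitudes reported for healthy volunteers in self-gated functional
#' lung MRI (ventilation ~0.22 mL air/mL parenchyma, perfusion amplitude
#' ~0.028 of the blood reference signal).
#'
#' Ground truth is defined so that the map estimators invert it exactly in
#' the noiseless limit: the respiratory cosine modulation for a target
#' ventilation `v` is `m = v / (2 - v)`, and the cardiac modulation for a
#' target amplitude `p` is `p * S_ref / a0`, with `S_ref` the mean aorta
#' baseline.
#'
#' @param grid_shape integer (rows, cols), both >= 32.
#' @param seed integer seed; the phantom is deterministic given the seed.
#' @param vent_median target median ventilation over the lung (mL/mL).
#' @param perf_amp_median target median perfusion amplitude over the lung
#'   (fraction of the blood reference signal).
#' @param vent_scale,perf_scale extra multiplicative scales applied to the
#'   calibrated fields (0 gives an identically zero field).
#' @param baseline_lung,baseline_body,baseline_blood DC signal levels
#'   (arbitrary units) for lung parenchyma, other body tissue and blood.
#' @param noise_sigma SD (same units as the baseline) of one un-averaged
#'   sample; series noise is `noise_sigma / sqrt(n_avg)`.
#' @param cycle_duration_resp_ms,cycle_duration_card_ms cycle durations in
#'   ms (defaults: ~15 breaths/min, ~70 beats/min).
#' @param depth_nominal fractional lung-area change between expiration and
#'   inspiration at `depth_scale = 1` (default 0.243, a typical free-
#'   breathing depth).
#' @param perf_phase_center,perf_phase_spread centre (radians) and spatial
#'   spread of the lung perfusion-phase field; the aorta phase is 0.
#' @return an object of class `lung_phantom` with fields `lung_mask`,
#'   `aorta_roi`, `body_mask`, `baseline_signal`, `vent_true`,
#'   `perf_amp_true`, `perf_phase_true` and the scalar metadata above.
#' @examples
#' ph <- make_phantom(c(32, 32), seed = 1)
#' median(ph$vent_true[ph$lung_mask])
#' @export
make_phantom <- function(grid_shape = c(64, 64), seed = 1L,
                         vent_median = 0.22, perf_amp_median = 0.028,
                         vent_scale = 1, perf_scale = 1,
                         baseline_lung = 40, baseline_body = 100,
                         baseline_blood = 200,
                         noise_sigma = 2.5,
                         cycle_duration_resp_ms = 4000,
                         cycle_duration_card_ms = 857,
                         depth_nominal = 0.243,
                         perf_phase_center = -0.60,
                         perf_phase_spread = 0.5) {
  stopifnot(length(grid_shape) == 2L)
  r <- as.integer(grid_shape[1]); cc <- as.integer(grid_shape[2])
  if (r < 32L || cc < 32L)
    stop("grid too small: the default lung/aorta geometry needs at least 32x32")

  x <- matrix((seq_len(r) - 0.5) / r, r, cc)           # head-foot, 0..1
  y <- matrix(rep((seq_len(cc) - 0.5) / cc, each = r), r, cc)  # left-right

  ell <- function(cx, cy, ax, ay) ((x - cx) / ax)^2 + ((y - cy) / ay)^2 <= 1
  body_mask <- ell(0.52, 0.50, 0.42, 0.45)
  # half-ellipse lungs: elliptical apex, flat diaphragm cut
  lung_mask <- (ell(0.50, 0.30, 0.30, 0.15) | ell(0.50, 0.70, 0.30, 0.15)) &
    x <= 0.72
  rad <- max(2, round(0.035 * min(r, cc)))
  aorta_roi <- ((x - 0.55) * r)^2 + ((y - 0.50) * cc)^2 <= rad^2
  lung_mask <- lung_mask & !aorta_roi
  if (!any(lung_mask)) stop("grid too small: empty lung mask")
  if (!any(aorta_roi)) stop("grid too small: empty aorta ROI")

  with_seed(as.integer(seed), {
    sf_base_body <- smooth_field(r, cc)
    sf_base_lung <- smooth_field(r, cc)
    sf_vent <- smooth_field(r, cc)
    sf_perf <- smooth_field(r, cc)
    sf_phase <- smooth_field(r, cc)
  })

  baseline <- matrix(0, r, cc)
  baseline[body_mask] <- baseline_body * (1 + 0.05 * sf_base_body[body_mask])
  baseline[lung_mask] <- baseline_lung * (1 + 0.08 * sf_base_lung[lung_mask])
  baseline[aorta_roi] <- baseline_blood
  baseline[body_mask] <- pmax(baseline[body_mask], 1)

  vent <- matrix(0, r, cc)
  vraw <- exp(0.35 * sf_vent[lung_mask])
  vent[lung_mask] <- pmin(vent_median * vraw / median(vraw), 0.6) * vent_scale

  perf <- matrix(0, r, cc)
  praw <- exp(0.30 * sf_perf[lung_mask])
  perf[lung_mask] <- pmax(perf_amp_median * praw / median(praw),
                          0.4 * perf_amp_median) * perf_scale
  perf[aorta_roi] <- 0.12 * perf_scale

  phase <- matrix(0, r, cc)
  phase[lung_mask] <- wrap_phase(perf_phase_center +
                                   perf_phase_spread * sf_phase[lung_mask])

  structure(
    list(grid_shape = c(r, cc), lung_mask = lung_mask, aorta_roi = aorta_roi,
         body_mask = body_mask, baseline_signal = baseline,
         vent_true = vent, perf_amp_true = perf, perf_phase_true = phase,
         cycle_duration_resp_ms = cycle_duration_resp_ms,
         cycle_duration_card_ms = cycle_duration_card_ms,
         noise_sigma = noise_sigma, depth_nominal = depth_nominal,
         seed = as.integer(seed)),
    class = "lung_phantom")
}

# Smooth random field: a short random Fourier series over the grid.
# Roughly zero-mean with per-voxel SD ~ 0.7; deterministic given RNG state.
smooth_field <- function(r, cc, n_modes = 6) {
  x <- matrix((seq_len(r) - 0.5) / r, r, cc)
  y <- matrix(rep((seq_len(cc) - 0.5) / cc, each = r), r, cc)
  f <- matrix(0, r, cc)
  for (k in seq_len(n_modes)) {
    fx <- runif(1, 0.5, 2.5); fy <- runif(1, 0.5, 2.5)
    ph <- runif(1, 0, 2 * pi); a <- rnorm(1)
    f <- f + a * sin(2 * pi * (fx * x + fy * y) + ph)
  }
  f / sqrt(n_modes)
}

# wrap into [-pi, pi); the tie at +pi maps to -pi
wrap_phase <- function(x) ((x + pi) %% (2 * pi)) - pi

#' @export
print.lung_phantom <- function(x, ...) {
  cat(sprintf("<lung_phantom> %dx%d, %d lung voxels, %d aorta voxels, seed %d\n",
              x$grid_shape[1], x$grid_shape[2], sum(x$lung_mask),
              sum(x$aorta_roi), x$seed))
  cat(sprintf("  median vent %.3f mL/mL, median perf amp %.4f, noise sigma %.2f\n",
              median(x$vent_true[x$lung_mask]),
              median(x$perf_amp_true[x$lung_mask]), x$noise_sigma))
  invisible(x)
}

#' Simulate a cine series from a phantom
#'
#' Voxel time courses follow `a0 * (1 + m * cos(2*pi*t/N + phi)) + noise`.
#' For respiratory series the modulation is derived from the ground-truth
#' ventilation (`m = v_eff / (2 - v_eff)` with
#' `v_eff = depth_scale * vent_true`), phase 0 is expiration (signal
#' maximum).  For cardiac series the first-harmonic amplitude is
#' `perf_amp_true * S_ref` (with `S_ref` the mean aorta baseline) at phase
#' `perf_phase_true`.  Noise is i.i.d. Gaussian with SD
#' `noise_sigma / sqrt(n_avg)`.
#'
#' Respiratory series carry a per-phase lung-area vector (metadata for
#' [breathing_depth()]): the fractional area change over the cycle equals
#' `depth_scale * depth_nominal`.
#'
#' @param phantom a [make_phantom()] object.
#' @param cycle_kind `"respiratory"` or `"cardiac"`.
#' @param n_phases number of reconstructed phases (default 20).
#' @param n_avg averaging factor (>= 1).
#' @param depth_scale breathing-depth multiplier relative to the phantom's
#'   nominal depth; 1 reproduces `vent_true` exactly.  Ignored (with a
#'   warning) for cardiac series.
#' @param seed integer seed for the noise.
#' @return a [cine_series()].
#' @export
simulate_cine <- function(phantom, cycle_kind = c("respiratory", "cardiac"),
                          n_phases = 20, n_avg = 6, depth_scale = 1,
                          seed = 1L) {
  stopifnot(inherits(phantom, "lung_phantom"))
  cycle_kind <- match.arg(cycle_kind)
  if (n_phases < 4) stop("`n_phases` must be >= 4")
  if (n_avg < 1) stop("`n_avg` must be >= 1")
  if (depth_scale < 0) stop("`depth_scale` must be >= 0")
  r <- phantom$grid_shape[1]; cc <- phantom$grid_shape[2]
  N <- as.integer(n_phases)
  t <- 0:(N - 1)
  omega_t <- 2 * pi * t / N
  a0 <- phantom$baseline_signal
  lung_area <- NULL

  if (cycle_kind == "respiratory") {
    v_eff <- pmin(depth_scale * phantom$vent_true, 0.97)
    m <- v_eff / (2 - v_eff)
    amp <- as.vector(a0 * m)
    phi <- 0
    cyc <- phantom$cycle_duration_resp_ms
    a_exp <- sum(phantom$lung_mask)
    d_frac <- min(depth_scale * phantom$depth_nominal, 0.95)
    lung_area <- a_exp * (1 - d_frac * (1 - cos(omega_t)) / 2)
  } else {
    if (!identical(depth_scale, 1) && depth_scale != 1) {
      warning("`depth_scale` is ignored for cardiac series")
    }
    s_ref <- mean(phantom$baseline_signal[phantom$aorta_roi])
    amp <- as.vector(phantom$perf_amp_true * s_ref)
    phi <- as.vector(phantom$perf_phase_true)
    cyc <- phantom$cycle_duration_card_ms
  }

  V <- r * cc
  dat <- matrix(as.vector(a0), V, N)
  for (ti in seq_len(N)) {
    dat[, ti] <- dat[, ti] + amp * cos(omega_t[ti] + phi)
  }
  if (phantom$noise_sigma > 0) {
    dat <- dat + with_seed(as.integer(seed),
      matrix(rnorm(V * N, 0, phantom$noise_sigma / sqrt(n_avg)), V, N))
  }
  cine_series(array(dat, c(r, cc, N)), cycle_kind, cyc, n_avg = n_avg,
              lung_area = lung_area)
}

#' Simulate a set of repeated scans
#'
#' Emulates a repeatability study: `n_scans` pairs of (respiratory, cardiac)
#' cine series of the same phantom, each with its own noise realisation and
#' its own breathing depth drawn from a Gaussian truncated at 0.  Scans are
#' spatially aligned by construction, so inter-scan registration is a no-op
#' for phantom data.
#'
#' The defaults (`depth_mean = 1`, `depth_sd = 5.6 / 24.3` relative to the
#' phantom's nominal depth) reproduce the free-breathing condition of a
#' measured breathing depth of 24.3% +/- 5.6% across scans.
#'
#' @param phantom a [make_phantom()] object.
#' @param n_scans number of scans (>= 2).
#' @param depth_mean,depth_sd mean and SD of the per-scan `depth_scale`.
#' @param n_avg averaging factor for all series.
#' @param seed master seed; per-scan seeds are derived via [derive_seeds()].
#' @param depths optional explicit `depth_scale` vector (overrides the
#'   random draw; used when reconstructing the same physiological scans at
#'   several averaging levels).
#' @param n_phases phases per cycle.
#' @return an object of class `scan_set`: list with `scans` (each a list
#'   with `resp` and `card` [cine_series()]), `depths_true`, `n_avg`,
#'   `seed`, and the `phantom`.
#' @export
simulate_scan_set <- function(phantom, n_scans = 10, depth_mean = 1,
                              depth_sd = 5.6 / 24.3, n_avg = 6, seed = 1L,
                              depths = NULL, n_phases = 20) {
  stopifnot(inherits(phantom, "lung_phantom"))
  if (n_scans < 2) stop("`n_scans` must be >= 2 (SD over scans undefined)")
  if (depth_sd < 0) stop("`depth_sd` must be >= 0")
  seeds <- derive_seeds(seed, 2L * n_scans + 1L)
  if (is.null(depths)) {
    depths <- with_seed(seeds[1], {
      d <- rnorm(n_scans, depth_mean, depth_sd)
      while (any(d <= 0)) {                      # truncate at 0
        d[d <= 0] <- rnorm(sum(d <= 0), depth_mean, depth_sd)
      }
      d
    })
  } else {
    if (length(depths) != n_scans) stop("`depths` must have length `n_scans`")
  }
  scans <- lapply(seq_len(n_scans), function(i) {
    list(resp = simulate_cine(phantom, "respiratory", n_phases, n_avg,
                              depth_scale = depths[i], seed = seeds[2L * i]),
         card = simulate_cine(phantom, "cardiac", n_phases, n_avg,
                              seed = seeds[2L * i + 1L]))
  })
  structure(list(scans = scans, depths_true = depths, n_avg = n_avg,
                 seed = as.integer(seed), phantom = phantom),
            class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf("<scan_set> %d scans, n_avg %s, depth_scale %.3f +/- %.3f, seed %d\n",
              length(x$scans), format(x$n_avg), mean(x$depths_true),
              sd(x$depths_true), x$seed))
  invisible(x)
}
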