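map_units <- c(ventilation = "mL air/mL lung parenchyma",
               perfusion_amplitude = "dimensionless",
               perfusion_timing = "ms")

new_param_map <- function(values, kind, mask, reference = NULL) {
  structure(list(values = values, kind = kind, mask = mask,
                 reference = reference, units = unname(map_units[kind])),
            class = "param_map")
}

#' @export
print.param_map <- function(x, ...) {
  cat(sprintf("<param_map> %s (%s), %dx%d, %d valid voxels\n",
              x$kind, x$units, nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

assert_roi <- function(roi, dim_ref) {
  if (is.null(roi)) stop("an aorta ROI mask is required for perfusion maps")
  if (!is.logical(roi) || !identical(dim(roi), dim_ref))
    stop("`aorta_roi` must be a logical mask with the map's spatial shape")
  if (!any(roi)) stop("`aorta_roi` is empty")
  invisible(roi)
}

#' Ventilation map from a respiratory first-harmonic fit
#'
#' Under the phase-0-is-expiration convention the signed ventilation signal
#' of a voxel is `v = Re(c1)`, so the modelled signal at expiration is
#' `S_exp = a0 + v` and at inspiration `S_ins = a0 - v`.  The absolute
#' ventilation is `V_abs = (S_exp - S_ins) / S_exp = 2v / (a0 + v)` in
#' mL air / mL lung parenchyma.  Values are not clamped: implausible values
#' are diagnostic and should stay visible.  Voxels with `S_exp <= 0` are
#' flagged invalid in the mask (values set `NA`), not silently zeroed.
#'
#' @param fit a respiratory [fit_first_harmonic()].
#' @param mode `"real"` (default, signed real part) or `"magnitude"`
#'   (`v = |c1|`, for use when the expiration phase alignment is unknown).
#' @return a `param_map` of kind `"ventilation"`.
#' @export
ventilation_map <- function(fit, mode = c("real", "magnitude")) {
  stopifnot(inherits(fit, "harmonic_fit"))
  mode <- match.arg(mode)
  if (fit$cycle_kind != "respiratory")
    stop("ventilation requires a respiratory fit")
  v <- if (mode == "real") Re(fit$c1) else Mod(fit$c1)
  s_exp <- fit$a0 + v
  valid <- is.finite(s_exp) & s_exp > 0
  values <- matrix(NA_real_, nrow(v), ncol(v))
  values[valid] <- 2 * v[valid] / s_exp[valid]
  new_param_map(values, "ventilation", valid, reference = list(mode = mode))
}

# reference DC level of the blood-filled ROI
roi_reference_level <- function(fit, roi, normalization) {
  if (normalization == "dc") mean(fit$a0[roi]) else mean(Mod(fit$c1)[roi])
}

#' Perfusion-amplitude map from a cardiac first-harmonic fit
#'
#' The voxel first-harmonic amplitude `|c1|` normalised to a completely
#' blood-filled reference ROI in the descending aorta, yielding a
#' dimensionless fraction of the full-blood signal.  By default the
#' reference level is the ROI's mean DC signal (`a0`), interpreting the
#' blood-filled ROI as the 100%-blood reference; normalising by the ROI's
#' mean harmonic amplitude is available as an option.
#'
#' @param fit a cardiac [fit_first_harmonic()].
#' @param aorta_roi logical mask of the reference ROI (nonempty).
#' @param normalization `"dc"` (default) or `"harmonic"`.
#' @return a `param_map` of kind `"perfusion_amplitude"`.
#' @export
perfusion_amplitude_map <- function(fit, aorta_roi,
                                    normalization = c("dc", "harmonic")) {
  stopifnot(inherits(fit, "harmonic_fit"))
  normalization <- match.arg(normalization)
  if (fit$cycle_kind != "cardiac")
    stop("perfusion amplitude requires a cardiac fit")
  assert_roi(aorta_roi, dim(fit$a0))
  s_ref <- roi_reference_level(fit, aorta_roi, normalization)
  if (!is.finite(s_ref) || s_ref <= 0)
    stop("reference ROI level is not positive; cannot normalise")
  values <- Mod(fit$c1) / s_ref
  new_param_map(values, "perfusion_amplitude", is.finite(values),
                reference = list(s_ref = s_ref, n_roi = sum(aorta_roi),
                                 normalization = normalization))
}

#' Perfusion-timing map from a cardiac first-harmonic fit
#'
#' The first-harmonic phase of each voxel is compared with the reference
#' phase of the aorta ROI (`phi_ref = arg(sum of c1 over the ROI)`, the
#' argument of the complex mean, which is robust to phase wrapping inside
#' the ROI).  The wrapped difference `wrap(arg c1 - phi_ref)` in
#' `[-pi, pi)` is converted to milliseconds via the cycle duration:
#' `timing = dphi / (2*pi) * T_RR`, so timing lies in `[-T_RR/2, T_RR/2)`.
#' Positive timing means the voxel's first-harmonic peak occurs later in
#' the cycle than the reference.
#'
#' @param fit a cardiac [fit_first_harmonic()] with positive cycle duration.
#' @param aorta_roi logical mask of the reference ROI (nonempty).
#' @return a `param_map` of kind `"perfusion_timing"`.
#' @export
perfusion_timing_map <- function(fit, aorta_roi) {
  stopifnot(inherits(fit, "harmonic_fit"))
  if (fit$cycle_kind != "cardiac")
    stop("perfusion timing requires a cardiac fit")
  t_rr <- fit$cycle_duration_ms
  if (!is.finite(t_rr) || t_rr <= 0) stop("cycle duration must be positive")
  assert_roi(aorta_roi, dim(fit$a0))
  z <- sum(fit$c1[aorta_roi])
  # undefined when the ROI harmonics cancel, or are pure numerical noise
  # relative to the ROI's DC signal level
  if (Mod(z) <= sqrt(.Machine$double.eps) * sum(Mod(fit$c1[aorta_roi])) ||
      Mod(z) / sum(aorta_roi) < 1e-12 * mean(abs(fit$a0[aorta_roi])))
    stop("reference phase undefined: complex mean over the ROI is ~0")
  phi_ref <- Arg(z)
  dphi <- wrap_phase(Arg(fit$c1) - phi_ref)
  values <- dphi / (2 * pi) * t_rr
  new_param_map(values, "perfusion_timing", Mod(fit$c1) > 0,
                reference = list(phase_ref = phi_ref, n_roi = sum(aorta_roi),
                                 t_rr_ms = t_rr))
}

# statistic evaluated on (a0, c1) coefficient vectors; shared by the map
# functions above (via fits) and by the bootstrap engine, which updates the
# coefficients directly instead of refitting each synthetic series.
map_from_coeffs <- function(kind, a0v, c1v, roi_idx = NULL, t_rr = NULL,
                            s_ref_fixed = NULL) {
  switch(kind,
    ventilation = {
      v <- Re(c1v)
      s_exp <- a0v + v
      out <- rep(NA_real_, length(v))
      ok <- is.finite(s_exp) & s_exp > 0
      out[ok] <- 2 * v[ok] / s_exp[ok]
      out
    },
    perfusion_amplitude = {
      s_ref <- s_ref_fixed %||% mean(a0v[roi_idx])
      Mod(c1v) / s_ref
    },
    perfusion_timing = {
      phi_ref <- Arg(sum(c1v[roi_idx]))
      wrap_phase(Arg(c1v) - phi_ref) / (2 * pi) * t_rr
    },
    stop("unknown map kind: ", kind))
}
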