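sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

write_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

#' Write / read a cine series as NIfTI + JSON sidecar
#'
#' The series is stored as one 3D volume (row, column, phase) and a JSON
#' sidecar carrying the cycle metadata (`cycle_kind`, `n_phases`,
#' `cycle_duration_ms`, `n_avg`, `phase_zero`, optional per-phase
#' `lung_area`).
#'
#' @param series a [cine_series()].
#' @param path output `.nii` / `.nii.gz` path; the sidecar gets the same
#'   stem with `.json`.
#' @return `write_cine_nifti` returns `path` invisibly; `read_cine_nifti`
#'   returns a [cine_series()].
#' @export
write_cine_nifti <- function(series, path) {
  assert_cine(series)
  RNifti::writeNifti(series$data, path)
  write_sidecar(list(cycle_kind = series$cycle_kind,
                     n_phases = series$n_phases,
                     cycle_duration_ms = series$cycle_duration_ms,
                     n_avg = series$n_avg, phase_zero = series$phase_zero,
                     lung_area = series$lung_area), path)
  invisible(path)
}

#' @rdname write_cine_nifti
#' @export
read_cine_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  cine_series(array(as.numeric(arr), dim(arr)), meta$cycle_kind,
              meta$cycle_duration_ms, n_avg = meta$n_avg,
              phase_zero = meta$phase_zero,
              lung_area = if (length(meta$lung_area)) meta$lung_area else NULL)
}

#' Write / read a parameter or error map as NIfTI + JSON sidecar
#'
#' @param map a `param_map`, `error_map` or `ci_width_map`.
#' @param path output `.nii` path.
#' @return `write_map_nifti` returns `path` invisibly; `read_map_nifti`
#'   returns the map object.
#' @export
write_map_nifti <- function(map, path) {
  cls <- class(map)[1]
  if (!cls %in% c("param_map", "error_map", "ci_width_map"))
    stop("expected a param_map, error_map or ci_width_map")
  RNifti::writeNifti(map$values, path)
  meta <- list(map_class = cls, kind = map$kind, units = map$units)
  if (cls == "param_map") meta$reference <- map$reference
  if (cls == "error_map") { meta$B_used <- map$B_used; meta$seed <- map$seed }
  if (cls == "ci_width_map") {
    meta$R_used <- map$R_used; meta$B_used <- map$B_used; meta$seed <- map$seed
  }
  write_sidecar(meta, path)
  invisible(path)
}

#' @rdname write_map_nifti
#' @export
read_map_nifti <- function(path) {
  vals <- as.array(RNifti::readNifti(path))
  vals <- matrix(as.numeric(vals), dim(vals)[1], dim(vals)[2])
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  switch(meta$map_class,
    param_map = new_param_map(vals, meta$kind, is.finite(vals),
                              reference = meta$reference),
    error_map = new_error_map(vals, meta$kind, meta$B_used, meta$seed),
    ci_width_map = new_ci_width_map(vals, meta$kind, meta$R_used,
                                    meta$B_used, meta$seed),
    stop("unknown map class in sidecar: ", meta$map_class))
}

#' Write / read phantom masks as a NIfTI label volume
#'
#' Integer labels: 0 background, 1 lung, 2 aorta ROI.
#'
#' @param phantom a [make_phantom()] object (write) .
#' @param path `.nii` path.
#' @return `write_mask_nifti` returns `path` invisibly; `read_mask_nifti`
#'   returns a list with logical `lung_mask` and `aorta_roi`.
#' @export
write_mask_nifti <- function(phantom, path) {
  stopifnot(inherits(phantom, "lung_phantom"))
  lab <- matrix(0L, phantom$grid_shape[1], phantom$grid_shape[2])
  lab[phantom$lung_mask] <- 1L
  lab[phantom$aorta_roi] <- 2L
  RNifti::writeNifti(lab, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  lab <- as.array(RNifti::readNifti(path))
  lab <- matrix(as.integer(lab), dim(lab)[1], dim(lab)[2])
  list(lung_mask = lab == 1L, aorta_roi = lab == 2L)
}

#' Display a map
#'
#' @param x a `param_map`, `error_map` or `ci_width_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.param_map <- function(x, ...) plot_map_impl(x, ...)
#' @rdname plot.param_map
#' @export
plot.error_map <- function(x, ...) plot_map_impl(x, ...)
#' @rdname plot.param_map
#' @export
plot.ci_width_map <- function(x, ...) plot_map_impl(x, ...)

plot_map_impl <- function(x, ...) {
  v <- x$values
  graphics::image(t(v[nrow(v):1, , drop = FALSE]), axes = FALSE, asp = 1,
                  main = sprintf("%s (%s)", x$kind, x$units), ...)
  invisible(x)
}
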