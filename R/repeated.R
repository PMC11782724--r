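#' Breathing depth of a respiratory cine series
#'
#' The relative change in 2D lung area between expiration and inspiration,
#' `100 * (A_max - A_min) / A_max` in percent, with the maximal area
#' (expiration) as denominator.  Per-phase areas come from the series'
#' `lung_area` metadata (phantom series carry the areas implied by their
#' simulated depth) or from the `areas` argument for real data with
#' per-phase segmentations.
#'
#' @param resp_series a respiratory [cine_series()].
#' @param areas optional numeric vector of per-phase lung areas; defaults
#'   to the series' `lung_area` field.
#' @return breathing depth in percent.
#' @export
breathing_depth <- function(resp_series, areas = NULL) {
  stopifnot(inherits(resp_series, "cine_series"))
  areas <- areas %||% resp_series$lung_area
  if (is.null(areas)) stop("no per-phase lung areas available")
  a_max <- max(areas); a_min <- min(areas)
  if (a_max <= 0) stop("maximal lung area must be positive")
  100 * (a_max - a_min) / a_max
}

#' Breathing-depth scan selection
#'
#' Computes mean and SD (sample SD, ddof 1) of per-scan breathing depths
#' and flags scans inside the closed interval `[mean - SD, mean + SD]` as
#' included; scans strictly outside the bounds are excluded from the
#' gold-standard error.
#'
#' @param depths numeric vector of per-scan breathing depths in percent
#'   (length >= 2).
#' @return an object of class `depth_summary`: `depths`, `mean`, `sd`,
#'   `lower_bound`, `upper_bound`, logical `included`.
#' @examples
#' s <- select_scans(c(20, 25, 30, 60))
#' s$included  # the 60% scan is excluded
#' @export
select_scans <- function(depths) {
  if (length(depths) < 2) stop("need at least 2 depths")
  m <- mean(depths); s <- sd(depths)
  lower <- m - s; upper <- m + s
  included <- depths >= lower & depths <= upper
  if (sum(included) < 2)
    warning("fewer than 2 scans included: gold-standard error undefined")
  structure(list(depths = depths, mean = m, sd = s, lower_bound = lower,
                 upper_bound = upper, included = included),
            class = "depth_summary")
}

#' @export
print.depth_summary <- function(x, ...) {
  cat(sprintf("<depth_summary> %d scans, %.1f%% +/- %.1f%%, bounds [%.1f, %.1f], %d included\n",
              length(x$depths), x$mean, x$sd, x$lower_bound, x$upper_bound,
              sum(x$included)))
  invisible(x)
}

#' Gold-standard error from repeated scans
#'
#' The per-voxel sample SD (ddof 1) of a functional parameter across
#' registered repeated scans of the same subject: the repeated-measurement
#' reference against which single-scan bootstrap errors are validated.
#' Maps must share kind and shape and be pre-registered (phantom maps are
#' aligned by construction).
#'
#' @param map_stack list of >= 2 `param_map`s of the same kind.
#' @return an `error_map` with `B_used` set to the number of scans.
#' @export
gold_standard_error <- function(map_stack) {
  if (length(map_stack) < 2) stop("need at least 2 maps")
  if (!all(vapply(map_stack, inherits, logical(1), "param_map")))
    stop("`map_stack` must be a list of param_map objects")
  kinds <- vapply(map_stack, `[[`, character(1), "kind")
  if (length(unique(kinds)) != 1) stop("maps have mixed kinds")
  dims <- vapply(map_stack, function(m) paste(dim(m$values), collapse = "x"),
                 character(1))
  if (length(unique(dims)) != 1) stop("maps have mixed shapes")
  n <- length(map_stack)
  d <- dim(map_stack[[1]]$values)
  M <- vapply(map_stack, function(m) as.vector(m$values),
              numeric(prod(d)))
  mu <- rowMeans(M)
  sdv <- sqrt(rowSums((M - mu)^2) / (n - 1))
  new_error_map(matrix(sdv, d[1], d[2]), kinds[1], B_used = n, seed = NA,
                boot_mean = matrix(mu, d[1], d[2]))
}
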