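#' Configuration for the synthetic validation experiment
#'
#' @param grid_shape phantom grid (rows, cols).
#' @param n_scans number of repeated scans.
#' @param n_avg averaging factors to reconstruct at (default 6, 3, 1, i.e.
#'   full, halved and minimal data).
#' @param depth_mean,depth_sd mean and SD of the per-scan breathing-depth
#'   scale factor (defaults reproduce measured depths of 24.3% +/- 5.6%).
#' @param B bootstrap iterations per error map.
#' @param shuffle_mode,sampling,sd_ddof passed to [boot_config()].
#' @param seed master seed for the whole experiment.
#' @param phantom_args extra arguments for [make_phantom()].
#' @param compute_ci if `TRUE`, also run the reproducibility CI
#'   ([error_map_ci()]) for the first scan at the first averaging level
#'   (ventilation), with `R` recomputations.  Off by default (cost).
#' @param R CI recomputations when `compute_ci` is `TRUE`.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(grid_shape = c(64, 64), n_scans = 10,
                              n_avg = c(6, 3, 1), depth_mean = 1,
                              depth_sd = 5.6 / 24.3, B = 2000,
                              shuffle_mode = "per-voxel",
                              sampling = "permutation", sd_ddof = 1,
                              seed = 1L, phantom_args = list(),
                              compute_ci = FALSE, R = 1000) {
  if (any(n_avg < 1)) stop("`n_avg` values must be >= 1")
  structure(list(grid_shape = grid_shape, n_scans = n_scans, n_avg = n_avg,
                 depth_mean = depth_mean, depth_sd = depth_sd, B = B,
                 shuffle_mode = shuffle_mode, sampling = sampling,
                 sd_ddof = sd_ddof, seed = as.integer(seed),
                 phantom_args = phantom_args, compute_ci = compute_ci,
                 R = R),
            class = "experiment_config")
}

#' Run the synthetic validation experiment
#'
#' The desk-scale replica of a repeatability study: simulate a set of
#' repeated scans of one phantom with variable breathing depth; for every
#' scan and every averaging factor compute the three functional maps and
#' their bootstrap error maps; measure per-scan breathing depths and apply
#' the mean +/- SD exclusion rule; compute the gold-standard error from
#' the included scans; summarise everything as lung medians/IQRs,
#' precision and accuracy of the median error.  Fully deterministic for a
#' fixed master seed.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print one progress line per stage.
#' @return an object of class `lung_experiment`: tibbles `summary`
#'   (per scan, kind, n_avg), `agreement` (per kind, n_avg: GSE median,
#'   median bootstrap-error median, precision, accuracy, `gse_defined`),
#'   the `depth_summary`, the `phantom`, the config echo, and optionally
#'   `ci` (a `ci_width_map`).
#' @export
run_experiment <- function(cfg = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  s <- derive_seeds(cfg$seed, 4)
  phantom <- do.call(make_phantom,
                     c(list(grid_shape = cfg$grid_shape, seed = s[1]),
                       cfg$phantom_args))
  lung <- phantom$lung_mask
  roi <- phantom$aorta_roi
  say("phantom %dx%d, %d lung voxels", cfg$grid_shape[1], cfg$grid_shape[2],
      sum(lung))

  depths <- with_seed(s[2], {
    d <- rnorm(cfg$n_scans, cfg$depth_mean, cfg$depth_sd)
    while (any(d <= 0)) d[d <= 0] <- rnorm(sum(d <= 0), cfg$depth_mean,
                                           cfg$depth_sd)
    d
  })
  level_seeds <- derive_seeds(s[3], length(cfg$n_avg))
  boot_seeds <- derive_seeds(s[4], length(cfg$n_avg) * cfg$n_scans * 3L)

  kinds <- c("ventilation", "perfusion_amplitude", "perfusion_timing")
  summary_rows <- list()
  maps_store <- list()      # maps_store[[level]][[kind]] = list of param_map
  depth_pct <- rep(NA_real_, cfg$n_scans)
  ctr <- 0L

  for (j in seq_along(cfg$n_avg)) {
    a <- cfg$n_avg[j]
    set <- simulate_scan_set(phantom, cfg$n_scans, cfg$depth_mean,
                             cfg$depth_sd, n_avg = a, seed = level_seeds[j],
                             depths = depths)
    say("simulated %d scans at n_avg=%d", cfg$n_scans, a)
    maps_store[[j]] <- lapply(kinds, function(k) vector("list", cfg$n_scans))
    names(maps_store[[j]]) <- kinds
    for (i in seq_len(cfg$n_scans)) {
      sc <- set$scans[[i]]
      if (j == 1L) depth_pct[i] <- breathing_depth(sc$resp)
      rfit <- fit_first_harmonic(sc$resp)
      cfit <- fit_first_harmonic(sc$card)
      pmaps <- list(ventilation = ventilation_map(rfit),
                    perfusion_amplitude = perfusion_amplitude_map(cfit, roi),
                    perfusion_timing = perfusion_timing_map(cfit, roi))
      for (k in kinds) {
        ctr <- ctr + 1L
        series <- if (k == "ventilation") sc$resp else sc$card
        bcfg <- boot_config(B = cfg$B, shuffle_mode = cfg$shuffle_mode,
                            sampling = cfg$sampling, sd_ddof = cfg$sd_ddof,
                            seed = boot_seeds[ctr])
        em <- bootstrap_error_map(series, k,
                                  roi = if (k == "ventilation") NULL else roi,
                                  cfg = bcfg)
        mv <- masked_median_iqr(pmaps[[k]], lung)
        me <- masked_median_iqr(em, lung)
        summary_rows[[length(summary_rows) + 1L]] <- tibble::tibble(
          scan = i, kind = k, n_avg = a,
          median_value = mv$median, iqr_value = mv$iqr,
          median_error = me$median, iqr_error = me$iqr,
          depth_pct = depth_pct[i])
        maps_store[[j]][[k]][[i]] <- pmaps[[k]]
      }
      say("scan %d/%d (n_avg=%d) done", i, cfg$n_scans, a)
    }
  }

  summary <- do.call(rbind, summary_rows)
  dsum <- select_scans(depth_pct)
  summary$included <- dsum$included[summary$scan]

  agreement_rows <- list()
  for (j in seq_along(cfg$n_avg)) {
    for (k in kinds) {
      inc <- which(dsum$included)
      gse_defined <- length(inc) >= 2
      gse_med <- NA_real_
      if (gse_defined) {
        gse <- gold_standard_error(maps_store[[j]][[k]][inc])
        gse_med <- masked_median_iqr(gse, lung)$median
      }
      boot_meds <- summary$median_error[summary$kind == k &
                                          summary$n_avg == cfg$n_avg[j]]
      agreement_rows[[length(agreement_rows) + 1L]] <- tibble::tibble(
        kind = k, n_avg = cfg$n_avg[j], gse_defined = gse_defined,
        gse_median = gse_med,
        boot_median = median(boot_meds),
        precision = precision_of_median(boot_meds),
        accuracy = if (gse_defined) accuracy_of_median(gse_med, boot_meds)
                   else NA_real_)
    }
  }
  agreement <- do.call(rbind, agreement_rows)

  ci <- NULL
  if (isTRUE(cfg$compute_ci)) {
    say("computing reproducibility CI (R=%d, B=%d)", cfg$R, cfg$B)
    set1 <- simulate_scan_set(phantom, cfg$n_scans, cfg$depth_mean,
                              cfg$depth_sd, n_avg = cfg$n_avg[1],
                              seed = level_seeds[1], depths = depths)
    ci <- error_map_ci(set1$scans[[1]]$resp, "ventilation",
                       cfg = boot_config(B = cfg$B, R = cfg$R,
                                         seed = boot_seeds[1]))
  }

  structure(list(summary = summary, agreement = agreement,
                 depth_summary = dsum, phantom = phantom, ci = ci,
                 config = cfg, seed = cfg$seed),
            class = "lung_experiment")
}

#' @export
print.lung_experiment <- function(x, ...) {
  cat(sprintf("<lung_experiment> %d scans x n_avg {%s}, B=%d, seed %d\n",
              x$config$n_scans, paste(x$config$n_avg, collapse = ","),
              x$config$B, x$seed))
  cat(sprintf("  breathing depth %.1f%% +/- %.1f%%, %d scans included\n",
              x$depth_summary$mean, x$depth_summary$sd,
              sum(x$depth_summary$included)))
  print(x$agreement)
  invisible(x)
}
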