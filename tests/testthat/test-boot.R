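test_that("shuffling preserves each voxel's residual multiset and sums", {
  s <- random_series(c(3, 3, 8), seed = 21)
  r <- compute_residuals(s, fit_first_harmonic(s))
  sh <- shuffle_residuals(r, seed = 5)
  for (v in seq_len(9)) {
    i <- ((v - 1) %% 3) + 1; j <- ((v - 1) %/% 3) + 1
    expect_equal(sort(sh$data[i, j, ]), sort(r$data[i, j, ]),
                 tolerance = 1e-15)
    expect_lt(abs(sum(sh$data[i, j, ])), 1e-9)
  }
  expect_identical(sh$data, shuffle_residuals(r, seed = 5)$data)
  expect_false(identical(sh$data, shuffle_residuals(r, seed = 6)$data))
  # shared mode applies one permutation to every voxel
  shs <- shuffle_residuals(r, seed = 7, mode = "shared")
  perm_of <- function(i, j) match(shs$data[i, j, ], r$data[i, j, ])
  p11 <- perm_of(1, 1)
  for (v in 2:9) {
    i <- ((v - 1) %% 3) + 1; j <- ((v - 1) %/% 3) + 1
    expect_identical(perm_of(i, j), p11)
  }
})

test_that("zero residuals give identically zero error and CI maps", {
  t <- 0:19
  a0 <- matrix(5, 2, 2); amp <- matrix(0.5, 2, 2); ph <- matrix(0, 2, 2)
  s <- coeff_series(a0, amp, ph, n = 20, cycle = "respiratory", t_ms = 4000)
  em <- bootstrap_error_map(s, "ventilation", cfg = boot_config(B = 25, seed = 1))
  expect_lt(max(em$values), 1e-12)
  ci <- error_map_ci(s, "ventilation",
                     cfg = boot_config(B = 10, R = 5, seed = 1))
  expect_lt(max(ci$values), 1e-12)
})

test_that("permutation bootstrap conserves the DC term exactly", {
  s <- random_series(c(3, 3, 10), seed = 31)
  f <- fit_first_harmonic(s)
  r <- compute_residuals(s, f)
  m <- reconstruct_model(f)
  sh <- shuffle_residuals(r, seed = 3)
  synth <- cine_series(m$data + sh$data, s$cycle_kind, s$cycle_duration_ms)
  f2 <- fit_first_harmonic(synth)
  expect_equal(f2$a0, f$a0, tolerance = 1e-12)
})

test_that("streaming engine equals stored-stack and full-refit reference", {
  ph <- make_phantom(c(32, 32), seed = 8)
  for (spec in list(list("respiratory", "ventilation", NULL),
                    list("cardiac", "perfusion_amplitude", ph$aorta_roi),
                    list("cardiac", "perfusion_timing", ph$aorta_roi))) {
    s <- simulate_cine(ph, spec[[1]], n_avg = 6, seed = 2)
    # shrink to an 12x12 corner crossing lung tissue to keep the refit cheap
    sub <- cine_series(s$data[15:26, 4:15, , drop = FALSE], spec[[1]],
                       s$cycle_duration_ms)
    roi <- if (is.null(spec[[3]])) NULL else {
      rr <- spec[[3]][15:26, 4:15]
      if (!any(rr)) rr[6, 6] <- TRUE
      rr
    }
    cfg <- boot_config(B = 40, seed = 17)
    fast <- bootstrap_error_map(sub, spec[[2]], roi, cfg, keep_stack = TRUE)
    sd_stack <- apply(fast$stack, 2, sd)
    expect_equal(as.vector(fast$values), sd_stack, tolerance = 1e-9)
    ref <- bootstrap_error_map(sub, spec[[2]], roi, cfg, engine = "reference")
    expect_equal(fast$values, ref$values, tolerance = 1e-9)
  }
})

test_that("with-replacement resampling runs and perturbs the DC term", {
  s <- random_series(c(3, 3, 10), seed = 41)
  cfg <- boot_config(B = 30, sampling = "with-replacement", seed = 2)
  em <- bootstrap_error_map(s, "ventilation", cfg = cfg)
  expect_true(all(em$values >= 0))
  expect_gt(median(em$values), 0)
  r <- compute_residuals(s, fit_first_harmonic(s))
  sh <- shuffle_residuals(r, seed = 1, sampling = "with-replacement")
  sums <- apply(sh$data, c(1, 2), sum)
  expect_gt(max(abs(sums)), 1e-6)  # multiset no longer preserved
})

test_that("configuration errors are rejected", {
  expect_error(boot_config(B = 1), "B")
  expect_error(boot_config(sd_ddof = 2), "sd_ddof")
  s <- random_series(seed = 51)
  expect_error(bootstrap_error_map(s, "perfusion_amplitude",
                                   cfg = boot_config(B = 10)),
               "cardiac")
  expect_error(error_map_ci(s, "ventilation",
                            cfg = boot_config(B = 5, R = 1)), "R")
})
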