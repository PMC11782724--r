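test_that("ventilation follows the expiration/inspiration signal ratio", {
  t <- 0:19
  # S_exp = 1.0, S_ins = 0.8  ->  a0 = 0.9, cosine amplitude 0.1
  s <- single_voxel_series(0.9 + 0.1 * cos(2 * pi * t / 20))
  vm <- ventilation_map(fit_first_harmonic(s))
  expect_equal(as.vector(vm$values), 0.2, tolerance = 1e-12)
  # no modulation -> zero ventilation
  v0 <- ventilation_map(fit_first_harmonic(single_voxel_series(rep(3, 20))))
  expect_equal(as.vector(v0$values), 0, tolerance = 1e-12)
  # S_exp <= 0 is masked invalid, not zeroed
  bad <- single_voxel_series(1 - 2 * cos(2 * pi * t / 20))
  vb <- ventilation_map(fit_first_harmonic(bad))
  expect_false(as.vector(vb$mask))
  expect_true(is.na(as.vector(vb$values)))
  # cardiac fit rejected
  cf <- fit_first_harmonic(single_voxel_series(rep(3, 20), "cardiac", 1000))
  expect_error(ventilation_map(cf), "respiratory")
})

test_that("perfusion maps are scale invariant and wrap timing correctly", {
  a0 <- matrix(c(10, 10, 50, 50), 2, 2)
  amp <- matrix(c(1, 0.5, 5, 0), 2, 2)
  phase <- matrix(c(pi / 2, -0.3, 0, 0), 2, 2)  # voxel [2,1] arbitrary
  roi <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2)
  s <- coeff_series(a0, amp, phase, n = 20, cycle = "cardiac", t_ms = 1000)
  f <- fit_first_harmonic(s)
  am <- perfusion_amplitude_map(f, roi)
  tm <- perfusion_timing_map(f, roi)
  # amplitude normalised by the ROI DC level (50)
  expect_equal(am$values, amp / 50, tolerance = 1e-9)
  # reference phase 0; delta phi = pi/2 with T_RR = 1000 ms -> +250 ms
  expect_equal(tm$values[1, 1], 250, tolerance = 1e-9)
  # wrap: 3*pi/2 -> -pi/2 -> -250 ms
  s2 <- coeff_series(a0, amp, matrix(c(3 * pi / 2, 0, 0, 0), 2, 2),
                     n = 20, cycle = "cardiac", t_ms = 1000)
  tm2 <- perfusion_timing_map(fit_first_harmonic(s2), roi)
  expect_equal(tm2$values[1, 1], -250, tolerance = 1e-9)
  # global intensity scaling leaves both maps unchanged
  sk <- cine_series(3.7 * s$data, "cardiac", 1000)
  fk <- fit_first_harmonic(sk)
  expect_equal(perfusion_amplitude_map(fk, roi)$values, am$values,
               tolerance = 1e-9)
  mod <- amp > 0   # timing is undefined where the harmonic vanishes
  expect_equal(perfusion_timing_map(fk, roi)$values[mod], tm$values[mod],
               tolerance = 1e-9)
  # anti-symmetry: negating all phases negates the timing (away from wrap)
  sneg <- coeff_series(a0, amp, -phase, n = 20, cycle = "cardiac",
                       t_ms = 1000)
  tneg <- perfusion_timing_map(fit_first_harmonic(sneg), roi)
  expect_equal(tneg$values[1, 1], -tm$values[1, 1], tolerance = 1e-9)
  # zero amplitude everywhere -> zero amplitude map
  sz <- coeff_series(a0, 0 * amp, phase, n = 20, cycle = "cardiac",
                     t_ms = 1000)
  expect_error(perfusion_timing_map(fit_first_harmonic(sz), roi),
               "reference phase undefined")
  # empty ROI rejected; respiratory fit rejected
  expect_error(perfusion_amplitude_map(f, roi & FALSE), "empty")
  rfit <- fit_first_harmonic(single_voxel_series(rep(3, 20)))
  expect_error(perfusion_amplitude_map(rfit, matrix(TRUE)), "cardiac")
})

test_that("all three maps recover the phantom ground truth without noise", {
  ph <- make_phantom(c(32, 32), seed = 4, noise_sigma = 0)
  rfit <- fit_first_harmonic(simulate_cine(ph, "respiratory", seed = 1))
  cfit <- fit_first_harmonic(simulate_cine(ph, "cardiac", seed = 1))
  lung <- ph$lung_mask
  vm <- ventilation_map(rfit)
  expect_lt(max(abs(vm$values - ph$vent_true)[lung]), 1e-9)
  am <- perfusion_amplitude_map(cfit, ph$aorta_roi)
  expect_lt(max(abs(am$values - ph$perf_amp_true)[lung]), 1e-9)
  tm <- perfusion_timing_map(cfit, ph$aorta_roi)
  tim_true <- ph$perf_phase_true / (2 * pi) * ph$cycle_duration_card_ms
  expect_lt(max(abs(tm$values - tim_true)[lung]), 1e-9)
  # timing range invariant
  t_rr <- ph$cycle_duration_card_ms
  expect_true(all(tm$values >= -t_rr / 2 & tm$values < t_rr / 2))
})
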