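test_that("phantom is deterministic and calibrated to healthy-volunteer medians", {
  ph1 <- make_phantom(c(64, 64), seed = 7)
  ph2 <- make_phantom(c(64, 64), seed = 7)
  expect_identical(ph1, ph2)

  lung <- ph1$lung_mask
  expect_true(any(lung))
  expect_lt(abs(median(ph1$vent_true[lung]) - 0.22), 0.02)
  expect_lt(abs(median(ph1$perf_amp_true[lung]) - 0.028), 0.005)

  # mask geometry invariants
  expect_false(any(ph1$lung_mask & ph1$aorta_roi))
  expect_true(all(ph1$body_mask[ph1$lung_mask]))
  expect_true(all(ph1$body_mask[ph1$aorta_roi]))
  # field invariants
  expect_true(all(ph1$vent_true[lung] >= 0 & ph1$vent_true[lung] < 1))
  expect_true(all(ph1$vent_true[!lung] == 0))
  expect_true(all(ph1$perf_amp_true >= 0))
  expect_true(all(ph1$perf_phase_true > -pi & ph1$perf_phase_true <= pi))
  expect_true(all(ph1$baseline_signal[ph1$body_mask] > 0))
  expect_true(all(ph1$baseline_signal[!ph1$body_mask] == 0))
})

test_that("zero amplitude scales and small grids are handled", {
  ph <- make_phantom(c(32, 32), seed = 1, vent_scale = 0, perf_scale = 0)
  expect_true(all(ph$vent_true == 0))
  expect_true(all(ph$perf_amp_true == 0))
  expect_error(make_phantom(c(16, 16), seed = 1), "grid too small")
})

test_that("noiseless series equal the harmonic model; phase mean recovers a0", {
  ph <- make_phantom(c(32, 32), seed = 3, noise_sigma = 0)
  rs <- simulate_cine(ph, "respiratory", seed = 1)
  # temporal mean equals the baseline at every voxel
  mu <- apply(rs$data, c(1, 2), mean)
  expect_lt(max(abs(mu - ph$baseline_signal)), 1e-10)
  # zero depth: lung voxels constant over phases
  rs0 <- simulate_cine(ph, "respiratory", depth_scale = 0, seed = 1)
  rng <- apply(rs0$data, c(1, 2), function(v) diff(range(v)))
  expect_lt(max(rng[ph$lung_mask]), 1e-12)
  # cardiac series warns when depth_scale is supplied
  expect_warning(simulate_cine(ph, "cardiac", depth_scale = 0.5, seed = 1),
                 "ignored")
})

test_that("voxel noise SD scales as 1/sqrt(n_avg)", {
  ph <- make_phantom(c(32, 32), seed = 5, noise_sigma = 2)
  ph0 <- ph; ph0$noise_sigma <- 0
  clean <- simulate_cine(ph0, "respiratory", seed = 1)
  s1 <- simulate_cine(ph, "respiratory", n_avg = 1, seed = 11)
  s4 <- simulate_cine(ph, "respiratory", n_avg = 4, seed = 12)
  sd1 <- sd(s1$data - clean$data)   # >1e4 draws each
  sd4 <- sd(s4$data - clean$data)
  expect_lt(abs(sd4 / sd1 - 0.5), 0.05 * 0.5)
})

test_that("scan sets share metadata and reproduce the depth distribution", {
  ph <- make_phantom(c(32, 32), seed = 2, noise_sigma = 0)
  ss <- simulate_scan_set(ph, n_scans = 3, seed = 9)
  expect_length(ss$depths_true, 3)
  expect_identical(ss, simulate_scan_set(ph, n_scans = 3, seed = 9))
  expect_true(all(vapply(ss$scans, function(s)
    identical(dim(s$resp$data), dim(s$card$data)), logical(1))))

  # degenerate distribution
  ss0 <- simulate_scan_set(ph, n_scans = 3, depth_mean = 0.8, depth_sd = 0,
                           seed = 1)
  expect_true(all(ss0$depths_true == 0.8))

  # sampling-distribution check on the realized depth scale factors
  ssn <- simulate_scan_set(ph, n_scans = 400, depth_mean = 0.243,
                           depth_sd = 0.056, seed = 4)
  se <- 0.056 / sqrt(400)
  expect_lt(abs(mean(ssn$depths_true) - 0.243), 3 * se)

  expect_error(simulate_scan_set(ph, n_scans = 1, seed = 1), "n_scans")
})
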