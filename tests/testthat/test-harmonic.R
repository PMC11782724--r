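test_that("first-harmonic fit recovers basis functions exactly", {
  t <- 0:19
  s <- single_voxel_series(2 + cos(2 * pi * t / 20))
  f <- fit_first_harmonic(s)
  expect_equal(as.vector(f$a0), 2, tolerance = 1e-12)
  expect_equal(as.vector(f$c1), 1 + 0i, tolerance = 1e-12)

  f0 <- fit_first_harmonic(single_voxel_series(rep(5, 8)))
  expect_equal(as.vector(f0$a0), 5, tolerance = 1e-12)
  expect_equal(Mod(as.vector(f0$c1)), 0, tolerance = 1e-12)
})

test_that("fitted c1 matches the loop-based DFT oracle", {
  for (n in c(5, 6, 8)) {
    s <- random_series(c(3, 4, n), seed = 100 + n)
    f <- fit_first_harmonic(s)
    for (v in seq_len(12)) {
      i <- ((v - 1) %% 3) + 1; j <- ((v - 1) %/% 3) + 1
      expect_equal(f$c1[i, j], dft_c1_oracle(s$data[i, j, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("fit is an idempotent linear projection", {
  x <- random_series(seed = 1)
  y <- random_series(seed = 2)
  fx <- fit_first_harmonic(x)
  # idempotence: fitting the model reproduces the fit
  fmx <- fit_first_harmonic(reconstruct_model(fx))
  expect_equal(fmx$a0, fx$a0, tolerance = 1e-10)
  expect_equal(fmx$c1, fx$c1, tolerance = 1e-10)
  # linearity
  z <- cine_series(2 * x$data + 3 * y$data, x$cycle_kind, x$cycle_duration_ms)
  fz <- fit_first_harmonic(z)
  fy <- fit_first_harmonic(y)
  expect_equal(fz$a0, 2 * fx$a0 + 3 * fy$a0, tolerance = 1e-10)
  expect_equal(fz$c1, 2 * fx$c1 + 3 * fy$c1, tolerance = 1e-10)
})

test_that("model plus residuals reproduces the data; residual bins vanish", {
  s <- random_series(c(4, 5, 20), seed = 3)
  f <- fit_first_harmonic(s)
  r <- compute_residuals(s, f)
  m <- reconstruct_model(f)
  expect_equal(m$data + r$data, s$data, tolerance = 1e-12)
  # temporal mean of the model is a0 everywhere
  expect_equal(apply(m$data, c(1, 2), mean), f$a0, tolerance = 1e-10)
  # per-voxel residual sum and first-harmonic bin vanish
  for (v in seq_len(20)) {
    i <- ((v - 1) %% 4) + 1; j <- ((v - 1) %/% 4) + 1
    rv <- r$data[i, j, ]
    expect_lt(abs(sum(rv)), 1e-9)
    expect_lt(Mod(dft_bin_oracle(rv, 1)), 1e-9)
  }
})

test_that("unmodelled harmonics pass through to the residuals exactly", {
  t <- 0:19
  second <- 0.3 * cos(4 * pi * t / 20)
  s <- single_voxel_series(4 + 1.2 * cos(2 * pi * t / 20 + 0.4) + second)
  f <- fit_first_harmonic(s)
  r <- compute_residuals(s, f)
  expect_equal(as.vector(r$data), second, tolerance = 1e-12)
  # pure first-harmonic input leaves no residual
  p <- single_voxel_series(4 + 1.2 * cos(2 * pi * t / 20 + 0.4))
  rp <- compute_residuals(p, fit_first_harmonic(p))
  expect_lt(max(abs(rp$data)), 1e-12)
  # a two-harmonic model absorbs the second harmonic too
  f2 <- fit_first_harmonic(s, n_harmonics = 2)
  r2 <- compute_residuals(s, f2)
  expect_lt(max(abs(r2$data)), 1e-12)
})

test_that("residuals reject a fit from a different series", {
  a <- random_series(seed = 10)
  b <- random_series(seed = 11)
  fa <- fit_first_harmonic(a)
  expect_error(compute_residuals(b, fa), "fingerprint")
})
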