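# Independent oracles and small builders used across the suite.

# loop-based DFT of one voxel time course (independent of the fit code)
dft_bin_oracle <- function(s, k) {
  n <- length(s)
  acc <- 0 + 0i
  for (t in 0:(n - 1)) acc <- acc + s[t + 1] * exp(-2i * pi * k * t / n)
  acc
}

# first-harmonic coefficient with the package's normalisation, by brute force
dft_c1_oracle <- function(s) (2 / length(s)) * dft_bin_oracle(s, 1)

# all n! permutations of 1..n as rows
perms_all <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- perms_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

single_voxel_series <- function(vals, cycle = "respiratory", t_ms = 4000) {
  cine_series(array(vals, c(1, 1, length(vals))), cycle, t_ms)
}

random_series <- function(dims = c(3, 4, 8), cycle = "respiratory",
                          t_ms = 4000, seed = 99) {
  set.seed(seed)
  cine_series(array(rnorm(prod(dims), 10, 2), dims), cycle, t_ms)
}

# noiseless cosine grid series from coefficient matrices
coeff_series <- function(a0, amp, phase, n = 20, cycle = "cardiac",
                         t_ms = 1000) {
  d <- dim(a0)
  dat <- array(0, c(d, n))
  for (ti in seq_len(n)) {
    dat[, , ti] <- a0 + amp * cos(2 * pi * (ti - 1) / n + phase)
  }
  cine_series(dat, cycle, t_ms)
}
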