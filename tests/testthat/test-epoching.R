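test_that("wavelet detail annihilates constants and passes bursts", {
  expect_lt(max(abs(wavelet_detail(rep(3.7, 256)))), 1e-10)

  # pure 1 Hz sinusoid at 167 Hz: level-1 detail is ~60 dB down
  fs <- 167
  s <- sin(2 * pi * 1 * (0:999) / fs)
  d <- wavelet_detail(s)
  expect_lt(sqrt(mean(d^2)) / sqrt(mean(s^2)), 0.01)

  expect_error(wavelet_detail(rnorm(4)), class = "ft_signal_error")
})

test_that("wavelet detail matches an explicit transform-matrix oracle", {
  # independent route: build the analysis/synthesis matrices of the
  # periodized one-level transform explicitly and project
  h <- fingertap:::.db4_scaling
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  N <- 64L
  A <- matrix(0, N / 2, N)  # approx analysis
  D <- matrix(0, N / 2, N)  # detail analysis
  for (k in seq_len(N / 2)) for (n in seq_len(L)) {
    col <- ((2 * (k - 1) + (n - 1)) %% N) + 1
    A[k, col] <- A[k, col] + h[n]
    D[k, col] <- D[k, col] + g[n]
  }
  set.seed(4)
  x <- rnorm(N)
  d_coefs <- D %*% x
  # synthesis of the detail band alone is the transpose (orthogonality)
  detail_oracle <- drop(t(D) %*% d_coefs)
  expect_equal(wavelet_detail(x), detail_oracle, tolerance = 1e-10)
  # and the two bands reconstruct the signal exactly
  expect_equal(drop(t(A) %*% (A %*% x)) + detail_oracle, x,
               tolerance = 1e-10)
})

test_that("impulse detail energy is localized within the filter support", {
  x <- numeric(256)
  x[100] <- 1
  d <- wavelet_detail(x)
  nz <- which(abs(d) > 1e-12)
  expect_true(all(nz >= 100 - 8 & nz <= 100 + 8))
})

test_that("taps of a clean score-0 train are recovered exactly", {
  p <- tap_train_params(base_freq = 2, seed = 42)
  rec <- simulate_tap_train(p)
  truth <- attr(rec, "truth")$boundaries
  taps <- detect_taps(rec)
  expect_length(taps, 11)
  expect_lte(max(abs(taps - truth)), 2)
})

test_that("noise-only signals raise an epoching failure", {
  set.seed(8)
  rec <- ft_recording(t = (0:999) / 167, ax = rnorm(1000, 0, 0.02),
                      ay = rnorm(1000, 0, 0.02),
                      az = 1 + rnorm(1000, 0, 0.02))
  expect_error(detect_taps(rec), class = "ft_epoching_error")
})

test_that("windowed search rejects spurious mid-movement bursts", {
  # clean train plus a strong high-frequency artifact mid-movement (e.g. a
  # tremor harmonic burst): default detection over-segments, the predictive
  # window recovers the construction boundaries
  p <- tap_train_params(base_freq = 2, seed = 21)
  rec <- simulate_tap_train(p)
  truth <- attr(rec, "truth")$boundaries
  fs <- rec$fs
  burst_len <- round(0.03 * fs)
  shape <- 0.5 * (1 - cos(2 * pi * seq_len(burst_len) / burst_len)) *
    cos(2 * pi * 55 * seq_len(burst_len) / fs)
  az <- rec$az
  for (b in truth[c(2, 4, 6, 8)]) {
    at <- b + round(0.25 * fs) + seq_len(burst_len)
    az[at] <- az[at] + 2.2 * shape
  }
  noisy <- ft_recording(rec$t, rec$ax, rec$ay, az, fs = fs)

  expect_gt(length(detect_taps(noisy)), 11)
  windowed <- detect_taps(noisy, window_pos = 0.35, window_width = 0.3)
  expect_length(windowed, 11)
  expect_lte(max(abs(windowed - truth)), 2)
})

test_that("epoch truncation keeps exactly the first 10 movements", {
  b14 <- cumsum(c(1, rep(80, 13)))
  expect_length(epoch_first_10(b14), 11)
  expect_identical(epoch_first_10(b14), as.integer(b14[1:11]))
  b11 <- cumsum(c(1, rep(80, 10)))
  expect_identical(epoch_first_10(b11), as.integer(b11))
  expect_error(epoch_first_10(b11[1:8]),
               class = "ft_insufficient_movements")
})

test_that("opening peak lands at the construction landmark", {
  p <- tap_train_params(base_freq = 2, topen_frac = 0.3, seed = 9)
  rec <- simulate_tap_train(p)
  ep <- epoch_recording(rec)
  truth <- attr(rec, "truth")
  frac <- (ep$opening_peak - ep$boundaries[1:10]) /
    diff(ep$boundaries)
  expect_lt(max(abs(frac - 0.3)), 0.05)
  expect_lte(max(abs(ep$opening_peak - truth$opening_peak)), 2)
})

test_that("guard band keeps the tap spike out of the opening search", {
  # adversarial: impact spike much larger than the opening bump
  fs <- 167
  n <- 200
  z <- numeric(n)
  z[96:104] <- 5 * exp(-0.5 * ((96:104 - 100) / 2)^2)  # opening bump
  z[1:4] <- c(8, -8, 8, -8)                            # spike at the tap
  z[197:200] <- c(8, -8, 8, -8)
  idx <- locate_opening_peak(z, fs, c(1L, 201L))
  expect_true(idx >= 90 && idx <= 110)
})

test_that("epoch ordering invariant holds on simulated cohort draws", {
  set.seed(30)
  for (s in 0:2) {
    rec <- simulate_tap_train(severity_to_params(s))
    ep <- epoch_recording(rec)
    expect_true(all(diff(ep$boundaries) > 0))
    expect_true(all(ep$boundaries[1:10] < ep$opening_peak))
    expect_true(all(ep$opening_peak < ep$boundaries[2:11]))
    expect_identical(ep$n_movements, 10L)
  }
})

test_that("score-4 rule is monotone under amplitude scaling", {
  p <- tap_train_params(base_freq = 2, seed = 13)
  rec <- simulate_tap_train(p)
  scale_rec <- function(c) ft_recording(rec$t, rec$ax * c, rec$ay * c,
                                        rec$az * c, fs = rec$fs)
  flags <- sapply(c(1, 0.3, 0.1, 0.03, 0.01),
                  function(c) detect_score4(scale_rec(c)))
  expect_false(flags[1])
  expect_true(flags[5])
  expect_true(all(diff(as.integer(flags)) >= 0))  # once TRUE, stays TRUE

  expect_true(detect_score4(ft_recording((0:499) / 167,
                                         rnorm(500, 0, 0.005),
                                         rnorm(500, 0, 0.005),
                                         1 + rnorm(500, 0, 0.005))))
})
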