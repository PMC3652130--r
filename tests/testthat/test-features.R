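test_that("movement frequencies are the inverse movement times", {
  ep <- structure(list(boundaries = as.integer(cumsum(c(1, rep(83, 10)))),
                       opening_peak = integer(10), n_movements = 10L),
                  class = "ft_epochs")
  expect_equal(movement_frequencies(ep, 167), rep(167 / 83, 10))

  # intervals doubling each movement halve the frequency each movement
  iv <- 10 * 2^(0:9)
  ep2 <- structure(list(boundaries = as.integer(cumsum(c(1, iv)))),
                   class = "ft_epochs")
  f <- movement_frequencies(ep2, 167)
  expect_equal(f[-1] / f[-10], rep(0.5, 9))
})

test_that("change onset rule matches brute-force enumeration on random series", {
  set.seed(123)
  for (rep in 1:200) {
    v <- rnorm(10, mean = 2, sd = 0.3)
    if (rep %% 3 == 0) {  # inject a step sometimes
      o <- sample(3:8, 1)
      v[(o + 1):10] <- v[(o + 1):10] - runif(1, 0.2, 1.5)
    }
    dir <- sample(c("decreasing", "increasing"), 1)
    expect_identical(change_onset_index(v, dir),
                     oracle_change_onset(v, dir))
  }
})

test_that("change onset returns 10 on constant series and stays in range", {
  expect_identical(change_onset_index(rep(2, 10), "decreasing"), 10L)
  expect_identical(change_onset_index(rep(2, 10), "increasing"), 10L)
  set.seed(99)
  for (i in 1:50) {
    v <- rnorm(10)
    r <- change_onset_index(v, "decreasing")
    expect_true(r %in% c(2:8, 10))
  }
  expect_error(change_onset_index(rnorm(3), "decreasing"),
               class = "ft_feature_error")
})

test_that("step series onset equals the oracle (frozen)", {
  # a clean step down at movement 5: with a near-constant completed side
  # every early split is significant, so the rule fires at the first
  # consecutive pair -- enumeration (and the oracle) give 2, not the
  # naive change point
  v <- c(2, 2, 2, 2, 1, 1, 1, 1, 1, 1)
  expect_identical(change_onset_index(v, "decreasing"), 2L)
  expect_identical(oracle_change_onset(v, "decreasing"), 2L)
})

test_that("robust slope resists a gross outlier", {
  expect_equal(as.numeric(robust_slope(1:10)), 1, tolerance = 1e-9)
  expect_equal(as.numeric(robust_slope(rep(4, 10))), 0)

  y <- 0.5 + 0.2 * (1:10)
  y_cont <- y
  y_cont[5] <- y[5] + 8
  sl <- as.numeric(robust_slope(y_cont))
  expect_lt(abs(sl - 0.2) / 0.2, 0.05)

  # oracle: MASS::rlm with bisquare psi on the same contaminated series
  skip_if_not_installed("MASS")
  or <- MASS::rlm(y_cont ~ I(1:10), psi = MASS::psi.bisquare,
                  scale.est = "MAD")
  expect_equal(sl, unname(coef(or)[2]), tolerance = 1e-3)
})

test_that("halt count thresholds residuals below the robust trend", {
  expect_identical(halt_count(rep(2, 10), 0.5), 0L)
  f <- rep(2, 10)
  f[6] <- 0.5
  expect_identical(halt_count(f, 1.0), 1L)
  # a fast outlier is never a halt
  f2 <- rep(2, 10)
  f2[6] <- 4
  expect_identical(halt_count(f2, 1.0), 0L)
})

test_that("hesitation band flags either series, once per movement", {
  expect_identical(hesitation_count(rep(2, 10), rep(0.3, 10)), 0L)
  set.seed(5)
  f <- rnorm(10, 2, 0.02)
  tp <- rnorm(10, 0.3, 0.005)
  f[3] <- 1.2
  tp[3] <- 0.55  # movement 3 deviant in both series: counted once
  f[8] <- 2.9    # movement 8 deviant in frequency only
  expect_identical(hesitation_count(f, tp), 2L)
})

test_that("injected hesitations are recovered on clean signals", {
  p <- tap_train_params(base_freq = 2, hesitation_indices = c(3, 8),
                        noise_sd = 0.02, seed = 1)
  rec <- simulate_tap_train(p)
  ep <- epoch_recording(rec)
  fv <- extract_features(rec, ep)
  expect_identical(unname(fv["Hesits"]), 2)
  expect_identical(unname(fv["Halts"]), 0)
})

test_that("injected halts and hypometria are recovered on clean signals", {
  p <- tap_train_params(base_freq = 1.3, halt_indices = 5L,
                        noise_sd = 0.02, seed = 2)
  rec <- simulate_tap_train(p)
  fv <- extract_features(rec, epoch_recording(rec))
  expect_identical(unname(fv["Halts"]), 1)

  p2 <- tap_train_params(base_freq = 1.4, hypometria_indices = c(2, 5, 6),
                         noise_sd = 0.02, seed = 3)
  rec2 <- simulate_tap_train(p2)
  fv2 <- extract_features(rec2, epoch_recording(rec2))
  expect_identical(unname(fv2["Hypom"]), 3)

  # clean single-bump openings yield zero
  p3 <- tap_train_params(base_freq = 1.4, noise_sd = 0.02, seed = 4)
  rec3 <- simulate_tap_train(p3)
  fv3 <- extract_features(rec3, epoch_recording(rec3))
  expect_identical(unname(fv3["Hypom"]), 0)
})

test_that("opening angle arcsin identities hold", {
  # a1x = 0, a2x = 1 -> 90 degrees; a1x = -0.5, a2x = 0.5 -> 60 degrees
  fs <- 167
  mk <- function(a1, a2) {
    # two movements of quasistatic closed/open plateaus
    one <- c(rep(a1, 30), seq(a1, a2, length.out = 25), rep(a2, 30),
             seq(a2, a1, length.out = 25), rep(a1, 10))
    x <- c(one, one)
    ep <- structure(list(boundaries = as.integer(c(1, 121, 241)),
                         opening_peak = as.integer(c(60, 180)),
                         n_movements = 2L), class = "ft_epochs")
    opening_angles(x, fs, ep)
  }
  expect_equal(mk(0, 1), c(90, 90), tolerance = 0.5)
  expect_equal(mk(-0.5, 0.5), c(60, 60), tolerance = 0.5)
})

test_that("peak accelerations recover construction amplitudes", {
  p <- tap_train_params(base_freq = 2, aclose_amp = 5, aopen_amp = 4,
                        seed = 6)
  rec <- simulate_tap_train(p)
  ep <- epoch_recording(rec)
  acc <- peak_accelerations(rec$az, rec$fs, ep)
  expect_lt(max(abs(acc$aclose - 5) / 5), 0.02)
  expect_lt(max(abs(acc$aopen - 4) / 4), 0.05)
})

test_that("event-free simulation yields the null feature pattern", {
  p <- tap_train_params(base_freq = 2.8, noise_sd = 0.02, seed = 10)
  rec <- simulate_tap_train(p)
  fv <- extract_features(rec, epoch_recording(rec))
  expect_identical(unname(fv[c("Dfreq", "Afreq", "Dangle")]), c(10, 10, 10))
  expect_identical(unname(fv[c("Hypom", "Hesits", "Halts")]), c(0, 0, 0))
  expect_length(fv, 18)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
})

test_that("noiseless parameter recovery is within 5%", {
  p <- tap_train_params(base_freq = 2, angle_open = 80, topen_frac = 0.3,
                        aclose_amp = 5, aopen_amp = 4, seed = 42)
  rec <- simulate_tap_train(p)
  fv <- extract_features(rec, epoch_recording(rec))
  expect_lt(abs(fv["Freq"] - 2) / 2, 0.05)
  expect_lt(abs(fv["Angle"] - 80) / 80, 0.05)
  expect_lt(abs(fv["Topen"] - 0.3) / 0.3, 0.05)
  expect_lt(abs(fv["Aclose"] - 5) / 5, 0.05)
  expect_lt(abs(fv["Aopen"] - 4) / 4, 0.05)
})

test_that("z-scaling covariance of the feature vector", {
  p <- tap_train_params(base_freq = 2, noise_sd = 0, seed = 17)
  rec <- simulate_tap_train(p)
  ep <- epoch_recording(rec)
  fv1 <- extract_features(rec, ep)
  cc <- 1.7
  # scale z only; reuse the same epochs (detection is scale-invariant here)
  rec2 <- ft_recording(rec$t, rec$ax, rec$ay, rec$az * cc, fs = rec$fs)
  fv2 <- extract_features(rec2, ep)
  scaled <- c("Aclose", "sdAclose", "slAclose", "Aopen", "sdAopen",
              "slAopen", "RMS")
  expect_equal(unname(fv2[scaled]), unname(fv1[scaled]) * cc,
               tolerance = 1e-6)
  fixed <- c("Freq", "Dfreq", "Afreq", "Topen", "sdTopen", "slTopen",
             "Hesits", "Halts")
  expect_equal(unname(fv2[fixed]), unname(fv1[fixed]), tolerance = 1e-8)
})

test_that("gravity artifact bound matches the trigonometric identity", {
  expect_equal(gravity_artifact_bound(0), 0)
  expect_equal(gravity_artifact_bound(90), 1)
  expect_lt(abs(gravity_artifact_bound(45) - 0.292), 1e-3)
  expect_error(gravity_artifact_bound(-5), class = "ft_param_error")
  expect_error(gravity_artifact_bound(95), class = "ft_param_error")
})
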