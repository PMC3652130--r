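#' Parameters of a simulated finger-tapping train
#'
#' Describes one synthetic recording of the 10-movement finger-tapping task.
#' A movement runs tap-to-tap; its duration is `1/freq` where `freq` follows
#' `base_freq * (1 + freq_trend * (i - 1))`, dropped by `freq_step` Hz for
#' every movement after `freq_decrement_onset`. The opening angle follows
#' `angle_open` minus `angle_step` degrees per movement after
#' `angle_decrement_onset`. Event indices inject clinical phenomena:
#' hesitations perturb the movement frequency or the opening-time fraction
#' beyond the outlier band, halts stretch a movement far below the frequency
#' trend, hypometric movements split the opening-acceleration peak into
#' three sub-peaks.
#'
#' @param n_taps number of movements (default 10).
#' @param fs sampling rate, Hz.
#' @param base_freq tapping frequency, Hz.
#' @param freq_trend per-movement relative frequency slope (dimensionless).
#' @param freq_decrement_onset movement index in `2..n_taps` after which the
#'   frequency drops by `freq_step`, or `NULL` for none.
#' @param freq_step frequency drop after the onset, Hz.
#' @param angle_open initial opening angle, degrees.
#' @param angle_decrement_onset index after which the angle decrements, or
#'   `NULL`.
#' @param angle_step angle loss per movement after the onset, degrees.
#' @param topen_frac fraction of movement time at maximum opening
#'   acceleration, in (0, 1).
#' @param aclose_amp,aopen_amp peak closing/opening accelerations, g.
#' @param aclose_trend,aopen_trend per-movement relative amplitude slopes.
#' @param hesitation_indices,halt_indices,hypometria_indices integer sets of
#'   affected movement indices.
#' @param tremor_amp tremor amplitude, g; `tremor_freq` in Hz (4-6 Hz rest
#'   tremor band).
#' @param tremor_freq tremor frequency, Hz.
#' @param noise_sd white sensor noise SD, g.
#' @param seed integer seed for the waveform randomness, or `NULL` to use
#'   the session RNG.
#' @return An object of class `tap_train_params`.
#' @export
tap_train_params <- function(n_taps = 10, fs = 167, base_freq = 2,
                             freq_trend = 0, freq_decrement_onset = NULL,
                             freq_step = 0.6, angle_open = 80,
                             angle_decrement_onset = NULL, angle_step = 6,
                             topen_frac = 0.3, aclose_amp = 5, aopen_amp = 4,
                             aclose_trend = 0, aopen_trend = 0,
                             hesitation_indices = integer(0),
                             halt_indices = integer(0),
                             hypometria_indices = integer(0),
                             tremor_amp = 0, tremor_freq = 5, noise_sd = 0,
                             seed = NULL) {
  p <- as.list(environment())
  validate_tap_train_params(p)
  structure(p, class = "tap_train_params")
}

validate_tap_train_params <- function(p) {
  ok_onset <- function(o) is.null(o) ||
    (length(o) == 1 && o == as.integer(o) && o >= 2 && o <= p$n_taps)
  if (p$n_taps < 2) stop(ft_error("n_taps must be >= 2", "ft_param_error"))
  if (p$fs <= 0 || p$base_freq <= 0)
    stop(ft_error("fs and base_freq must be positive", "ft_param_error"))
  if (p$topen_frac <= 0 || p$topen_frac >= 1)
    stop(ft_error("topen_frac must lie in (0, 1)", "ft_param_error"))
  if (!ok_onset(p$freq_decrement_onset) || !ok_onset(p$angle_decrement_onset))
    stop(ft_error("onsets must be in {2..n_taps} or NULL", "ft_param_error"))
  idx <- c(p$hesitation_indices, p$halt_indices, p$hypometria_indices)
  if (length(idx) && (any(idx < 1) || any(idx > p$n_taps)))
    stop(ft_error("event indices must be in 1..n_taps", "ft_param_error"))
  if (p$tremor_amp < 0 || p$noise_sd < 0 || p$aclose_amp < 0 || p$aopen_amp < 0)
    stop(ft_error("amplitudes must be non-negative", "ft_param_error"))
  invisible(p)
}

# per-movement ground-truth series implied by the parameters; hesitation
# perturbation draws use the current RNG state
.plan_train <- function(p) {
  n <- p$n_taps
  i <- seq_len(n)
  freq <- p$base_freq * (1 + p$freq_trend * (i - 1))
  if (!is.null(p$freq_decrement_onset))
    freq[i > p$freq_decrement_onset] <- freq[i > p$freq_decrement_onset] -
      p$freq_step
  topen <- rep(p$topen_frac, n)
  hes_type <- character(0)
  for (h in sort(p$hesitation_indices)) {
    type <- sample(c("freq_slow", "freq_fast", "topen"), 1)
    hes_type <- c(hes_type, type)
    if (type == "freq_slow") freq[h] <- freq[h] * stats::runif(1, 0.66, 0.70)
    else if (type == "freq_fast") freq[h] <- freq[h] * stats::runif(1, 1.30, 1.34)
    else topen[h] <- min(0.85, topen[h] + stats::runif(1, 0.16, 0.24))
  }
  for (h in p$halt_indices)
    freq[h] <- max(0.2, freq[h] - stats::runif(1, 0.9, 1.05))
  freq <- pmax(freq, 0.2)
  angle <- rep(p$angle_open, n)
  if (!is.null(p$angle_decrement_onset))
    angle <- pmax(2, p$angle_open -
                    p$angle_step * pmax(0, i - p$angle_decrement_onset))
  aclose <- pmax(0.01, p$aclose_amp * (1 + p$aclose_trend * (i - 1)))
  aopen <- pmax(0.01, p$aopen_amp * (1 + p$aopen_trend * (i - 1)))
  list(freq = freq, topen = topen, angle = angle, aclose = aclose,
       aopen = aopen, hes_type = hes_type)
}

# smooth open/close tilt profile on [0,1]: quasistatic plateaus at the
# closed (boundaries) and open (mid-movement) postures
.tilt_profile <- function(u) {
  s <- numeric(length(u))
  rise <- u > 0.10 & u < 0.38
  s[rise] <- 0.5 * (1 - cos(pi * (u[rise] - 0.10) / 0.28))
  s[u >= 0.38 & u <= 0.62] <- 1
  fall <- u > 0.62 & u < 0.90
  s[fall] <- 0.5 * (1 + cos(pi * (u[fall] - 0.62) / 0.28))
  s
}

#' Simulate a finger-tapping accelerometer recording
#'
#' Generates a triaxial trace with the morphology the pipeline assumes: a
#' short high-frequency closing burst (raised-cosine envelope, 50 Hz
#' carrier) at every tap boundary, a smooth Gaussian opening-acceleration
#' bump centred at `topen_frac` of each movement (split into three 1/3
#' amplitude sub-peaks for hypometric movements), an x-axis carrying the
#' gravity projection `sin(tilt)` with quasistatic plateaus at the closed
#' and open postures, a z-axis gravity term `cos(tilt)`, plus tremor
#' sinusoid and Gaussian sensor noise on all axes.
#'
#' @param params a [tap_train_params()].
#' @param hand,subject_id recording metadata.
#' @return An [ft_recording()]. The attribute `"truth"` carries the
#'   synthesis ground truth: tap boundary sample indices, opening-peak
#'   sample indices, and the per-movement frequency, opening-time fraction,
#'   angle, and peak-acceleration series actually realized (after sample
#'   quantization).
#' @export
simulate_tap_train <- function(params, hand = "right", subject_id = "sim") {
  stopifnot(inherits(params, "tap_train_params"))
  if (!is.null(params$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(params$seed)
  }
  p <- params
  plan <- .plan_train(p)
  fs <- p$fs
  n_mov <- p$n_taps
  n_i <- pmax(8L, as.integer(round(fs / plan$freq)))
  pad <- as.integer(round(0.3 * fs))
  N <- pad + sum(n_i) + pad
  boundaries <- pad + c(0L, cumsum(n_i)) + 1L   # n_mov + 1 tap instants

  z <- numeric(N)
  tilt <- numeric(N)

  # closing spike template: 36 ms raised-cosine envelope, 50 Hz carrier,
  # peaking exactly at the tap instant so its detail-band energy marks it
  spike_half <- as.integer(round(0.018 * fs))
  spike_t <- (-spike_half:spike_half) / fs
  spike_shape <- 0.5 * (1 + cos(pi * spike_t / max(spike_t))) *
    cos(2 * pi * 50 * spike_t)

  add_at <- function(sig, centre, shape) {
    idx <- centre + seq_along(shape) - 1L - (length(shape) - 1L) %/% 2L
    keep <- idx >= 1L & idx <= N
    sig[idx[keep]] <- sig[idx[keep]] + shape[keep]
    sig
  }

  # the tap occurs with fingers closed where z reads +1 g of gravity; the
  # burst amplitude is reduced so the realized |z| peak equals aclose
  spike_amp <- pmax(0.005, c(plan$aclose[1], plan$aclose) - 1)
  for (k in seq_len(n_mov + 1L))
    z <- add_at(z, boundaries[k], spike_amp[k] * spike_shape)

  # lay down the tilt profile first: the opening-bump amplitude is chosen
  # so the realized raw z peak (bump + gravity cos(tilt)) equals aopen
  for (i in seq_len(n_mov)) {
    b0 <- boundaries[i]
    len <- n_i[i]
    u <- (seq_len(len) - 1L) / len
    seg <- b0:(b0 + len - 1L)
    tilt[seg] <- plan$angle[i] * pi / 180 * .tilt_profile(u)
  }

  opening_idx <- integer(n_mov)
  for (i in seq_len(n_mov)) {
    b0 <- boundaries[i]
    len <- n_i[i]
    centre <- b0 + as.integer(round(plan$topen[i] * len))
    opening_idx[i] <- centre
    amp <- max(0.005, plan$aopen[i] - cos(tilt[centre]))
    tt <- (seq_len(N) - centre) / fs
    Ti <- len / fs
    if (i %in% p$hypometria_indices) {
      # fragmented opening: three narrow 1/3-amplitude bursts
      for (off in c(-0.14, 0, 0.14) * Ti) {
        bump <- (amp / 3) * exp(-0.5 * ((tt - off) / (0.035 * Ti))^2)
        z <- z + bump
      }
    } else {
      z <- z + amp * exp(-0.5 * (tt / (0.106 * Ti))^2)
    }
  }

  z <- z + cos(tilt)
  x <- sin(tilt)
  y <- numeric(N)

  if (p$tremor_amp > 0) {
    ph <- stats::runif(3, 0, 2 * pi)
    tt <- (seq_len(N) - 1L) / fs
    z <- z + p$tremor_amp * sin(2 * pi * p$tremor_freq * tt + ph[1])
    x <- x + 0.4 * p$tremor_amp * sin(2 * pi * p$tremor_freq * tt + ph[2])
    y <- y + 0.6 * p$tremor_amp * sin(2 * pi * p$tremor_freq * tt + ph[3])
  }
  if (p$noise_sd > 0) {
    z <- z + stats::rnorm(N, 0, p$noise_sd)
    x <- x + stats::rnorm(N, 0, p$noise_sd)
    y <- y + stats::rnorm(N, 0, p$noise_sd)
  }

  rec <- ft_recording(t = (seq_len(N) - 1L) / fs, ax = x, ay = y, az = z,
                      fs = fs, hand = hand, subject_id = subject_id)
  attr(rec, "truth") <- list(
    boundaries = boundaries, opening_peak = opening_idx,
    freq = fs / n_i, topen = plan$topen, angle = plan$angle,
    aclose = plan$aclose, aopen = plan$aopen,
    hesitation_indices = sort(p$hesitation_indices),
    halt_indices = sort(p$halt_indices),
    hypometria_indices = sort(p$hypometria_indices))
  rec
}

#' Draw tap-train parameters for a target clinical severity
#'
#' Maps an MDS-UPDRS finger-tapping score to a random parameter draw whose
#' phenomenology matches the scale anchors: 0 = steady fast tapping with no
#' events; 1 = one or two hesitations, or slight slowing, or a late
#' amplitude decrement; 2 = three to five interruptions, or mild slowing,
#' or a mid-sequence decrement; 3 = more than five interruptions or at
#' least one halt (freeze), or moderate slowing, or decrement from the
#' first tap; 4 = near-flat trace (task barely performed). Draws use the
#' session RNG (seed with [set.seed()] for reproducibility).
#'
#' @param score integer severity in `0..4`.
#' @return A [tap_train_params()] draw.
#' @export
severity_to_params <- function(score) {
  if (length(score) != 1 || !score %in% 0:4)
    stop(ft_error("score must be a single integer in 0..4", "ft_param_error"))
  U <- stats::runif
  common <- list(topen_frac = U(1, 0.24, 0.38), tremor_freq = U(1, 4, 6),
                 noise_sd = 0.02, seed = NULL)
  pars <- switch(as.character(score),
    "0" = list(base_freq = U(1, 2.4, 3.4), freq_trend = U(1, -0.005, 0.015),
               angle_open = U(1, 65, 105), aclose_amp = U(1, 4, 7),
               aopen_amp = U(1, 3, 6), tremor_amp = U(1, 0, 0.02)),
    "1" = {
      branch <- sample(c("hesit", "slow", "decrement"), 1)
      c(list(base_freq = if (branch == "slow") U(1, 1.5, 2.0)
             else if (branch == "hesit") U(1, 1.9, 2.3) else U(1, 1.9, 2.6),
             angle_open = U(1, 45, 85), aclose_amp = U(1, 3, 6),
             aopen_amp = U(1, 2.5, 5), tremor_amp = U(1, 0, 0.03),
             hesitation_indices = if (branch == "hesit")
               sort(sample(2:9, sample(1:2, 1))) else integer(0)),
        if (branch == "decrement")
          list(angle_decrement_onset = sample(7:9, 1), angle_step = U(1, 5, 9)))
    },
    "2" = {
      branch <- sample(c("hesit", "slow", "decrement"), 1)
      c(list(base_freq = if (branch == "slow") U(1, 1.0, 1.5) else U(1, 1.3, 1.9),
             angle_open = U(1, 30, 70), aclose_amp = U(1, 2, 5),
             aopen_amp = U(1, 1.8, 4), tremor_amp = U(1, 0, 0.04),
             hesitation_indices = if (branch == "hesit")
               sort(sample(2:10, sample(3:5, 1))) else integer(0),
             hypometria_indices = if (branch == "slow" &&
                                      stats::runif(1) < 0.5)
               sort(sample(2:9, sample(1:2, 1))) else integer(0)),
        if (branch == "decrement")
          list(angle_decrement_onset = sample(4:6, 1), angle_step = U(1, 6, 10)))
    },
    "3" = {
      branch <- sample(c("many_hesit", "halt", "slow", "decrement"), 1)
      c(list(base_freq = if (branch == "slow") U(1, 0.8, 1.1) else U(1, 1.1, 1.5),
             angle_open = U(1, 15, 55), aclose_amp = U(1, 1.5, 4),
             aopen_amp = U(1, 1.5, 3.5), tremor_amp = U(1, 0, 0.05),
             aclose_trend = U(1, -0.05, 0), aopen_trend = U(1, -0.05, 0),
             hesitation_indices = if (branch == "many_hesit")
               sort(sample(2:10, sample(6:8, 1))) else integer(0),
             halt_indices = if (branch == "halt")
               sort(sample(3:9, sample(1:2, 1))) else integer(0),
             hypometria_indices = if (stats::runif(1) < 0.6)
               sort(sample(2:9, sample(1:3, 1))) else integer(0)),
        if (branch == "decrement")
          list(angle_decrement_onset = 2, angle_step = U(1, 8, 12)))
    },
    "4" = list(base_freq = U(1, 0.5, 1.0), angle_open = U(1, 1, 4),
               aclose_amp = U(1, 0.02, 0.06), aopen_amp = U(1, 0.015, 0.05),
               tremor_amp = U(1, 0, 0.01), noise_sd = 0.015))
  args <- utils::modifyList(common, pars)
  do.call(tap_train_params, args)
}

#' Simulate a severity-graded cohort of labelled recordings
#'
#' @param scores integer vector of latent severities in `0..4`, one per
#'   observation (subject-hand).
#' @param seed integer seed making the whole cohort reproducible.
#' @return A list of labelled recordings; each element is a list with
#'   `recording` (an [ft_recording()]), `latent_score`, and `params`.
#' @export
simulate_cohort <- function(scores, seed = 1) {
  stopifnot(all(scores %in% 0:4))
  set.seed(seed)
  hands <- c("right", "left")
  lapply(seq_along(scores), function(i) {
    params <- severity_to_params(scores[i])
    rec <- simulate_tap_train(params, hand = hands[1 + (i %% 2)],
                              subject_id = sprintf("S%03d", i))
    list(recording = rec, latent_score = scores[i], params = params)
  })
}

#' Simulate a feature table from a cumulative-logit model
#'
#' Draws `n` feature vectors from `feature_sampler`, computes class
#' probabilities under the proportional-odds model
#' `P(y <= j | x) = logistic(alpha_j - beta'x)`, and samples ordinal scores
#' from them. Used to test parameter recovery of the fitter.
#'
#' @param alphas three strictly increasing cutpoint intercepts.
#' @param betas slope coefficients (length p).
#' @param n number of observations, >= 1.
#' @param feature_sampler function of `n` returning an `n x p` matrix;
#'   defaults to standard normal features.
#' @return A list with `X` (n x p matrix) and `y` (integer scores 0..3).
#' @export
simulate_feature_table <- function(alphas, betas, n,
                                   feature_sampler = NULL) {
  if (length(alphas) != 3 || any(diff(alphas) <= 0))
    stop(ft_error("alphas must be 3 strictly increasing values",
                  "ft_param_error"))
  if (n < 1) stop(ft_error("n must be >= 1", "ft_param_error"))
  p <- length(betas)
  X <- if (is.null(feature_sampler)) {
    matrix(stats::rnorm(n * p), n, p)
  } else {
    as.matrix(feature_sampler(n))
  }
  if (nrow(X) != n || ncol(X) != p)
    stop(ft_error("feature_sampler must return an n x p matrix",
                  "ft_param_error"))
  eta <- if (p) drop(X %*% betas) else rep(0, n)
  cum <- stats::plogis(outer(eta, alphas, function(e, a) a - e))
  probs <- cbind(cum[, 1], cum[, 2] - cum[, 1], cum[, 3] - cum[, 2],
                 1 - cum[, 3])
  y <- vapply(seq_len(n),
              function(i) sample(0:3, 1, prob = pmax(probs[i, ], 0)),
              integer(1))
  colnames(X) <- if (p) paste0("x", seq_len(p)) else character(0)
  list(X = X, y = y)
}
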