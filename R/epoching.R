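#' Level-1 Daubechies (db4) wavelet detail of a signal
#'
#' Decomposes the signal with the periodized discrete wavelet transform
#' using the 8-tap Daubechies filter with four vanishing moments and
#' reconstructs the requested detail band alone, returning a signal of the
#' same length as the input. Level 1 is the highest-frequency band
#' (fs/4 to fs/2), where the index-thumb impact burst lives and smooth
#' movement components do not.
#'
#' @param z numeric signal (g).
#' @param level decomposition level of the detail to reconstruct
#'   (default 1).
#' @return Numeric vector, same length as `z`.
#' @export
wavelet_detail <- function(z, level = 1L) {
  level <- as.integer(level)
  stopifnot(level >= 1)
  n <- length(z)
  if (n < 8 * 2^level)
    stop(ft_error("signal shorter than the wavelet filter support",
                  "ft_signal_error"))
  # periodized transform needs even length at each level; pad by reflection
  n_pad <- (2^level - n %% 2^level) %% 2^level
  x <- if (n_pad) c(z, z[n:(n - n_pad + 1L)]) else z

  approx <- list()
  cur <- x
  for (l in seq_len(level)) {
    st <- .dwt_step(cur)
    approx[[l]] <- st
    cur <- st$approx
  }
  # reconstruct only the deepest detail through the synthesis cascade
  rec <- .idwt_step(numeric(length(approx[[level]]$detail)),
                    approx[[level]]$detail)
  if (level > 1) {
    for (l in (level - 1):1)
      rec <- .idwt_step(rec, numeric(length(rec)))
  }
  rec[seq_len(n)]
}

#' Detect tap boundaries in a recording
#'
#' Taps (index-thumb impacts) appear as short high-frequency bursts in the
#' z-axis; they are located as local maxima of the absolute level-1 db4
#' wavelet detail above an adaptive robust threshold
#' `k * median(|detail|) / 0.6745`, separated by at least `min_interval`
#' seconds. When `window_pos`/`window_width` are given, detection switches
#' to a predictive windowed search: starting from the strongest burst, the
#' next (previous) tap is sought only inside a window `window_pos` seconds
#' after (before) the current one, `window_width` seconds wide — the manual
#' adaptation needed for tremulous or severely hesitant recordings.
#'
#' @param recording an [ft_recording()].
#' @param window_pos offset of the predictive search window from the
#'   current tap, seconds; `NULL` disables windowed search.
#' @param window_width width of the predictive search window, seconds.
#' @param min_interval minimum inter-tap separation, seconds (default
#'   0.12 s, i.e. a ceiling of ~8 Hz tapping).
#' @param k robust threshold multiplier (default 5).
#' @param floor_frac threshold floor as a fraction of the strongest detail
#'   burst (default 0.15); keeps the adaptive threshold meaningful on
#'   noise-free signals where the median detail is numerically zero.
#' @param level wavelet detail level (default 1, the highest band).
#' @return Integer vector of tap sample indices (1-based), increasing.
#' @export
detect_taps <- function(recording, window_pos = NULL, window_width = NULL,
                        min_interval = 0.12, k = 5, floor_frac = 0.15,
                        level = 1L) {
  stopifnot(inherits(recording, "ft_recording"))
  fs <- recording$fs
  d <- abs(wavelet_detail(recording$az, level = level))
  thr <- max(k * stats::median(d) / 0.6745, floor_frac * max(d))
  sep <- max(2L, as.integer(round(min_interval * fs)))
  peaks <- .find_peaks(d, min_height = thr, min_sep = sep)
  if (length(peaks) < 2)
    stop(ft_error("fewer than 2 tap candidates above threshold",
                  "ft_epoching_error"))
  if (is.null(window_pos) || is.null(window_width)) return(peaks)

  # predictive windowed search, anchored at the strongest burst
  off <- as.integer(round(window_pos * fs))
  width <- max(2L, as.integer(round(window_width * fs)))
  anchor <- peaks[which.max(d[peaks])]
  floor_thr <- thr / 2
  walk <- function(start, dir) {
    out <- integer(0)
    cur <- start
    repeat {
      if (dir > 0) {
        lo <- cur + off
        hi <- lo + width
      } else {
        hi <- cur - off
        lo <- hi - width
      }
      lo <- max(1L, lo); hi <- min(length(d), hi)
      if (lo >= hi) break
      seg <- d[lo:hi]
      j <- lo + which.max(seg) - 1L
      if (d[j] < floor_thr) break
      out <- c(out, j)
      cur <- j
    }
    out
  }
  sort(unique(c(walk(anchor, -1L), anchor, walk(anchor, +1L))))
}

#' Keep the first 10 movements of a boundary sequence
#'
#' @param boundaries increasing tap sample indices.
#' @param n_movements number of movements to keep (default 10).
#' @return Integer vector of `n_movements + 1` boundaries.
#' @export
epoch_first_10 <- function(boundaries, n_movements = 10L) {
  if (length(boundaries) < n_movements + 1L)
    stop(ft_error(sprintf(
      "need at least %d tap boundaries for %d movements, found %d",
      n_movements + 1L, n_movements, length(boundaries)),
      "ft_insufficient_movements"))
  if (any(diff(boundaries) <= 0))
    stop(ft_error("boundaries must be strictly increasing",
                  "ft_epoching_error"))
  as.integer(boundaries[seq_len(n_movements + 1L)])
}

#' Locate the opening-acceleration peak inside one movement
#'
#' The finger-opening acceleration is the low-frequency high-amplitude peak
#' in the interior of the movement; it is found as the argmax of the
#' low-pass filtered z-axis within the interval, excluding a guard band
#' around each tap burst so the impact spike can never win.
#'
#' @param z z-axis signal, g.
#' @param fs sampling rate, Hz.
#' @param interval integer `c(start, end)` sample indices of the movement,
#'   half-open `[start, end)`.
#' @param guard guard band half-width around each boundary, seconds.
#' @param cutoff low-pass cutoff, Hz.
#' @param x optional x-axis signal; when given, the tilt-dependent gravity
#'   baseline `sqrt(1 - x_lp^2)` is removed from z before the search,
#'   sharpening the opening peak against the gravity modulation.
#' @return Sample index of the opening peak.
#' @export
locate_opening_peak <- function(z, fs, interval, guard = 0.08, cutoff = 10,
                                x = NULL) {
  start <- interval[1]; end <- interval[2]
  if (end - start < 10)
    stop(ft_error("movement interval shorter than 10 samples",
                  "ft_epoching_error"))
  g <- as.integer(round(guard * fs))
  lo <- start + g
  hi <- end - 1L - g
  if (lo >= hi) {  # very short movement: fall back to the strict interior
    lo <- start + 2L
    hi <- end - 3L
  }
  zz <- if (is.null(x)) z else z - .gravity_z(x, fs, cutoff)
  zf <- .lowpass(zz[start:(end - 1L)], fs, cutoff)
  seg <- zf[(lo - start + 1L):(hi - start + 1L)]
  as.integer(lo + which.max(seg) - 1L)
}

#' Flag a recording as score 4 from its signal variance
#'
#' Patients who cannot perform the task produce a near-flat trace; the rule
#' returns `TRUE` when the z-axis variance over the whole recording is
#' below `threshold` (default 0.01 g^2).
#'
#' @param recording an [ft_recording()].
#' @param threshold variance threshold, g^2.
#' @return Logical.
#' @export
detect_score4 <- function(recording, threshold = 0.01) {
  stopifnot(inherits(recording, "ft_recording"))
  stats::var(recording$az) < threshold
}

#' Epoch a recording into its first 10 movements
#'
#' Runs [detect_taps()], truncates to the first `n_movements` inter-tap
#' intervals with [epoch_first_10()], and locates the opening peak of each
#' movement. Movement `i` spans samples `[boundaries[i], boundaries[i+1])`.
#'
#' @param recording an [ft_recording()].
#' @param config a [pipeline_config()] (defaults used when `NULL`).
#' @return An object of class `ft_epochs`: list with `boundaries`
#'   (length `n_movements + 1`), `opening_peak` (length `n_movements`) and
#'   `n_movements`.
#' @export
epoch_recording <- function(recording, config = NULL) {
  cfg <- if (is.null(config)) pipeline_config() else config
  taps <- detect_taps(recording, window_pos = cfg$window_pos,
                      window_width = cfg$window_width,
                      min_interval = cfg$min_interval, k = cfg$detector_k,
                      level = cfg$wavelet_level)
  b <- epoch_first_10(taps, cfg$n_movements)
  op <- vapply(seq_len(cfg$n_movements), function(i) {
    locate_opening_peak(recording$az, recording$fs, c(b[i], b[i + 1L]),
                        guard = cfg$opening_guard,
                        cutoff = cfg$opening_lowpass_hz,
                        x = recording$ax)
  }, integer(1))
  structure(list(boundaries = b, opening_peak = op,
                 n_movements = cfg$n_movements),
            class = "ft_epochs")
}

#' @export
print.ft_epochs <- function(x, ...) {
  cat(sprintf("<ft_epochs> %d movements, taps at samples %s...\n",
              x$n_movements, paste(utils::head(x$boundaries, 4),
                                   collapse = ", ")))
  invisible(x)
}
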