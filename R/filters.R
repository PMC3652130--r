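# Internal signal-processing primitives.
#
# No wavelet or filter-design package is assumed; the one-level periodized
# db4 transform and the bilinear-transform Butterworth low-pass are small,
# self-contained, and verified against direct-convolution / analytic
# frequency-response oracles in the test suite.

# Daubechies-4 (8-tap) scaling filter, normalized so sum(h) = sqrt(2)
.db4_scaling <- c(
   0.230377813308855230, 0.714846570552541500,
   0.630880767929590400, -0.027983769416983850,
  -0.187034811718881140, 0.030841381835986965,
   0.032883011666982945, -0.010597401784997278
)

.db4_filters <- function() {
  lo_r <- .db4_scaling
  L <- length(lo_r)
  # quadrature mirror: g[k] = (-1)^k h[L-1-k]  (0-based)
  hi_r <- rev(lo_r) * (-1)^(seq_len(L) - 1)
  list(lo_d = rev(lo_r), hi_d = rev(hi_r), lo_r = lo_r, hi_r = hi_r)
}

# circular filtering: y[n] = sum_m f[m] x[n - m + 1] (periodic extension)
.circ_filter <- function(x, f) {
  N <- length(x)
  y <- numeric(N)
  for (m in seq_along(f)) {
    idx <- ((seq_len(N) - m) %% N) + 1L
    y <- y + f[m] * x[idx]
  }
  y
}

# One level of the periodized orthogonal DWT: a[k] = sum_n h[n] x[2k+n],
# d[k] likewise with the quadrature-mirror filter (0-based indexing).
# Returns list(approx, detail), each length N/2.
.dwt_step <- function(x) {
  fl <- .db4_filters()
  N <- length(x)
  odd <- seq(1L, N, by = 2L)
  a <- .circ_filter2(x, fl$lo_r)[odd]
  d <- .circ_filter2(x, fl$hi_r)[odd]
  list(approx = a, detail = d)
}

# inverse of one step given approx/detail (either may be zeroed):
# x[m] = sum_k h[m-2k] a[k] + g[m-2k] d[k]
.idwt_step <- function(a, d) {
  fl <- .db4_filters()
  N <- 2L * length(a)
  ua <- numeric(N); ua[seq(1L, N, by = 2L)] <- a
  ud <- numeric(N); ud[seq(1L, N, by = 2L)] <- d
  .circ_filter(ua, fl$lo_r) + .circ_filter(ud, fl$hi_r)
}

# correlation form used on the synthesis side: y[n] = sum_m f[m] x[n + m - 1]
.circ_filter2 <- function(x, f) {
  N <- length(x)
  y <- numeric(N)
  for (m in seq_along(f)) {
    idx <- ((seq_len(N) + m - 2L) %% N) + 1L
    y <- y + f[m] * x[idx]
  }
  y
}

# Butterworth low-pass design via bilinear transform.
# Returns list(b, a) for cutoff in Hz at sampling rate fs.
.butter_lowpass <- function(cutoff, fs, order = 4L) {
  stopifnot(cutoff > 0, cutoff < fs / 2, order >= 1)
  warped <- tan(pi * cutoff / fs)
  k <- seq_len(order)
  # analog prototype poles on the unit circle, left half-plane
  p_analog <- warped * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  p_z <- (1 + p_analog) / (1 - p_analog)
  a <- Re(.poly_from_roots(p_z))
  b <- choose(order, 0:order)          # zeros at z = -1
  b <- b * sum(a) / sum(b)             # unit DC gain
  list(b = b, a = a)
}

.poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# direct-form IIR filter with zero initial state
.iir_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  v <- stats::filter(c(rep(0, length(b) - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[length(b):(length(b) - 1 + length(x))]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# zero-phase filtering (forward + reverse) with odd reflection padding
.filtfilt <- function(b, a, x) {
  n_pad <- 3L * (max(length(a), length(b)) - 1L)
  n_pad <- min(n_pad, length(x) - 1L)
  if (n_pad > 0) {
    head_pad <- 2 * x[1] - x[(n_pad + 1L):2L]
    tail_pad <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - n_pad)]
    xe <- c(head_pad, x, tail_pad)
  } else xe <- x
  y <- .iir_filter(b, a, xe)
  y <- rev(.iir_filter(b, a, rev(y)))
  if (n_pad > 0) y <- y[(n_pad + 1L):(n_pad + length(x))]
  y
}

# zero-phase Butterworth low-pass, cutoff in Hz
.lowpass <- function(x, fs, cutoff, order = 4L) {
  if (cutoff >= fs / 2) return(x)
  ba <- .butter_lowpass(cutoff, fs, order)
  .filtfilt(ba$b, ba$a, x)
}

# centered moving variance over a window of `width` samples
.moving_variance <- function(x, width) {
  width <- max(3L, as.integer(width))
  w <- rep(1 / width, width)
  mu <- as.numeric(stats::filter(x, w, sides = 2))
  mu2 <- as.numeric(stats::filter(x^2, w, sides = 2))
  v <- mu2 - mu^2
  v[v < 0] <- 0
  # fill edges with nearest interior value
  first <- which(!is.na(v))[1]
  last <- max(which(!is.na(v)))
  v[seq_len(first - 1)] <- v[first]
  if (last < length(v)) v[(last + 1):length(v)] <- v[last]
  v
}

# local maxima above a threshold with a minimum separation (greedy by height)
.find_peaks <- function(x, min_height = -Inf, min_sep = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}
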