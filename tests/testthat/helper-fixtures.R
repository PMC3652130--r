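# Shared fixtures, built once per test run and cached.

.fx <- new.env()

# severity-graded cohort of 80 observations (20 per class 0..3) with the
# features extracted by the full pipeline
fx_cohort <- function() {
  if (is.null(.fx$cohort)) {
    cohort <- simulate_cohort(rep(0:3, each = 20), seed = 101)
    X <- NULL
    y <- integer(0)
    for (lr in cohort) {
      ep <- epoch_recording(lr$recording)
      X <- rbind(X, extract_features(lr$recording, ep))
      y <- c(y, lr$latent_score)
    }
    rownames(X) <- NULL
    .fx$cohort <- list(X = X, y = y, recordings = cohort)
  }
  .fx$cohort
}

# small, fast cohort for pipeline/CLI tests: 24 observations, classes 0..3
fx_small_cohort <- function() {
  if (is.null(.fx$small)) {
    .fx$small <- simulate_cohort(rep(0:3, each = 6), seed = 77)
  }
  .fx$small
}

# --- independent oracles -------------------------------------------------

# O(n^2) double-loop Goodman-Kruskal Gamma
oracle_gamma <- function(a, b) {
  n <- length(a)
  C <- 0; D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(a[i] - a[j]) * sign(b[i] - b[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  (C - D) / (C + D)
}

# O(n^2) pairwise concordance AUC with midpoint ties
oracle_auc <- function(score, positive) {
  pos <- score[as.logical(positive)]
  neg <- score[!as.logical(positive)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# independently coded change-onset rule (Welch t, directional,
# two consecutive significant splits)
oracle_change_onset <- function(v, direction, alpha = 0.05) {
  n <- length(v)
  welch_p <- function(a, b) {
    va <- var(a); vb <- var(b)
    se2 <- va / length(a) + vb / length(b)
    if (se2 <= 0) return(if (mean(a) == mean(b)) 1 else 0)
    tt <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                     (vb / length(b))^2 / (length(b) - 1))
    2 * pt(-abs(tt), df)
  }
  sig <- sapply(2:(n - 2), function(i) {
    a <- v[1:i]; b <- v[(i + 1):n]
    ok <- if (direction == "decreasing") mean(b) < mean(a)
          else mean(b) > mean(a)
    ok && welch_p(a, b) < alpha
  })
  idx <- 2:(n - 2)
  for (j in seq_len(length(idx) - 1))
    if (sig[j] && sig[j + 1]) return(idx[j])
  n
}

# the published 4x4 contingency table (predicted rows 0..3, consensus
# columns 0..3)
published_table <- function() {
  matrix(c(9, 3, 0, 0,
           3, 24, 6, 0,
           0, 5, 24, 2,
           0, 0, 1, 9), nrow = 4, byrow = TRUE)
}
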