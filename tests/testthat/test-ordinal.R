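test_that("intercept-only MLE equals empirical cumulative logits", {
  counts <- c(12, 32, 31, 11)
  y <- rep(0:3, counts)
  fit <- ordinal_fit(matrix(numeric(0), length(y), 0), y, ridge = 0)
  emp <- qlogis(cumsum(counts)[1:3] / sum(counts))
  expect_equal(fit$alphas, emp, tolerance = 1e-8)
  # fitted cumulative probabilities = empirical cumulative proportions
  probs <- class_probs(fit, matrix(numeric(0), 1, 0))
  expect_equal(cumsum(probs[1, ])[1:3], cumsum(counts / sum(counts))[1:3],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(3)
  X <- matrix(rnorm(200), 50, 4)
  y <- sample(0:3, 50, replace = TRUE)
  for (rep in 1:5) {
    al <- sort(rnorm(3, sd = 1.5))
    be <- rnorm(4, sd = 0.5)
    g <- fingertap:::.ord_grad_cpp(X, y, al, be)
    h <- 1e-6
    fd <- sapply(1:7, function(k) {
      ap <- al; bp <- be; am <- al; bm <- be
      if (k <= 3) { ap[k] <- ap[k] + h; am[k] <- am[k] - h }
      else { bp[k - 3] <- bp[k - 3] + h; bm[k - 3] <- bm[k - 3] - h }
      (fingertap:::.ord_loglik_cpp(X, y, ap, bp) -
         fingertap:::.ord_loglik_cpp(X, y, am, bm)) / (2 * h)
    })
    expect_lt(max(abs(g - fd)), 1e-6)
  }
})

test_that("parameters are recovered within 15% at n = 2000", {
  set.seed(2)
  true_b <- c(1, -0.7)
  sim <- simulate_feature_table(c(-2, 0, 2), true_b, 2000)
  fit <- ordinal_fit(sim$X, sim$y, ridge = 0)
  expect_true(fit$converged)
  expect_true(all(abs(fit$betas - true_b) / abs(true_b) < 0.15))
  # optimization improved on the starting point (ll non-decreasing)
  ll0 <- fingertap:::.ord_loglik_cpp(sim$X, sim$y,
                                     qlogis(cumsum(tabulate(sim$y + 1,
                                                            4) / 2000)[1:3]),
                                     c(0, 0))
  expect_gte(fit$loglik, ll0)
})

test_that("fit agrees with the MASS::polr oracle", {
  skip_if_not_installed("MASS")
  set.seed(6)
  sim <- simulate_feature_table(c(-1.5, 0, 1.5), c(0.8, -0.5, 0.3), 400)
  fit <- ordinal_fit(sim$X, sim$y, ridge = 0)
  df <- data.frame(y = factor(sim$y, ordered = TRUE), sim$X)
  or <- MASS::polr(y ~ x1 + x2 + x3, df)
  expect_equal(fit$betas, unname(coef(or)), tolerance = 1e-4)
  expect_equal(fit$alphas, unname(or$zeta), tolerance = 1e-4)
})

test_that("separation blows up at ridge 0 and is tamed by the penalty", {
  y <- rep(0:3, each = 10)
  X <- matrix(as.numeric(y >= 2), ncol = 1,
              dimnames = list(NULL, "Halts"))
  f0 <- ordinal_fit(X, y, ridge = 0)
  expect_true(!f0$converged || abs(f0$betas) > 10)
  f1 <- ordinal_fit(X, y, ridge = 0.01)
  expect_true(f1$converged)
  expect_true(is.finite(f1$betas) && abs(f1$betas) < 20)
})

test_that("fit input contracts are enforced", {
  y <- rep(0:2, each = 10)  # class 3 absent
  X <- matrix(rnorm(30), ncol = 1)
  expect_error(ordinal_fit(X, y), class = "ft_model_error")
  y4 <- c(rep(0:3, 2), 0)
  expect_error(ordinal_fit(matrix(rnorm(9 * 6), 9, 6), y4),
               class = "ft_model_error")
})

test_that("class probabilities follow the cumulative-logit identities", {
  fit <- structure(list(alphas = c(-1.386, 0, 1.386), betas = numeric(0),
                        feature_names = character(0), loglik = NA,
                        converged = TRUE, ridge = 0, n = 0),
                   class = "ordinal_fit")
  p <- class_probs(fit, matrix(numeric(0), 1, 0))
  expect_equal(unname(p[1, ]), c(0.2, 0.3, 0.3, 0.2), tolerance = 1e-3)
  expect_equal(continuous_score(p), 1.5, tolerance = 1e-6)

  # large positive linear predictor pushes all mass to class 3
  fit2 <- structure(list(alphas = c(-1, 0, 1), betas = 5,
                         feature_names = "x", loglik = NA, converged = TRUE,
                         ridge = 0, n = 0), class = "ordinal_fit")
  p2 <- class_probs(fit2, matrix(50, 1, 1, dimnames = list(NULL, "x")))
  expect_equal(unname(p2[1, ]), c(0, 0, 0, 1), tolerance = 1e-10)
})

test_that("probabilities are non-negative and sum to one (property)", {
  set.seed(44)
  for (i in 1:1000) {
    al <- sort(rnorm(3, sd = 2))
    p <- length(be <- rnorm(sample(1:5, 1), sd = 2))
    fit <- structure(list(alphas = al, betas = be,
                          feature_names = paste0("x", 1:p), loglik = NA,
                          converged = TRUE, ridge = 0, n = 0),
                     class = "ordinal_fit")
    pr <- class_probs(fit, matrix(rnorm(p), 1, p,
                                  dimnames = list(NULL, paste0("x", 1:p))))
    expect_true(all(pr >= 0))
    expect_lt(abs(sum(pr) - 1), 1e-12)
  }
})

test_that("continuous score is monotone in a positive-beta feature", {
  set.seed(12)
  sim <- simulate_feature_table(c(-1, 0, 1), c(1.2, -0.4), 300)
  fit <- ordinal_fit(sim$X, sim$y)
  xs <- seq(-3, 3, length.out = 21)
  scores <- sapply(xs, function(v)
    predict(fit, matrix(c(v, 0.5), 1, 2,
                        dimnames = list(NULL, c("x1", "x2")))))
  expect_true(all(diff(scores) >= 0))
})

test_that("continuous score and discretization edge cases", {
  expect_equal(continuous_score(rep(0.25, 4)), 1.5)
  expect_equal(continuous_score(c(0, 0, 0, 1)), 3)
  expect_error(continuous_score(c(0.5, 0.2, 0.2, 0.2)),
               class = "ft_param_error")

  expect_identical(discretize_score(c(1.49, 1.51)), c(1, 2))
  expect_identical(discretize_score(c(0, 3)), c(0, 3))
  expect_identical(discretize_score(2.5), 3)  # boundary rounds up
  expect_error(discretize_score(1, thresholds = c(2, 1, 3)),
               class = "ft_param_error")
})

test_that("consensus scores round half-values up", {
  expect_identical(consensus_score(c(1, 1, 2)), 1L)
  expect_identical(consensus_score(c(1, 2, 2)), 2L)
  expect_identical(consensus_score(rbind(c(1, 2), c(2, 3), c(0, 0))),
                   c(2L, 3L, 0L))
})
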