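#' Fit the proportional-odds cumulative-logit model
#'
#' Maximum (optionally ridge-penalized) likelihood fit of the ordinal
#' logistic regression `P(y <= j | x) = logistic(alpha_j - beta'x)` for
#' classes 0..3 and cutpoints j = 0, 1, 2. The sign convention is such
#' that a positive slope means higher feature values push towards higher
#' scores. Fitting uses damped Newton-Raphson with analytic gradient and
#' Hessian; the penalty `ridge * ||beta||^2` (intercepts unpenalized)
#' stabilizes quasi-separated features such as a binary halt indicator.
#' Non-convergence (e.g. true separation at `ridge = 0`) is reported via
#' the `converged` flag, not an error.
#'
#' @param X numeric n x p feature matrix (p may be 0 for an intercept-only
#'   model); column names become `feature_names`.
#' @param y integer scores in 0..3; every class must occur at least once.
#' @param ridge penalty weight on the slopes (default 1e-4; 0 gives the
#'   pure maximum-likelihood fit).
#' @param max_iter,tol Newton iteration cap and gradient tolerance.
#' @return An object of class `ordinal_fit`: list with `alphas` (3 ordered
#'   intercepts), `betas`, `feature_names`, `loglik` (unpenalized),
#'   `converged`, `ridge`.
#' @export
ordinal_fit <- function(X, y, ridge = 1e-4, max_iter = 200, tol = 1e-8) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop(ft_error("X and y lengths differ",
                                    "ft_param_error"))
  if (!all(y %in% 0:3)) stop(ft_error("y must contain scores in 0..3",
                                      "ft_param_error"))
  if (!all(0:3 %in% y))
    stop(ft_error("every class 0..3 must be present (cutpoints collapse otherwise)",
                  "ft_model_error"))
  if (n < p + 4) stop(ft_error("need n >= p + 4 observations",
                               "ft_model_error"))
  if (ridge < 0) stop(ft_error("ridge must be >= 0", "ft_param_error"))
  r <- .ord_fit_cpp(X, y, ridge, as.integer(max_iter), tol)
  structure(list(alphas = as.numeric(r$alphas), betas = as.numeric(r$betas),
                 feature_names = colnames(X) %||% character(0),
                 loglik = r$loglik, converged = r$converged,
                 ridge = ridge, n = n),
            class = "ordinal_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("<ordinal_fit> %d features, n = %d, loglik = %.3f%s\n",
              length(x$betas), x$n, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  cat("  alphas:", sprintf("%.3f", x$alphas), "\n")
  if (length(x$betas)) {
    nm <- if (length(x$feature_names)) x$feature_names
          else paste0("b", seq_along(x$betas))
    cat("  betas: ", paste(sprintf("%s=%.3f", nm, x$betas),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Class probabilities under a fitted ordinal model
#'
#' @param fit an [ordinal_fit()].
#' @param x a feature vector matching `fit$feature_names`, or an n x p
#'   matrix of such rows.
#' @return Numeric matrix (n x 4) of probabilities over scores 0..3; rows
#'   are non-negative and sum to 1.
#' @export
class_probs <- function(fit, x) {
  stopifnot(inherits(fit, "ordinal_fit"))
  X <- if (is.matrix(x) || is.data.frame(x)) as.matrix(x) else
    matrix(x, nrow = 1)
  if (ncol(X) != length(fit$betas))
    stop(ft_error("feature dimension mismatch", "ft_param_error"))
  if (length(fit$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), fit$feature_names))
    X <- X[, fit$feature_names, drop = FALSE]
  eta <- if (ncol(X)) drop(X %*% fit$betas) else rep(0, nrow(X))
  cum <- stats::plogis(outer(eta, fit$alphas, function(e, a) a - e))
  probs <- cbind(cum[, 1], cum[, 2] - cum[, 1], cum[, 3] - cum[, 2],
                 1 - cum[, 3])
  probs[probs < 0] <- 0
  colnames(probs) <- as.character(0:3)
  probs
}

#' Continuous score from class probabilities
#'
#' The expected score `sum_j j P(y = j)`, a continuous severity in
#' `[0, 3]` that is finer-grained than the 5-point scale.
#'
#' @param probs probability vector over scores 0..3, or a matrix of rows.
#' @return Numeric score(s) in `[0, 3]`.
#' @export
continuous_score <- function(probs) {
  P <- if (is.matrix(probs)) probs else matrix(probs, nrow = 1)
  if (ncol(P) != 4) stop(ft_error("probs must have 4 classes",
                                  "ft_param_error"))
  if (any(abs(rowSums(P) - 1) > 1e-6))
    stop(ft_error("probabilities must sum to 1 (within 1e-6)",
                  "ft_param_error"))
  drop(P %*% (0:3))
}

#' Discretize continuous scores into ordinal classes
#'
#' @param score continuous score(s).
#' @param thresholds three strictly increasing cut values (default
#'   0.5, 1.5, 2.5); a score equal to a threshold rounds up.
#' @return Integer class(es) in 0..3.
#' @export
discretize_score <- function(score, thresholds = c(0.5, 1.5, 2.5)) {
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0))
    stop(ft_error("thresholds must be 3 strictly increasing values",
                  "ft_param_error"))
  vapply(score, function(s) sum(s >= thresholds), numeric(1))
}

#' Consensus score from several raters
#'
#' The consensus is the mean of the raters' scores rounded to the nearest
#' integer, with half-values rounding up.
#'
#' @param ratings numeric matrix, one row per observation, one column per
#'   rater (or a vector for a single observation).
#' @return Integer consensus score(s).
#' @export
consensus_score <- function(ratings) {
  R <- if (is.matrix(ratings)) ratings else matrix(ratings, nrow = 1)
  as.integer(floor(rowMeans(R) + 0.5))
}

#' Predict method for ordinal fits
#'
#' @param object an [ordinal_fit()].
#' @param newdata feature matrix or vector.
#' @param type `"probs"`, `"continuous"`, or `"class"`.
#' @param thresholds discretization thresholds for `type = "class"`.
#' @param ... unused.
#' @return Probabilities, continuous scores, or discrete classes.
#' @export
predict.ordinal_fit <- function(object, newdata,
                                type = c("continuous", "probs", "class"),
                                thresholds = c(0.5, 1.5, 2.5), ...) {
  type <- match.arg(type)
  probs <- class_probs(object, newdata)
  switch(type,
         probs = probs,
         continuous = continuous_score(probs),
         class = discretize_score(continuous_score(probs), thresholds))
}
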