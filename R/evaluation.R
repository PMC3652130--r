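#' Goodman-Kruskal Gamma between two ordinal variables
#'
#' `(C - D) / (C + D)` over concordant and discordant pairs, ties
#' excluded: 1 is perfect agreement, -1 perfect inversion. Computed from
#' the cross-tabulation, so either two equal-length ordinal vectors or a
#' ready-made contingency table (rows and columns in increasing order)
#' may be supplied.
#'
#' @param a ordinal vector, or a contingency table / matrix of counts.
#' @param b ordinal vector (ignored when `a` is a table).
#' @return Gamma in `[-1, 1]`; signals a classed error
#'   (`ft_undefined_gamma`) when all pairs are tied.
#' @export
goodman_kruskal_gamma <- function(a, b = NULL) {
  tab <- if (is.matrix(a) || is.table(a)) {
    unclass(as.matrix(a))
  } else {
    if (length(a) != length(b)) stop(ft_error("length mismatch",
                                              "ft_param_error"))
    if (length(a) < 2) stop(ft_error("need at least 2 observations",
                                     "ft_param_error"))
    table(factor(a, levels = sort(unique(a))),
          factor(b, levels = sort(unique(b))))
  }
  tab <- matrix(as.numeric(tab), nrow(tab))
  R <- nrow(tab); S <- ncol(tab)
  C <- 0; D <- 0
  for (i in seq_len(R)) for (j in seq_len(S)) {
    if (tab[i, j] == 0) next
    if (i < R && j < S)
      C <- C + tab[i, j] * sum(tab[(i + 1):R, (j + 1):S])
    if (i < R && j > 1)
      D <- D + tab[i, j] * sum(tab[(i + 1):R, 1:(j - 1)])
  }
  if (C + D == 0)
    stop(ft_error("all pairs tied: Gamma undefined", "ft_undefined_gamma"))
  (C - D) / (C + D)
}

#' Sensitivity, specificity, and accuracy of a binarized ordinal task
#'
#' The four-class problem is collapsed at `cut`: the positive class is the
#' lower score group (`score <= cut`), the convention that reproduces the
#' published confusion-table metrics. Cut 0 separates score 0 from 1-3,
#' cut 1 separates 0-1 from 2-3, cut 2 separates 0-2 from 3.
#'
#' @param pred predicted ordinal scores.
#' @param truth consensus ordinal scores.
#' @param cut task cut in `{0, 1, 2}`.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`.
#' @export
binary_task_metrics <- function(pred, truth, cut) {
  if (!cut %in% 0:2) stop(ft_error("cut must be 0, 1 or 2",
                                   "ft_param_error"))
  pos_p <- pred <= cut
  pos_t <- truth <= cut
  if (!any(pos_t) || all(pos_t))
    stop(ft_error("empty positive or negative stratum",
                  "ft_undefined_metric"))
  TP <- sum(pos_p & pos_t); FN <- sum(!pos_p & pos_t)
  FP <- sum(pos_p & !pos_t); TN <- sum(!pos_p & !pos_t)
  c(sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
    accuracy = (TP + TN) / (TP + TN + FP + FN))
}

# binary metrics straight from a 4x4 contingency table (pred rows 0..3,
# truth columns 0..3)
.binary_metrics_from_table <- function(tab, cut) {
  idx <- 1:(cut + 1)
  TP <- sum(tab[idx, idx, drop = FALSE])
  FN <- sum(tab[-idx, idx, drop = FALSE])
  FP <- sum(tab[idx, -idx, drop = FALSE])
  TN <- sum(tab[-idx, -idx, drop = FALSE])
  c(sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
    accuracy = (TP + TN) / sum(tab))
}

#' ROC curve and AUC for a continuous marker
#'
#' Sweeps all observed thresholds (plus infinite endpoints), predicting
#' positive when the marker is at or above the threshold, and integrates
#' by trapezoid; with the midpoint tie convention the AUC equals the
#' Mann-Whitney concordance probability
#' `P(marker_pos > marker_neg) + 0.5 P(tie)`.
#'
#' @param continuous numeric marker values.
#' @param truth_binary logical (or 0/1) positive-class indicator.
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(continuous, truth_binary) {
  truth <- as.logical(truth_binary)
  if (!any(truth) || all(truth))
    stop(ft_error("both classes must be present", "ft_undefined_metric"))
  n_pos <- sum(truth); n_neg <- sum(!truth)
  thr <- c(Inf, sort(unique(continuous), decreasing = TRUE), -Inf)
  pts <- t(vapply(thr, function(s) {
    c(fpr = sum(continuous[!truth] >= s) / n_neg,
      tpr = sum(continuous[truth] >= s) / n_pos)
  }, numeric(2)))
  points <- data.frame(threshold = thr, fpr = pts[, "fpr"],
                       tpr = pts[, "tpr"])
  # Mann-Whitney with midrank ties (equals the trapezoid over the sweep)
  r <- rank(continuous)
  auc <- (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(points = points, auc = auc)
}

#' Nested leave-one-out evaluation of the full prediction pipeline
#'
#' For each outer fold, the held-out observation is set aside, the greedy
#' backward wrapper (whose criterion is itself a leave-one-out Gamma on
#' the training rows) selects a feature subset, the ordinal model is
#' fitted on the training rows with that subset, and the held-out
#' continuous score is predicted. The pooled predictions are discretized
#' and summarized: 4x4 contingency table, Goodman-Kruskal Gamma, per-task
#' ROC/AUC and sensitivity/specificity/accuracy, and per-feature
#' selection counts over the outer folds.
#'
#' @param X n x p feature matrix with column names.
#' @param y integer consensus scores 0..3 (all classes present, n >= 20).
#' @param ridge,thresholds model and discretization settings.
#' @param verbose print per-fold progress.
#' @return An object of class `ft_evaluation`: list with
#'   `continuous`, `discrete`, `gamma`, `table`, `tasks` (data frame with
#'   auc/sensitivity/specificity/accuracy per cut), `selection_counts`,
#'   `subsets` (per-fold selected features), `invalid_folds`.
#' @export
nested_loocv <- function(X, y, ridge = 1e-4, thresholds = c(0.5, 1.5, 2.5),
                         verbose = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 20) stop(ft_error("need at least 20 observations",
                            "ft_model_error"))
  if (!all(0:3 %in% y)) stop(ft_error("all four classes must be present",
                                      "ft_model_error"))
  cont <- rep(NA_real_, n)
  subsets <- vector("list", n)
  invalid <- integer(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      tr <- greedy_backward(X[-i, , drop = FALSE], y[-i],
                            ridge = ridge, thresholds = thresholds)
      fit <- ordinal_fit(X[-i, tr$final_subset, drop = FALSE], y[-i],
                         ridge = ridge)
      list(subset = tr$final_subset,
           pred = predict(fit, X[i, tr$final_subset, drop = FALSE],
                          type = "continuous"))
    }, ft_error = function(e) e)
    if (inherits(res, "ft_error")) {
      invalid <- c(invalid, i)
      if (verbose) message(sprintf("fold %d invalid: %s", i,
                                   conditionMessage(res)))
      next
    }
    cont[i] <- res$pred
    subsets[[i]] <- res$subset
    if (verbose) message(sprintf("fold %3d/%d: pred %.2f (truth %d), %d features",
                                 i, n, res$pred, y[i], length(res$subset)))
  }
  ok <- !is.na(cont)
  disc <- rep(NA_integer_, n)
  disc[ok] <- as.integer(discretize_score(cont[ok], thresholds))
  tab <- table(factor(disc[ok], levels = 0:3), factor(y[ok], levels = 0:3))
  gamma <- goodman_kruskal_gamma(tab)
  tasks <- do.call(rbind, lapply(0:2, function(cut) {
    roc <- roc_auc(cont[ok], y[ok] > cut)
    m <- binary_task_metrics(disc[ok], y[ok], cut)
    data.frame(task = c("0|123", "01|23", "012|3")[cut + 1], cut = cut,
               auc = roc$auc, sensitivity = m["sensitivity"],
               specificity = m["specificity"], accuracy = m["accuracy"],
               row.names = NULL)
  }))
  sel <- table(factor(unlist(subsets), levels = colnames(X)))
  structure(list(continuous = cont, discrete = disc, gamma = gamma,
                 table = tab, tasks = tasks,
                 selection_counts = as.integer(sel),
                 selection_features = colnames(X),
                 subsets = subsets, invalid_folds = invalid),
            class = "ft_evaluation")
}

#' @export
print.ft_evaluation <- function(x, ...) {
  cat(sprintf("<ft_evaluation> n = %d (%d invalid folds), Gamma = %.3f\n",
              length(x$continuous), length(x$invalid_folds), x$gamma))
  print(x$table)
  print(x$tasks, digits = 3)
  invisible(x)
}
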