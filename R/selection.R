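#' Inner cross-validated Goodman-Kruskal Gamma of a feature subset
#'
#' Leave-one-out over the provided observations: the model is fitted on
#' n-1 rows with the given feature subset, the held-out continuous score
#' is predicted and discretized, and the Gamma between the discretized
#' predictions and the observed scores is returned as the wrapper
#' criterion.
#'
#' @param X n x p feature matrix with column names.
#' @param y integer scores 0..3.
#' @param subset character vector of feature names (non-empty).
#' @param ridge slope penalty passed to the fitter.
#' @param thresholds discretization thresholds.
#' @return Gamma in `[-1, 1]`, or `NA` when the criterion is undefined
#'   (a fold's training set misses a class, or all prediction pairs tie);
#'   the search treats `NA` as `-Inf`.
#' @export
inner_cv_criterion <- function(X, y, subset, ridge = 1e-4,
                               thresholds = c(0.5, 1.5, 2.5)) {
  if (!length(subset)) stop(ft_error("subset must be non-empty",
                                     "ft_param_error"))
  X <- as.matrix(X)
  if (!all(subset %in% colnames(X)))
    stop(ft_error("unknown feature name in subset", "ft_param_error"))
  if (nrow(X) < 10) stop(ft_error("need at least 10 observations",
                                  "ft_model_error"))
  Xs <- X[, subset, drop = FALSE]
  storage.mode(Xs) <- "double"
  cont <- .ord_loocv_cpp(Xs, as.integer(y), ridge)
  if (anyNA(cont)) return(NA_real_)
  pred <- discretize_score(cont, thresholds)
  tryCatch(goodman_kruskal_gamma(pred, y),
           ft_undefined_gamma = function(e) NA_real_)
}

#' Greedy backward wrapper feature selection
#'
#' Starts from the full feature set and iteratively removes the feature
#' whose elimination yields the highest inner-CV Gamma, as long as that
#' Gamma does not fall below the current criterion (removals leaving it
#' exactly unchanged are accepted, preferring smaller models). Ties are
#' broken towards the feature earliest in the canonical order. Stops when
#' every possible removal strictly decreases the criterion or one feature
#' remains. Subsets are memoized so none is evaluated twice.
#'
#' @param X n x p feature matrix with column names.
#' @param y integer scores 0..3.
#' @param features feature names to search over (default all columns).
#' @param ridge,thresholds passed to [inner_cv_criterion()].
#' @return An object of class `selection_trace`: list with `steps` (data
#'   frame of `removed` / `criterion` per accepted removal), `final_subset`,
#'   `final_criterion`, `initial_criterion`, and `n_evaluations`.
#' @export
greedy_backward <- function(X, y, features = colnames(X), ridge = 1e-4,
                            thresholds = c(0.5, 1.5, 2.5)) {
  X <- as.matrix(X)
  if (length(features) < 2)
    stop(ft_error("need at least 2 features to search", "ft_param_error"))
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  crit <- function(subset) {
    key <- paste(sort(subset), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    v <- inner_cv_criterion(X, y, subset, ridge, thresholds)
    cache[[key]] <- v
    v
  }
  val <- function(v) if (is.na(v)) -Inf else v

  current <- features
  cur_crit <- crit(current)
  steps <- list()
  while (length(current) > 1) {
    cand <- vapply(current, function(f) val(crit(setdiff(current, f))),
                   numeric(1))
    best_val <- max(cand)
    if (best_val < val(cur_crit)) break
    # tie-break: earliest feature in the canonical order
    best_feats <- current[cand == best_val]
    remove <- best_feats[which.min(match(best_feats, features))]
    current <- setdiff(current, remove)
    cur_crit <- crit(current)
    steps[[length(steps) + 1L]] <- data.frame(removed = remove,
                                              criterion = cur_crit)
  }
  structure(list(
    steps = if (length(steps)) do.call(rbind, steps)
            else data.frame(removed = character(0), criterion = numeric(0)),
    final_subset = current,
    final_criterion = cur_crit,
    initial_criterion = crit(features),
    n_evaluations = n_eval), class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf(
    "<selection_trace> %d -> %d features, criterion %.3f -> %.3f (%d evaluations)\n",
    nrow(x$steps) + length(x$final_subset), length(x$final_subset),
    x$initial_criterion, x$final_criterion, x$n_evaluations))
  cat("  kept:", paste(x$final_subset, collapse = ", "), "\n")
  invisible(x)
}
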