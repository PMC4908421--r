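## Stratified fold assignment: shuffles within each class and deals fold ids
## round-robin, so every fold holds both classes whenever the minority class
## has at least n_folds members.
stratified_folds <- function(labels, n_folds) {
  fold_id <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold_id[idx] <- rep_len(sample(seq_len(n_folds)), length(idx))
  }
  fold_id
}

#' Repeated stratified cross-validation of a classifier zoo
#'
#' For each run, assigns stratified folds once and evaluates every
#' configuration on the same splits: any preprocessing (log transform,
#' train-fold univariate filtering) is fitted on the training folds only, the
#' classifier is trained on the training folds, and its scores for the held-out
#' fold are pooled. The merged AUC of a run is the AUC of the pooled
#' validation scores; the reported merged AUC averages over runs. Identical
#' seeds and inputs give bit-identical results.
#'
#' @param configurations list of zoo configurations
#'   (\code{\link{default_model_zoo}}).
#' @param features Numeric feature matrix (rows = patients).
#' @param labels 0/1 outcome labels.
#' @param n_runs,n_folds Cross-validation geometry (default 10 x 10-fold).
#' @param seed Integer seed driving all fold assignments and stochastic
#'   learners.
#' @param log_transform Apply \code{log1p} to the features (fixed transform,
#'   fitted nowhere).
#' @param filter_k Keep only the \code{filter_k} features with the largest
#'   absolute two-sample t statistic, computed on the training folds only;
#'   \code{NULL} disables filtering.
#' @return A \code{cv_result} list: \code{summary} data.frame (config_id,
#'   model_class, disparate, merged_auc), \code{auc_runs} matrix
#'   (configurations x runs), and \code{predictions} (per configuration, a
#'   patients x runs matrix of pooled validation scores).
#' @export
run_cv <- function(configurations, features, labels, n_runs = 10, n_folds = 10,
                   seed = 1, log_transform = FALSE, filter_k = NULL) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (n_folds < 2) stop("n_folds must be at least 2")
  x_all <- as.matrix(features)
  if (is.null(colnames(x_all)))
    colnames(x_all) <- paste0("f", seq_len(ncol(x_all)))
  if (log_transform) x_all <- log1p(pmax(x_all, 0))
  n <- nrow(x_all)
  ids <- vapply(configurations, `[[`, "", "config_id")
  auc_runs <- matrix(NA_real_, length(configurations), n_runs,
                     dimnames = list(ids, NULL))
  predictions <- lapply(configurations, function(cfg)
    matrix(NA_real_, n, n_runs))
  names(predictions) <- ids
  for (run in seq_len(n_runs)) {
    set.seed(seed + 7919L * run)
    fold_id <- stratified_folds(labels, n_folds)
    for (attempt in 1:2) {
      bad <- vapply(seq_len(n_folds), function(f)
        length(unique(labels[fold_id != f])) < 2, TRUE)
      if (!any(bad)) break
      if (attempt == 2) stop("a training fold contains a single class")
      fold_id <- stratified_folds(labels, n_folds)
    }
    for (f in seq_len(n_folds)) {
      tr <- fold_id != f
      if (!any(!tr)) next
      cols <- seq_len(ncol(x_all))
      if (!is.null(filter_k) && filter_k < ncol(x_all)) {
        tstat <- vapply(cols, function(j) {
          a <- x_all[tr & labels == 1, j]; b <- x_all[tr & labels == 0, j]
          s <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
          if (!is.finite(s) || s == 0) 0 else abs(mean(a) - mean(b)) / s
        }, 0)
        cols <- order(-tstat)[seq_len(filter_k)]
      }
      xtr <- x_all[tr, cols, drop = FALSE]
      xte <- x_all[!tr, cols, drop = FALSE]
      for (ci in seq_along(configurations)) {
        clf <- configurations[[ci]]$classifier
        set.seed(seed + 104729L * run + 1299709L * f + ci)
        model <- clf$fit(xtr, labels[tr])
        predictions[[ci]][!tr, run] <- clf$predict(model, xte)
      }
    }
    for (ci in seq_along(configurations))
      auc_runs[ci, run] <- auc_binary(predictions[[ci]][, run], labels)
  }
  summary <- data.frame(
    config_id = ids,
    model_class = vapply(configurations, `[[`, "", "model_class"),
    disparate = vapply(configurations, `[[`, TRUE, "disparate"),
    merged_auc = rowMeans(auc_runs),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, auc_runs = auc_runs,
                 predictions = predictions, labels = labels,
                 n_runs = n_runs, n_folds = n_folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cross-validation:", x$n_runs, "runs x", x$n_folds, "folds\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
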