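# Feature-level fusion and the evaluation protocol: stratified 70/30 split,
# stratified 10-fold cross-validation on the calibration part, accuracy,
# probabilistic RMSE and confusion matrices.

#' Feature-level fusion of two feature tables
#'
#' Column-wise concatenation of the feature blocks of two modalities
#' measured on the same samples (e.g. 54 e-nose + 52 image features ->
#' 106 fused features). Row order is preserved.
#'
#' @param a,b Feature tables with identical `sample_id` and `grade` columns
#'   (same samples, same order) and disjoint feature names.
#' @return The fused feature table.
#' @export
fuse_features <- function(a, b) {
  check_feature_table(a, "a")
  check_feature_table(b, "b")
  if (!identical(a$sample_id, b$sample_id) || !identical(a$grade, b$grade)) {
    abort("`a` and `b` must hold the same samples in the same order.")
  }
  dup <- intersect(feature_names(a), feature_names(b))
  if (length(dup)) {
    abort(sprintf("Duplicate feature names across tables: %s",
                  paste(dup, collapse = ", ")))
  }
  out <- bind_cols(a, b[feature_names(b)])
  check_feature_table(out)
  out
}

#' Probabilistic root mean squared error
#'
#' `sqrt( sum_i sum_c (p_hat[i, c] - onehot[i, c])^2 / (n * C) )`: the RMSE
#' between predicted class-probability vectors and one-hot true labels,
#' averaged over samples times classes. Ranges from 0 (perfect, confident
#' predictions) to `sqrt(2)`; uniform three-class predictions give
#' `sqrt(2/9) ~ 0.4714` whatever the labels.
#'
#' @param prob Matrix or data frame of class probabilities, columns named by
#'   class.
#' @param truth Character vector of true labels.
#' @return The RMSE, a scalar in `[0, sqrt(2)]`.
#' @export
probabilistic_rmse <- function(prob, truth) {
  p <- as.matrix(prob)
  if (nrow(p) != length(truth)) abort("Row count must match `truth` length.")
  onehot <- outer(truth, colnames(p), "==") * 1
  sqrt(sum((p - onehot)^2) / (nrow(p) * ncol(p)))
}

#' Confusion matrix of predictions
#'
#' @param truth,predicted Character vectors of equal length.
#' @param classes Class levels (default: sorted union).
#' @return A `length(classes)` square matrix of counts, rows = truth,
#'   columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  classes <- classes %||% sort(union(truth, predicted))
  table(factor(truth, classes), factor(predicted, classes)) |>
    unclass()
}

# stratified split: per class, floor(frac * n) into the first part
stratified_split <- function(grades, frac = 0.7, seed = 1L) {
  set.seed(seed)
  first <- unlist(lapply(sort(unique(grades)), function(cl) {
    idx <- which(grades == cl)
    sample(idx, floor(frac * length(idx)))
  }))
  list(calibration = sort(first),
       evaluation = sort(setdiff(seq_along(grades), first)))
}

# stratified k-fold assignment
stratified_folds <- function(grades, k, seed = 1L) {
  set.seed(seed)
  fold <- integer(length(grades))
  for (cl in sort(unique(grades))) {
    idx <- sample(which(grades == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Evaluate a classifier under the study protocol
#'
#' Splits the samples into a stratified 70% calibration / 30% evaluation
#' partition (per class, `floor(0.7 * n)` samples go to calibration; with
#' 15 samples per grade this gives 10 calibration and 5 evaluation samples
#' per grade). Calibration metrics are computed from pooled out-of-fold
#' predictions of a stratified 10-fold cross-validation on the calibration
#' part; evaluation metrics come from a model fitted on the full
#' calibration part and applied to the held-out 30%.
#'
#' @param spec A [classifier_spec()].
#' @param table A feature table with at least 2 classes.
#' @param split_seed Seed controlling the split and fold assignment.
#' @param cv_folds Cross-validation folds (default 10; reduced with a
#'   warning when a class has fewer calibration samples than folds).
#' @return An `evaluation_report` with calibration and evaluation accuracy
#'   (percent), probabilistic RMSE, confusion matrices, per-fold accuracy,
#'   and the split indices.
#' @export
evaluate_classifier <- function(spec, table, split_seed = 1L, cv_folds = 10L) {
  stopifnot(inherits(spec, "classifier_spec"))
  check_feature_table(table)
  classes <- sort(unique(table$grade))
  if (length(classes) < 2) abort("Need at least 2 classes.")

  split <- stratified_split(table$grade, 0.7, seed = split_seed)
  cal <- table[split$calibration, ]
  eva <- table[split$evaluation, ]

  min_class <- min(table(cal$grade))
  k <- cv_folds
  if (min_class < k) {
    k <- max(2L, min_class)
    warn(sprintf("Class with %d calibration samples; using %d-fold CV.",
                 min_class, k))
  }
  fold <- stratified_folds(cal$grade, k, seed = split_seed + 1L)

  prob_cv <- matrix(NA_real_, nrow(cal), length(classes),
                    dimnames = list(NULL, classes))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- cal[fold != f, ]
    te <- cal[fold == f, ]
    model <- train_grader(spec, tr)
    pr <- predict_proba(model, te)
    prob_cv[fold == f, ] <- as.matrix(pr[classes])
    fold_acc[f] <- mean(pr$.pred_class == te$grade)
  }
  pred_cv <- classes[max.col(prob_cv, ties.method = "first")]

  final <- train_grader(spec, cal)
  pr_ev <- predict_proba(final, eva)
  prob_ev <- as.matrix(pr_ev[classes])

  report <- list(
    spec = spec,
    classes = classes,
    calibration = list(
      accuracy = 100 * mean(pred_cv == cal$grade),
      rmse = probabilistic_rmse(prob_cv, cal$grade),
      confusion = confusion_matrix(cal$grade, pred_cv, classes),
      fold_accuracy = fold_acc,
      n = nrow(cal)),
    evaluation = list(
      accuracy = 100 * mean(pr_ev$.pred_class == eva$grade),
      rmse = probabilistic_rmse(prob_ev, eva$grade),
      confusion = confusion_matrix(eva$grade, pr_ev$.pred_class, classes),
      n = nrow(eva)),
    split = split,
    cv_folds = k,
    split_seed = split_seed)
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", x$spec$family, "\n")
  cat(sprintf("  calibration (%d-fold CV, n=%d): accuracy %.2f%%, RMSE %.4f\n",
              x$cv_folds, x$calibration$n,
              x$calibration$accuracy, x$calibration$rmse))
  cat(sprintf("  evaluation (n=%d): accuracy %.2f%%, RMSE %.4f\n",
              x$evaluation$n, x$evaluation$accuracy, x$evaluation$rmse))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return Tibble with one row per phase (`calibration`, `evaluation`) and
#'   columns `phase`, `n`, `accuracy`, `rmse`.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  tibble(phase = c("calibration", "evaluation"),
         n = c(x$calibration$n, x$evaluation$n),
         accuracy = c(x$calibration$accuracy, x$evaluation$accuracy),
         rmse = c(x$calibration$rmse, x$evaluation$rmse))
}

#' One-row summary of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return One-row tibble with family, kernel/search, fold count and both
#'   phases' accuracy and RMSE.
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(family = x$spec$family,
         variant = switch(x$spec$family,
                          svm = x$spec$kernel,
                          bayes_net = x$spec$bn_search,
                          tree = x$spec$pruning),
         cv_folds = x$cv_folds,
         cal_accuracy = x$calibration$accuracy,
         cal_rmse = x$calibration$rmse,
         eval_accuracy = x$evaluation$accuracy,
         eval_rmse = x$evaluation$rmse)
}

#' Plot an evaluation report's confusion matrix
#'
#' @param object An `evaluation_report`.
#' @param phase `"calibration"` or `"evaluation"`.
#' @param ... Unused.
#' @return A ggplot heatmap of the confusion matrix.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object,
                                       phase = c("calibration", "evaluation"),
                                       ...) {
  phase <- match.arg(phase)
  cm <- object[[phase]]$confusion
  df <- as_tibble(as.table(cm), .name_repair = "minimal")
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = paste("Confusion matrix,", phase),
                  x = "Predicted grade", y = "True grade") +
    ggplot2::theme_minimal()
}
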