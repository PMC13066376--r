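# Evaluation: confusion matrix, classification metrics, stratified model
# comparison, and the paired t-test used to compare classifier accuracies.

#' Confusion matrix
#'
#' Tallies predictions against truth. Rows are the actual labels, columns the
#' predicted labels (this convention is fixed; serialisers label the axes).
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param class_order Class codes defining row/column order; defaults to the
#'   sorted union of observed labels.
#' @return An N x N integer matrix of class `confusion_matrix` with
#'   `dimnames = list(actual, predicted)`.
#' @export
confusion_matrix <- function(y_true, y_pred,
                             class_order = sort(unique(c(y_true, y_pred)))) {
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  unknown <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(unknown))
    stop("label(s) not in class_order: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cm <- table(actual = factor(y_true, levels = class_order),
              predicted = factor(y_pred, levels = class_order))
  cm <- unclass(cm)
  storage.mode(cm) <- "integer"
  class(cm) <- c("confusion_matrix", "matrix")
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Derives, per class in a one-vs-rest sense, true/false positives and
#' negatives and from them precision `Tp/(Tp+Fp)`, recall `Tp/(Tp+Fn)` and
#' F1-score `2*P*R/(P+R)`; overall accuracy is the diagonal fraction
#' `trace/total`. Classes never predicted get precision 0 (with a warning);
#' classes with no positive instances get recall 0.
#'
#' @param cm A [confusion_matrix()].
#' @param average `"macro"` (unweighted class mean, the default) or
#'   `"weighted"` (support-weighted mean) for the summary precision, recall
#'   and F1.
#' @return A list of class `metrics_report`: `accuracy`, `precision`,
#'   `recall`, `f1` (summary values), `per_class` (data.frame with support),
#'   `average`.
#' @export
classification_metrics <- function(cm, average = c("macro", "weighted")) {
  average <- match.arg(average)
  if (!inherits(cm, "confusion_matrix")) {
    cm <- as.matrix(cm)
    if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square", call. = FALSE)
    class(cm) <- c("confusion_matrix", "matrix")
  }
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  support <- rowSums(cm)
  if (any(tp + fp == 0))
    warning("class(es) never predicted: ",
            paste(rownames(cm)[tp + fp == 0], collapse = ", "),
            "; precision set to 0")
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- if (average == "macro") rep(1 / nrow(cm), nrow(cm)) else support / total
  structure(
    list(accuracy = sum(tp) / total,
         precision = sum(w * precision), recall = sum(w * recall),
         f1 = sum(w * f1),
         per_class = data.frame(class = rownames(cm), support = support,
                                precision = precision, recall = recall,
                                f1 = f1, row.names = NULL),
         average = average),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | %s precision %.4f recall %.4f F1 %.4f\n",
              x$accuracy, x$average, x$precision, x$recall, x$f1))
  print(x$per_class, digits = 4)
  invisible(x)
}

#' Paired t-test between two sets of per-subject scores
#'
#' Two-tailed paired Student t-test on matched per-subject accuracies:
#' `t = mean(d) / (sd(d)/sqrt(n))` with `d = a - b`, sample standard
#' deviation (denominator n-1) and n-1 degrees of freedom.
#'
#' @param acc_a,acc_b Equal-length numeric vectors of paired scores.
#' @return A list of class `t_test_result`: `t_statistic`, `p_value`, `df`,
#'   `mean_difference`, `n_pairs`.
#' @examples
#' paired_t_test(c(86.80, 89.20, 87.90, 78.40),
#'               c(85.20, 87.30, 87.15, 76.60))
#' @export
paired_t_test <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b))
    stop("paired samples must have equal length", call. = FALSE)
  n <- length(acc_a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- acc_a - acc_b
  if (sd(d) == 0)
    stop("degenerate variance: all paired differences are identical",
         call. = FALSE)
  ht <- t.test(acc_a, acc_b, paired = TRUE, alternative = "two.sided")
  structure(list(t_statistic = unname(ht$statistic),
                 p_value = ht$p.value, df = unname(ht$parameter),
                 mean_difference = unname(ht$estimate), n_pairs = n),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("paired t-test: t = %.4f, df = %d, p = %.4f (mean diff %.4f)\n",
              x$t_statistic, x$df, x$p_value, x$mean_difference))
  invisible(x)
}

#' Stratified train/test split
#'
#' Splits row indices class by class so both parts contain every class.
#'
#' @param labels Class label vector.
#' @param split Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, split = 0.7, seed = 1L) {
  if (split <= 0 || split >= 1)
    stop("`split` must lie strictly in (0, 1)", call. = FALSE)
  idx <- with_private_seed(seed, {
    unlist(lapply(split(seq_along(labels), labels), function(rows) {
      n_tr <- round(length(rows) * split)
      if (n_tr == 0L || n_tr == length(rows))
        stop("stratification error: class with rows only in one split",
             call. = FALSE)
      sample(rows, n_tr)
    }), use.names = FALSE)
  })
  list(train = sort(idx), test = setdiff(seq_along(labels), idx))
}

subset_features <- function(fm, rows) {
  structure(list(values = fm$values[rows, , drop = FALSE],
                 labels = fm$labels[rows], feature_names = fm$feature_names,
                 params = fm$params, subject_id = fm$subject_id),
            class = "feature_matrix")
}

#' Compare MEET against baseline classifiers on a shared split
#'
#' Fits each requested model on the same stratified training fraction and
#' evaluates all of them on the identical held-out remainder.
#'
#' @param features A [featurize()] result.
#' @param models Character vector among `"meet"` and `"et"`; MEET and its
#'   base extra-trees ensemble are always included.
#' @param split Training fraction (default 0.7).
#' @param seed Seed governing the split and all model fits.
#' @param a Classes per expert for MEET.
#' @param control A [meet_control()].
#' @param average Metric averaging passed to [classification_metrics()].
#' @return A list of class `model_comparison`: `table` (one row per model:
#'   accuracy, precision, recall, f1), `reports` (named list of
#'   `metrics_report`s), `split` indices, `seed`.
#' @export
compare_models <- function(features, models = c("meet", "et"), split = 0.7,
                           seed = 1L, a = 2L, control = meet_control(),
                           average = "macro") {
  models <- union(c("meet", "et"), models)
  fd <- coerce_features(features)
  parts <- stratified_split(fd$y, split, seed)
  train <- subset_features(features, parts$train)
  test <- subset_features(features, parts$test)
  reports <- list()
  preds <- list()
  for (m in models) {
    fit <- switch(m,
      meet = meet_fit(train, a = a, control = control, seed = seed),
      et = et_fit(train, control = control, seed = seed),
      stop("unknown model spec: ", m, call. = FALSE))
    preds[[m]] <- predict(fit, test)
    cm <- confusion_matrix(test$labels, preds[[m]],
                           class_order = sort(unique(fd$y)))
    reports[[m]] <- classification_metrics(cm, average = average)
  }
  tab <- do.call(rbind, lapply(names(reports), function(m) {
    r <- reports[[m]]
    data.frame(model = m, accuracy = r$accuracy, precision = r$precision,
               recall = r$recall, f1 = r$f1)
  }))
  structure(list(table = tab, reports = reports, split = parts, seed = seed),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}
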