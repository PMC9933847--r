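# evaluate-with-seed helper: runs code under a temporary RNG state
with_rng <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

class_levels <- c("P", "LP", "WN", "LN", "RN")

#' Per-class evaluation report from truth and prediction
#'
#' Builds the 5x5 confusion matrix (rows = truth, columns = prediction)
#' and per-class precision, recall and F1, plus macro and
#' support-weighted averages and overall accuracy. Undefined ratios
#' (empty class or empty prediction column) are reported as 0.
#'
#' @param truth,pred factors (or characters) over the five class levels.
#' @return object of class `eval_report`: list with `confusion`,
#'   `per_class` (data.frame), `macro_avg`, `weighted_avg`, `accuracy`,
#'   `n`.
#' @export
eval_report <- function(truth, pred) {
  truth <- factor(truth, levels = class_levels)
  pred <- factor(pred, levels = class_levels)
  stopifnot(length(truth) == length(pred), !anyNA(truth), !anyNA(pred))
  cm <- table(truth = truth, pred = pred)
  tp <- diag(cm)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, colSums(cm))
  recall <- safe_div(tp, rowSums(cm))
  f1 <- safe_div(2 * precision * recall, precision + recall)
  support <- rowSums(cm)
  per_class <- data.frame(
    label = class_levels, precision = as.numeric(precision),
    recall = as.numeric(recall), f1 = as.numeric(f1),
    support = as.integer(support)
  )
  w <- support / sum(support)
  structure(
    list(
      confusion = unclass(cm),
      per_class = per_class,
      macro_avg = c(precision = mean(precision), recall = mean(recall),
                    f1 = mean(f1)),
      weighted_avg = c(precision = sum(w * precision),
                       recall = sum(w * recall), f1 = sum(w * f1)),
      accuracy = sum(tp) / sum(cm),
      n = sum(cm)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d accuracy=%.3f macro-F1=%.3f\n",
              x$n, x$accuracy, x$macro_avg[["f1"]]))
  print(x$per_class, row.names = FALSE, digits = 3)
  invisible(x)
}

fit_and_predict <- function(X_train, y_train, X_test,
                            model = c("rf", "svm", "mlp")) {
  model <- match.arg(model)
  y_train <- factor(y_train, levels = class_levels)
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  pred <- switch(model,
    rf = {
      fit <- randomForest::randomForest(x = X_train, y = y_train)
      predict(fit, X_test)
    },
    svm = {
      fit <- e1071::svm(x = X_train, y = y_train)
      predict(fit, X_test)
    },
    mlp = {
      fit <- nnet::nnet(
        x = X_train, y = nnet::class.ind(y_train),
        size = 16, decay = 1e-4, maxit = 300, softmax = TRUE, trace = FALSE
      )
      cls <- predict(fit, X_test, type = "class")
      factor(cls, levels = class_levels)
    }
  )
  factor(as.character(pred), levels = class_levels)
}

stratified_test_idx <- function(y, test_fraction) {
  idx <- integer(0)
  for (lv in levels(y)) {
    members <- which(y == lv)
    if (length(members) < 2L) {
      stop(sprintf("class %s has < 2 members; cannot stratify", lv))
    }
    n_test <- min(length(members) - 1L,
                  max(1L, round(test_fraction * length(members))))
    idx <- c(idx, sample(members, n_test))
  }
  sort(idx)
}

#' Train a classifier on the assigned labels and evaluate held-out data
#'
#' Stratified train/test split preserving class proportions (every class
#' keeps at least one sample on each side), then a classifier fit on the
#' training split and scored on the test split.
#'
#' @param X a `feature_matrix`.
#' @param labels a `label_assignment` or a named factor over the rows of
#'   `X` with levels P/LP/WN/LN/RN.
#' @param model `"rf"` (random forest), `"svm"` or `"mlp"`.
#' @param test_fraction held-out fraction (default 0.3).
#' @param seed RNG seed controlling the split and the stochastic fits.
#' @return an `eval_report` with the test indices attached as attribute
#'   `test_idx`.
#' @export
train_eval <- function(X, labels, model = c("rf", "svm", "mlp"),
                       test_fraction = 0.3, seed = 1L) {
  model <- match.arg(model)
  if (inherits(labels, "label_assignment")) labels <- labels$labels
  y <- factor(as.character(labels[rownames(X)]), levels = class_levels)
  stopifnot(!anyNA(y))
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie in (0, 1)")
  }
  with_rng(seed, {
    test <- stratified_test_idx(y, test_fraction)
    train <- setdiff(seq_along(y), test)
    pred <- fit_and_predict(X[train, , drop = FALSE], y[train],
                            X[test, , drop = FALSE], model)
    rep <- eval_report(y[test], pred)
    attr(rep, "test_idx") <- test
    rep
  })
}

#' Stratified k-fold cross-validation of the label classifier
#'
#' @inheritParams train_eval
#' @param k number of folds (default 5).
#' @return list of class `cv_report`: `folds` (list of `eval_report`),
#'   `summary` (data.frame of pooled mean and sd of accuracy, macro and
#'   weighted precision/recall/F1 over folds).
#' @export
cross_validate <- function(X, labels, model = c("rf", "svm", "mlp"),
                           k = 5L, seed = 1L) {
  model <- match.arg(model)
  if (inherits(labels, "label_assignment")) labels <- labels$labels
  y <- factor(as.character(labels[rownames(X)]), levels = class_levels)
  stopifnot(!anyNA(y))
  if (k < 2L) stop("k must be >= 2")
  with_rng(seed, {
    fold_of <- integer(length(y))
    for (lv in levels(y)) {
      members <- which(y == lv)
      if (length(members) < 2L) {
        stop(sprintf("class %s has < 2 members; cannot stratify", lv))
      }
      fold_of[sample(members)] <- rep_len(seq_len(k), length(members))
    }
    reports <- lapply(seq_len(k), function(f) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      pred <- fit_and_predict(X[train, , drop = FALSE], y[train],
                              X[test, , drop = FALSE], model)
      eval_report(y[test], pred)
    })
    metric_rows <- vapply(reports, function(r) {
      c(accuracy = r$accuracy,
        macro_precision = r$macro_avg[["precision"]],
        macro_recall = r$macro_avg[["recall"]],
        macro_f1 = r$macro_avg[["f1"]],
        weighted_precision = r$weighted_avg[["precision"]],
        weighted_recall = r$weighted_avg[["recall"]],
        weighted_f1 = r$weighted_avg[["f1"]])
    }, numeric(7))
    summary <- data.frame(
      metric = rownames(metric_rows),
      mean = apply(metric_rows, 1, mean),
      sd = apply(metric_rows, 1, sd),
      row.names = NULL
    )
    structure(list(folds = reports, summary = summary, k = k),
              class = "cv_report")
  })
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds\n", x$k))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
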