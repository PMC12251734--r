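# Movement-correctness classification: RBF-kernel SVM on the ten windowed
# angle features, balanced class weights, features standardised on the
# training set, evaluated by leave-one-out cross-validation.

#' Balanced class weights
#'
#' Weights inversely proportional to class frequencies,
#' `w_c = n / (n_classes * n_c)`, so rarer classes weigh more.
#'
#' @param y Factor (or coercible) of class labels.
#' @return Named numeric vector of weights.
#' @export
balanced_class_weights <- function(y) {
  y <- factor(y)
  tab <- table(y)
  w <- length(y) / (nlevels(y) * as.numeric(tab))
  names(w) <- names(tab)
  w
}

.standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

.standardize_apply <- function(x, std) {
  scale(x, center = std$center, scale = std$scale)
}

#' Fit the movement-correctness SVM
#'
#' Standardises the features (training-set mean/SD), then fits a C-SVM with
#' RBF kernel, `cost = 1`, `gamma = 1 / (n_features * var)` where `var` is
#' the overall variance of the standardised training matrix, and balanced
#' class weights. Deterministic given fixed inputs.
#'
#' @param table A `feature_table` (or data.frame) with the ten feature
#'   columns and a binary `label` column (correct = 1, incorrect = 0).
#' @param cost SVM cost parameter.
#' @param gamma RBF width; default as above.
#' @param feature_cols Feature columns to use; default [feature_columns()].
#' @return An object of class `movement_svm` with `print`, `summary` and
#'   `predict` methods.
#' @export
fit_movement_svm <- function(table, cost = 1, gamma = NULL,
                             feature_cols = feature_columns()) {
  x <- as.matrix(table[, feature_cols, drop = FALSE])
  y <- factor(table$label, levels = c(0, 1))
  tab <- table(y)
  if (any(tab == 0)) stop("training data contains a single class")
  if (any(tab < 2)) stop("need at least 2 rows per class")
  std <- .standardize_fit(x)
  xs <- .standardize_apply(x, std)
  if (is.null(gamma)) {
    v <- mean((xs - mean(xs))^2)
    gamma <- 1 / (ncol(xs) * v)
  }
  w <- balanced_class_weights(y)
  fit <- e1071::svm(x = xs, y = y, kernel = "radial", cost = cost,
                    gamma = gamma, class.weights = w, scale = FALSE)
  structure(list(model = fit, std = std, gamma = gamma, cost = cost,
                 class_weights = w, feature_cols = feature_cols,
                 n = nrow(x), supports = as.vector(tab),
                 call = match.call()),
            class = "movement_svm")
}

#' @export
print.movement_svm <- function(x, ...) {
  cat("Movement-correctness SVM (RBF kernel)\n")
  cat("  n =", x$n, " features =", length(x$feature_cols),
      " cost =", x$cost, " gamma =", signif(x$gamma, 4), "\n")
  cat("  class weights:",
      paste(names(x$class_weights), signif(x$class_weights, 4),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.movement_svm <- function(object, ...) {
  print(object)
  cat("  support vectors:", object$model$tot.nSV, "\n")
  invisible(object)
}

#' Predict movement correctness
#'
#' @param object A `movement_svm`.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... Unused.
#' @return Factor of predicted labels (levels `0`, `1`).
#' @export
predict.movement_svm <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  xs <- .standardize_apply(x, object$std)
  stats::predict(object$model, xs)
}

# Per-class precision/recall/F1/support with macro and support-weighted
# averages; NA predictions (failed folds) count as incorrect.
make_cv_report <- function(truth, pred, failed_folds = integer()) {
  truth <- factor(truth, levels = c(0, 1))
  lv <- levels(truth)
  per <- lapply(lv, function(cl) {
    tp <- sum(pred == cl & truth == cl, na.rm = TRUE)
    fp <- sum(pred == cl & truth != cl, na.rm = TRUE)
    fn <- sum(truth == cl, na.rm = TRUE) - tp
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    c(precision = precision, recall = recall, f1 = f1,
      support = sum(truth == cl))
  })
  per <- do.call(rbind, per)
  rownames(per) <- lv
  n <- length(truth)
  acc <- sum(pred == truth, na.rm = TRUE) / n
  macro <- colMeans(per[, c("precision", "recall", "f1"), drop = FALSE])
  wts <- per[, "support"] / n
  weighted <- colSums(per[, c("precision", "recall", "f1"), drop = FALSE] * wts)
  structure(list(accuracy = acc, per_class = as.data.frame(per),
                 macro_avg = macro, weighted_avg = weighted, n_total = n,
                 failed_folds = failed_folds),
            class = "cv_report")
}

#' Leave-one-out cross-validation of the movement SVM
#'
#' For each held-out unit the model (including standardisation) is refit on
#' the remainder and the unit predicted; predictions are aggregated into one
#' report. `granularity = "sample"` holds out one feature-window row at a
#' time (the protocol behind the published accuracies; windows of one
#' participant appear on both sides of a split). `granularity =
#' "participant"` holds out all rows of one participant, quantifying the
#' participant-leakage optimism of the sample-level protocol.
#'
#' @param table A `feature_table` with `label` (and `participant_id` for
#'   participant granularity).
#' @param granularity `"sample"` or `"participant"`.
#' @param ... Passed to [fit_movement_svm()].
#' @return A `cv_report`: accuracy, per-class precision/recall/F1/support,
#'   macro and weighted averages. Folds whose training data degenerates (a
#'   single class, or fewer than two rows of one) are recorded in
#'   `failed_folds` and scored as errors.
#' @export
loocv <- function(table, granularity = c("sample", "participant"), ...) {
  granularity <- match.arg(granularity)
  if (nrow(table) < 3) stop("need at least 3 rows for LOOCV")
  units <- if (granularity == "sample") seq_len(nrow(table))
           else unique(table$participant_id)
  truth <- factor(table$label, levels = c(0, 1))
  pred <- factor(rep(NA_character_, nrow(table)), levels = c(0, 1))
  failed <- integer()
  for (u in seq_along(units)) {
    hold <- if (granularity == "sample") units[u]
            else which(table$participant_id == units[u])
    train <- table[-hold, , drop = FALSE]
    fold_pred <- tryCatch(
      predict(fit_movement_svm(train, ...), table[hold, , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(fold_pred)) {
      failed <- c(failed, u)
      next
    }
    pred[hold] <- fold_pred
  }
  make_cv_report(truth, pred, failed_folds = failed)
}

#' Hold-out evaluation
#'
#' Fits on `train` and reports metrics on `test`. Warns when participants
#' overlap between the two tables (disjoint participant sets are
#' recommended for an honest estimate).
#'
#' @param train,test `feature_table`s with `label` columns.
#' @param ... Passed to [fit_movement_svm()].
#' @return A `cv_report` on the test predictions.
#' @export
holdout_eval <- function(train, test, ...) {
  if (!nrow(test)) stop("empty test set")
  if ("participant_id" %in% names(train) && "participant_id" %in% names(test)) {
    overlap <- intersect(unique(train$participant_id), unique(test$participant_id))
    if (length(overlap))
      warning("participant(s) present in both train and test: ",
              paste(overlap, collapse = ", "))
  }
  fit <- fit_movement_svm(train, ...)
  make_cv_report(factor(test$label, levels = c(0, 1)), predict(fit, test))
}

#' Format a CV report as a classification-report table
#'
#' Rows `0`, `1`, `accuracy`, `macro avg`, `weighted avg`; per-class
#' percentages rounded to the nearest integer, overall accuracy carried at
#' two decimals in the header attribute.
#'
#' @param report A `cv_report`.
#' @return data.frame of formatted cells with an `accuracy_label` attribute
#'   (e.g. `"96.26%"`).
#' @export
report_to_table <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  pc <- function(v) paste0(round(v * 100), "%")
  per <- report$per_class
  tab <- data.frame(
    precision = c(pc(per$precision), "", pc(report$macro_avg["precision"]),
                  pc(report$weighted_avg["precision"])),
    recall = c(pc(per$recall), "", pc(report$macro_avg["recall"]),
               pc(report$weighted_avg["recall"])),
    f1_score = c(pc(per$f1), pc(report$accuracy),
                 pc(report$macro_avg["f1"]), pc(report$weighted_avg["f1"])),
    support = as.character(c(per$support, report$n_total, report$n_total,
                             report$n_total)),
    row.names = c(rownames(per), "accuracy", "macro avg", "weighted avg"),
    stringsAsFactors = FALSE
  )
  attr(tab, "accuracy_label") <- sprintf("%.2f%%", report$accuracy * 100)
  tab
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Average accuracy:", sprintf("%.2f%%", x$accuracy * 100), "\n")
  print(report_to_table(x))
  if (length(x$failed_folds))
    cat("failed folds (single-class training data):",
        length(x$failed_folds), "\n")
  invisible(x)
}
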