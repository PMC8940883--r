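# Evaluation metrics: confusion matrix in fixed class order, one-vs-rest
# sensitivity/specificity, ROC by threshold sweep with trapezoidal AUC
# (tie handling equivalent to rank-midpoint pair counting), and
# fold-averaged ROC curves on a fixed specificity grid.

#' Confusion matrix in fixed class order
#'
#' @param true,predicted label vectors over [tissue_classes()] (rows = true,
#'   columns = predicted).
#' @return integer 3 x 3 matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(true, predicted) {
  if (length(true) != length(predicted))
    oct_error("invalid_parameter", "label vectors differ in length")
  t <- as_tissue_label(true)
  p <- as_tissue_label(predicted)
  m <- unclass(table(true = t, predicted = p))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Overall accuracy of a confusion matrix
#' @param cm a [confusion_matrix()].
#' @return trace / total.
#' @export
cm_accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' One-vs-rest sensitivity and specificity
#'
#' Collapses the 3 x 3 matrix to the 2 x 2 one-vs-rest table of `class`:
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP). A class with
#' no true instances yields `NA` sensitivity with a warning (flagged, not
#' silently zero).
#'
#' @param cm a [confusion_matrix()].
#' @param class one of [tissue_classes()].
#' @return named list `sensitivity`, `specificity`.
#' @export
sensitivity_specificity <- function(cm, class) {
  class <- as.character(class)
  if (!class %in% rownames(cm))
    oct_error("label_error", "unknown class %s", class)
  tp <- cm[class, class]
  fn <- sum(cm[class, ]) - tp
  fp <- sum(cm[, class]) - tp
  tn <- sum(cm) - tp - fn - fp
  sens <- if (tp + fn == 0) {
    log_event("warning", "evaluate",
              "sensitivity undefined: no true %s instances", class)
    NA_real_
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  list(sensitivity = sens, specificity = spec)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (positive call when
#' `score >= threshold`) and integrates the curve by the trapezoid rule, so
#' tied scores earn the rank-midpoint credit: the AUC equals the
#' pair-counting statistic `(#\{pos > neg\} + #\{ties\}/2) / (n_pos n_neg)`.
#' Both curve endpoints, (sensitivity 0, specificity 1) and (1, 0), are
#' always present.
#'
#' @param scores scores (e.g. predicted class probability) in `[0, 1]`.
#' @param true true labels.
#' @param class the positive class.
#' @return object of class `roc_result`: thresholds, sensitivity,
#'   specificity, auc.
#' @export
roc_auc_ovr <- function(scores, true, class) {
  pos <- as_tissue_label(true) == class
  if (!any(pos) || all(pos))
    oct_error("undefined_auc_error",
              "AUC undefined: need both positive and negative instances of %s",
              class)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- spec <- numeric(length(thr))
  npos <- sum(pos); nneg <- sum(!pos)
  for (i in seq_along(thr)) {
    call_pos <- scores >= thr[i]
    sens[i] <- sum(call_pos & pos) / npos
    spec[i] <- sum(!call_pos & !pos) / nneg
  }
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (head(sens, -1) + sens[-1]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, class = as.character(class)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s vs rest: AUC %.4f (%d thresholds)\n",
              x$class, x$auc, length(x$thresholds)))
  invisible(x)
}

#' Average ROC curves across folds
#'
#' Interpolates each fold's sensitivity onto a fixed specificity grid
#' (linear interpolation, 101 points by default) and reports the pointwise
#' mean and standard deviation band together with mean AUC +/- sd.
#'
#' @param rocs list of [roc_auc_ovr()] results.
#' @param grid specificity grid.
#' @return list: specificity, mean_sensitivity, sd_sensitivity, auc_mean,
#'   auc_sd, n_folds.
#' @export
average_roc_over_folds <- function(rocs, grid = seq(0, 1, by = 0.01)) {
  if (length(rocs) == 0)
    oct_error("invalid_parameter", "need at least one ROC curve")
  sens_mat <- vapply(rocs, function(r) {
    approx(r$specificity, r$sensitivity, xout = grid, ties = max,
           rule = 2)$y
  }, numeric(length(grid)))
  sens_mat <- matrix(sens_mat, nrow = length(grid))
  aucs <- vapply(rocs, function(r) r$auc, 1)
  one <- length(rocs) == 1
  list(specificity = grid,
       mean_sensitivity = rowMeans(sens_mat),
       sd_sensitivity = if (one) rep(0, length(grid))
                        else apply(sens_mat, 1, sd),
       auc_mean = mean(aucs),
       auc_sd = if (one) 0 else sd(aucs),
       n_folds = length(rocs))
}

#' Evaluate a model on a frame set
#'
#' Predictions use the argmax probability rule (ties broken by class
#' order NOR < GBM < PCNSL).
#'
#' @param model an `oct_model`.
#' @param fs a [frame_set()].
#' @return object of class `eval_report`: probabilities, predicted labels,
#'   confusion matrix, accuracy, macro (balanced) accuracy, per-class
#'   sensitivity/specificity, one-vs-rest ROC per class.
#' @export
evaluate_frames <- function(model, fs) {
  probs <- predict_proba(model, fs)
  pred <- tissue_classes()[max.col(probs, ties.method = "first")]
  cm <- confusion_matrix(as.character(fs$labels), pred)
  per_class <- lapply(stats::setNames(nm = tissue_classes()), function(cl)
    sensitivity_specificity(cm, cl))
  present <- tissue_classes()[tissue_classes() %in% unique(fs$labels) &
                                vapply(tissue_classes(), function(cl)
                                  any(fs$labels != cl), TRUE)]
  rocs <- lapply(stats::setNames(nm = present), function(cl)
    roc_auc_ovr(probs[, cl], as.character(fs$labels), cl))
  recalls <- vapply(per_class, function(x) x$sensitivity, 1)
  structure(list(probs = probs, predicted = pred,
                 true = as.character(fs$labels), confusion = cm,
                 accuracy = cm_accuracy(cm),
                 macro_accuracy = mean(recalls, na.rm = TRUE),
                 per_class = per_class, roc = rocs),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy %.3f, macro accuracy %.3f\n",
              sum(x$confusion), x$accuracy, x$macro_accuracy))
  print(x$confusion)
  for (cl in names(x$roc))
    cat(sprintf("  %s: sens %.3f spec %.3f AUC %.3f\n", cl,
                x$per_class[[cl]]$sensitivity,
                x$per_class[[cl]]$specificity, x$roc[[cl]]$auc))
  invisible(x)
}
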