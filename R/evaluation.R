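# Evaluation: contingency counts, point metrics (Sn, Sp, Acc, MCC),
# ROC / precision-recall curves with their areas, Pearson correlation, and
# the full model evaluation report.

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.numeric(as.character(labels) == "positive")
  } else {
    if (!all(labels %in% c(0, 1))) abort("Labels must be binary (0/1).")
    as.numeric(labels)
  }
}

#' Contingency counts at a hard-call threshold
#'
#' A sample is called positive iff its score is greater than or equal to the
#' threshold (ties count as positive).
#'
#' @param labels Binary labels (0/1, or `"positive"`/`"negative"`).
#' @param probs Scores in [0, 1].
#' @param threshold Hard-call threshold (default 0.5).
#' @return A one-row tibble with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(labels, probs, threshold = 0.5) {
  y <- as_binary_labels(labels)
  if (length(y) != length(probs)) abort("`labels` and `probs` differ in length.")
  if (any(probs < 0 | probs > 1)) abort("`probs` must lie in [0, 1].")
  call_pos <- probs >= threshold
  tibble(TP = sum(y == 1 & call_pos), TN = sum(y == 0 & !call_pos),
         FP = sum(y == 0 & call_pos), FN = sum(y == 1 & !call_pos))
}

#' Point metrics from contingency counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/total, and
#' MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)).  A zero
#' factor in the MCC denominator yields MCC = 0 (the standard degenerate
#' convention); an empty class makes the corresponding rate `NaN` with a
#' warning.
#'
#' @param counts One-row tibble/list with `TP`, `TN`, `FP`, `FN`.
#' @return A one-row tibble with `Sn`, `Sp`, `Acc`, `MCC`.
#' @export
point_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  if (any(c(TP, TN, FP, FN) < 0)) abort("Counts must be non-negative.")
  total <- TP + TN + FP + FN
  if (total == 0) abort("All counts are zero.")
  sn <- if (TP + FN == 0) {
    warn("No positive samples: Sn is undefined (NaN).")
    NaN
  } else TP / (TP + FN)
  sp <- if (TN + FP == 0) {
    warn("No negative samples: Sp is undefined (NaN).")
    NaN
  } else TN / (TN + FP)
  acc <- (TP + TN) / total
  denom2 <- as.numeric(TP + FN) * (TN + FP) * (TP + FP) * (TN + FN)
  mcc <- if (denom2 == 0) 0 else
    (as.numeric(TP) * TN - as.numeric(FN) * FP) / sqrt(denom2)
  tibble(Sn = sn, Sp = sp, Acc = acc, MCC = mcc)
}

#' ROC and precision-recall curves with their areas
#'
#' Thresholds sweep the unique scores in decreasing order.  AUROC uses the
#' trapezoid rule (equivalent to the normalised Mann-Whitney U statistic
#' with ties counted one half); AUPRC uses step-wise interpolation
#' (precision held at each operating point over the recall increment), which
#' avoids the optimistic bias of linear PR interpolation.
#'
#' @param labels Binary labels; both classes must be present.
#' @param probs Scores.
#' @return A list with `roc` (tibble `threshold`, `fpr`, `tpr`), `auroc`,
#'   `pr` (tibble `threshold`, `recall`, `precision`), and `auprc`.  The ROC
#'   starts at (0, 0) and ends at (1, 1).
#' @export
roc_pr_curves <- function(labels, probs) {
  y <- as_binary_labels(labels)
  if (length(y) != length(probs)) abort("`labels` and `probs` differ in length.")
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0) abort("Both classes are required for ROC/PR curves.")

  ord <- order(probs, decreasing = TRUE)
  ys <- y[ord]; ps <- probs[ord]
  last_of_tie <- c(ps[-1] != ps[-length(ps)], TRUE)
  tp <- cumsum(ys)[last_of_tie]
  fp <- cumsum(1 - ys)[last_of_tie]
  thr <- ps[last_of_tie]

  tpr <- tp / P; fpr <- fp / N
  roc <- tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auroc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)

  precision <- tp / (tp + fp)
  recall <- tpr
  pr <- tibble(threshold = thr, recall = recall, precision = precision)
  auprc <- sum(diff(c(0, recall)) * precision)

  list(roc = roc, auroc = auroc, pr = pr, auprc = auprc)
}

#' Pearson correlation coefficient
#'
#' Textbook product-moment correlation of two equal-length vectors, in
#' [-1, 1].  Zero variance in either vector is an error (the coefficient is
#' undefined there, not 0).
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` differ in length.")
  if (length(x) < 2) abort("Need at least two observations.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Zero variance: the Pearson correlation is undefined.")
  }
  stats::cor(x, y)
}

#' Evaluate a model on a dataset split
#'
#' Computes the full report: contingency counts at the hard-call threshold,
#' Sn/Sp/Acc/MCC, ROC and PR curves with AUROC/AUPRC, and — when the model
#' has a regression head and the split carries `support_target` — both the
#' Pearson r of the regression output against the targets and the Pearson r
#' of the classification probability against the same targets (the latter
#' shows what the classifier alone would offer as a confidence score).
#'
#' @param model A trained `m6a_model` with a classification head.
#' @param data Windows tibble with `label` (and optionally
#'   `support_target`).
#' @param threshold Hard-call threshold on the positive-class probability.
#' @return An object of class `m6a_eval`.
#' @export
evaluate_model <- function(model, data, threshold = 0.5) {
  pred <- predict(model, data)
  if (is.null(pred$p_positive)) {
    abort("The model has no classification head to evaluate.")
  }
  y <- as_binary_labels(data$label)
  counts <- confusion_counts(y, pred$p_positive, threshold = threshold)
  metrics <- point_metrics(counts)
  curves <- roc_pr_curves(y, pred$p_positive)

  pearson_reg <- pearson_prob <- NULL
  if (is.data.frame(data) && "support_target" %in% names(data)) {
    tgt <- data$support_target
    if (stats::sd(tgt) > 0) {
      if (!is.null(pred$reg_output) && stats::sd(pred$reg_output) > 0) {
        pearson_reg <- pearson_r(pred$reg_output, tgt)
      }
      if (stats::sd(pred$p_positive) > 0) {
        pearson_prob <- pearson_r(pred$p_positive, tgt)
      }
    }
  }

  structure(list(
    counts = counts, metrics = metrics, roc = curves$roc, pr = curves$pr,
    auroc = curves$auroc, auprc = curves$auprc,
    pearson_reg = pearson_reg, pearson_prob = pearson_prob,
    threshold = threshold, n = length(y), predictions = pred
  ), class = "m6a_eval")
}

#' @export
print.m6a_eval <- function(x, ...) {
  cat(sprintf(
    "<m6a_eval> n = %d | Acc %.4f  MCC %.4f  AUROC %.4f  AUPRC %.4f%s\n",
    x$n, x$metrics$Acc, x$metrics$MCC, x$auroc, x$auprc,
    if (!is.null(x$pearson_reg)) sprintf("  r(reg) %.4f", x$pearson_reg) else ""))
  invisible(x)
}

#' @export
tidy.m6a_eval <- function(x, ...) {
  out <- tibble(
    metric = c("Sn", "Sp", "Acc", "MCC", "AUROC", "AUPRC"),
    value = c(x$metrics$Sn, x$metrics$Sp, x$metrics$Acc, x$metrics$MCC,
              x$auroc, x$auprc))
  if (!is.null(x$pearson_reg)) {
    out <- dplyr::bind_rows(out, tibble(metric = "pearson_reg",
                                        value = x$pearson_reg))
  }
  if (!is.null(x$pearson_prob)) {
    out <- dplyr::bind_rows(out, tibble(metric = "pearson_prob",
                                        value = x$pearson_prob))
  }
  out
}

#' @export
glance.m6a_eval <- function(x, ...) {
  tibble(n = x$n, Sn = x$metrics$Sn, Sp = x$metrics$Sp, Acc = x$metrics$Acc,
         MCC = x$metrics$MCC, AUROC = x$auroc, AUPRC = x$auprc,
         pearson_reg = x$pearson_reg %||% NA_real_,
         pearson_prob = x$pearson_prob %||% NA_real_,
         threshold = x$threshold)
}

#' Plot ROC and/or precision-recall curves of an evaluation
#'
#' @param object An `m6a_eval`.
#' @param type `"roc"`, `"pr"`, or `"both"` (facetted).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.m6a_eval <- function(object, type = c("both", "roc", "pr"), ...) {
  type <- match.arg(type)
  roc_df <- dplyr::transmute(object$roc, curve = "ROC", x = .data$fpr,
                             y = .data$tpr)
  pr_df <- dplyr::transmute(object$pr, curve = "Precision-recall",
                            x = .data$recall, y = .data$precision)
  df <- switch(type, roc = roc_df, pr = pr_df,
               both = dplyr::bind_rows(roc_df, pr_df))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~curve) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate / recall",
      y = "True positive rate / precision",
      subtitle = sprintf("AUROC %.4f | AUPRC %.4f", object$auroc, object$auprc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the training-loss trajectory of a model
#'
#' @param object A trained `m6a_model` (with a `log`).
#' @param ... Unused.
#' @return A ggplot of the loss components per epoch.
#' @export
autoplot.m6a_model <- function(object, ...) {
  if (is.null(object$log)) abort("The model has no training log yet.")
  df <- tidyr::pivot_longer(object$log, -"epoch", names_to = "component",
                            values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Loss", colour = NULL) +
    ggplot2::theme_minimal()
}
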