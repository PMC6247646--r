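# Classification metrics: confusion matrices, accuracy, overall success
# ratio (OSR), success rate, quality ratio (QR), leave-one-out
# cross-validation, ROC/AUC with bootstrap confidence bounds, and
# Kolmogorov-Smirnov comparisons.

#' Confusion matrix (predicted x target)
#'
#' @param predicted,target Class labels of equal length.
#' @param levels Class levels; defaults to the union of both.
#' @return A `confusion_matrix`: integer matrix with predicted classes as
#'   rows and target classes as columns.
#' @export
confusion_matrix <- function(predicted, target, levels = NULL) {
  if (is.null(levels))
    levels <- union(levels(factor(target)), levels(factor(predicted)))
  cm <- table(predicted = factor(predicted, levels = levels),
              target = factor(target, levels = levels))
  structure(unclass(cm), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows predicted, columns target), OSR =",
      sprintf("%.2f%%\n", osr(x)))
  print(unclass(x))
  invisible(x)
}

#' Per-class TP/TN/FP/FN counts
#'
#' For one class of a multiclass confusion matrix, under the one-vs-all
#' convention: TP + TN + FP + FN equals the total sample count.
#'
#' @param cm A `confusion_matrix`.
#' @param class Class name.
#' @return Named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
class_counts <- function(cm, class) {
  stopifnot(class %in% rownames(cm))
  tp <- cm[class, class]
  fp <- sum(cm[class, ]) - tp
  fn <- sum(cm[, class]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Per-class accuracy
#'
#' accuracy = (TP + TN) / (TP + TN + FP + FN) for the given class.
#'
#' @param cm A `confusion_matrix` with a positive total.
#' @param class Class name.
#' @return Scalar in \[0, 1\].
#' @export
accuracy <- function(cm, class) {
  stopifnot(sum(cm) > 0)
  k <- class_counts(cm, class)
  (k["TP"] + k["TN"]) / sum(k)
}

#' Overall success ratio (percentage)
#'
#' OSR = 100 x (sum of the confusion-matrix diagonal) / total samples.
#'
#' @param cm A `confusion_matrix` with a positive total.
#' @return Percentage in \[0, 100\].
#' @export
osr <- function(cm) {
  stopifnot(sum(cm) > 0)
  100 * sum(diag(as.matrix(cm))) / sum(cm)
}

#' Per-class true-positive rates
#'
#' R_TP = TP / (TP + FN) per class (diagonal over target-column sum).
#'
#' @param cm A `confusion_matrix`.
#' @return Named vector of rates in \[0, 1\] (NA for empty classes).
#' @export
true_positive_rates <- function(cm) {
  m <- as.matrix(cm)
  diag(m) / colSums(m)
}

#' Success rate over a grid slice
#'
#' The mean of per-class true-positive rates over the v x tau cells of a
#' grid slice (v preprocessing combinations, tau tasks).
#'
#' @param r_tp Numeric vector (or matrix) of true-positive rates covering
#'   the complete slice.
#' @return Scalar in \[0, 1\].
#' @export
success_rate <- function(r_tp) {
  r_tp <- as.numeric(r_tp)
  stopifnot(length(r_tp) > 0, !anyNA(r_tp))
  mean(r_tp)
}

#' Quality ratio
#'
#' QR = (OSR_LOOCV + OSR_test) / 2, the score used to select the best
#' embedding scenarios; like OSR it lives in \[0, 100\].
#'
#' @param osr_loocv,osr_test OSR percentages.
#' @return Percentage in \[0, 100\].
#' @export
quality_ratio <- function(osr_loocv, osr_test) {
  stopifnot(osr_loocv >= 0, osr_loocv <= 100, osr_test >= 0, osr_test <= 100)
  (osr_loocv + osr_test) / 2
}

#' Column-normalized confusion matrix
#'
#' Each target column is divided by its total, so columns sum to 1 (the
#' style of the grand-average confusion table).
#'
#' @param cm A `confusion_matrix`.
#' @return Numeric matrix with unit column sums.
#' @export
normalize_confusion <- function(cm) {
  m <- as.matrix(cm)
  sweep(m, 2, pmax(colSums(m), 1), "/")
}

#' Grand average of confusion matrices
#'
#' Averages column-normalized confusion matrices over grid configurations.
#'
#' @param cms List of `confusion_matrix` objects with identical classes.
#' @return Numeric matrix with unit column sums.
#' @export
grand_average_confusion <- function(cms) {
  stopifnot(length(cms) > 0)
  Reduce(`+`, lapply(cms, normalize_confusion)) / length(cms)
}

#' Leave-one-out cross-validation of the one-vs-all SVM
#'
#' Refits the classifier n times, each time predicting the single held-out
#' sample; the held-out predictions are accumulated into one confusion
#' matrix. If a fold's training set loses a class entirely, prediction
#' proceeds among the remaining classes and the fold is flagged.
#'
#' @param points Numeric matrix of (embedding) coordinates.
#' @param labels Class labels.
#' @param kernel_scale,cost Passed to [svm_ova()].
#' @return List with `confusion`, `r_tp`, `osr`, `predictions`, and the
#'   held-out `decisions` matrix (samples x classes, for ROC analysis).
#' @export
loocv <- function(points, labels, kernel_scale = 0.35, cost = 1) {
  points <- as.matrix(points)
  labels <- factor(labels)
  classes <- levels(droplevels(labels))
  n <- nrow(points)
  stopifnot(n >= length(classes) + 1)
  preds <- character(n)
  decs <- matrix(NA_real_, n, length(classes),
                 dimnames = list(NULL, classes))
  flagged <- FALSE
  for (i in seq_len(n)) {
    tr_y <- droplevels(labels[-i])
    if (nlevels(tr_y) < length(classes)) flagged <- TRUE
    fit <- svm_ova(points[-i, , drop = FALSE], tr_y,
                   kernel_scale = kernel_scale, cost = cost)
    d <- predict(fit, points[i, , drop = FALSE], type = "decision")
    decs[i, colnames(d)] <- d
    cand <- colnames(d)[d == max(d)]
    preds[i] <- sort(cand)[1]
  }
  if (flagged)
    warning("some folds lost a class; prediction among remaining classes")
  cm <- confusion_matrix(preds, labels, levels = classes)
  list(confusion = cm, r_tp = true_positive_rates(cm), osr = osr(cm),
       predictions = preds, decisions = decs)
}

#' ROC curve and AUC with bootstrap confidence bounds
#'
#' One-vs-all ROC from decision values: the AUC is the Mann-Whitney
#' concordance probability (ties counted 1/2), and the confidence interval
#' is the percentile bootstrap over samples.
#'
#' @param scores Decision values (larger = more positive).
#' @param labels Binary labels (logical, or coercible: the positive class is
#'   `TRUE`/1/the second factor level).
#' @param replicas Bootstrap replicas.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return List of class `roc_result`: `roc` (data frame fpr/tpr), `auc`,
#'   `ci` (two-sided percentile interval), `auc_boot`.
#' @export
roc_auc_bootstrap <- function(scores, labels, replicas = 1000L, seed = 1L,
                              conf = 0.95) {
  pos <- if (is.logical(labels)) labels else {
    f <- factor(labels)
    if (nlevels(f) != 2) stop("labels must be binary")
    f == levels(f)[2]
  }
  if (!any(pos) || all(pos)) stop("both label values must be present")
  if (length(unique(scores)) == 1) {
    warning("degenerate scores (all equal): AUC = 0.5")
    return(structure(list(
      roc = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
      auc = 0.5, ci = c(lower = NA_real_, upper = NA_real_),
      auc_boot = numeric(0)), class = "roc_result"))
  }
  auc_of <- function(s, p) {
    r <- rank(s)
    np <- sum(p); nn <- sum(!p)
    (sum(r[p]) - np * (np + 1) / 2) / (np * nn)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), 1.0),
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), 1.0))
  old <- .Random.seed_guard(.substream(seed, 23L))
  on.exit(old(), add = TRUE)
  n <- length(scores)
  auc_boot <- vapply(seq_len(replicas), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (!any(pos[idx]) || all(pos[idx])) return(NA_real_)
    auc_of(scores[idx], pos[idx])
  }, 1.0)
  auc_boot <- auc_boot[!is.na(auc_boot)]
  qs <- stats::quantile(auc_boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  structure(list(roc = roc, auc = auc_of(scores, pos),
                 ci = c(lower = qs[1], upper = qs[2]),
                 auc_boot = auc_boot),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% bootstrap CI %.3f-%.3f, %d replicas)\n",
              x$auc, x$ci["lower"], x$ci["upper"], length(x$auc_boot)))
  invisible(x)
}

#' Plot an ROC curve with its bootstrap confidence band
#'
#' @param x A `roc_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "s", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "false positive rate",
                 ylab = "true positive rate",
                 main = sprintf("ROC (AUC %.2f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test (asymptotic p value) between two success-rate
#' distributions.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List with `statistic` (max ECDF gap) and `p_value`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  ht <- suppressWarnings(stats::ks.test(sample_a, sample_b,
                                        exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' One-sample KS normality check
#'
#' KS test of a sample against a normal with the sample's mean and sd (the
#' normality pre-check used before comparing success-rate distributions).
#'
#' @param x Numeric vector, length >= 3.
#' @return List with `statistic` and `p_value`.
#' @export
normality_check <- function(x) {
  stopifnot(length(x) >= 3)
  ht <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Scatter plot with the classifier's decision regions
#'
#' Classifies a dense grid over the plotting range with the trained model and
#' shades the regions, overlaying the embedded points.
#'
#' @param model An `svm_ova` (or any model with a class-returning `predict`).
#' @param points n x 2 coordinates.
#' @param labels Class labels of the points.
#' @param resolution Grid resolution per axis.
#' @export
plot_decision_boundary <- function(model, points, labels,
                                   resolution = 150L) {
  points <- as.matrix(points)
  rx <- grDevices::extendrange(points[, 1]); ry <-
    grDevices::extendrange(points[, 2])
  gx <- seq(rx[1], rx[2], length.out = resolution)
  gy <- seq(ry[1], ry[2], length.out = resolution)
  grid <- as.matrix(expand.grid(gx, gy))
  cls <- factor(predict(model, grid), levels = levels(factor(labels)))
  z <- matrix(as.integer(cls), resolution, resolution)
  graphics::image(gx, gy, z, col = grDevices::adjustcolor(
    seq_len(nlevels(cls)), alpha.f = 0.2),
    xlab = "dimension 1", ylab = "dimension 2", useRaster = TRUE)
  f <- factor(labels)
  graphics::points(points, col = as.integer(f), pch = c(2, 8, 1)[as.integer(f)])
  graphics::legend("topright", legend = levels(f),
                   col = seq_len(nlevels(f)), pch = c(2, 8, 1), bty = "n")
  invisible(NULL)
}
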