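#' Confusion table for a binary diagnostic test
#'
#' @param pred,truth equal-length vectors of 0/1 (or logical) labels:
#'   predictions and clinician ground truth.
#' @return A `confusion_table` with fields `tp`, `fn`, `fp`, `tn`.
#' @export
#' @examples
#' confusion_table(c(1, 1, 0, 0), c(1, 1, 0, 0))
confusion_table <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (length(pred) < 1) stop("empty inputs")
  if (anyNA(pred) || anyNA(truth) ||
      !all(pred %in% 0:1) || !all(truth %in% 0:1))
    stop("labels must be binary 0/1")
  structure(list(tp = sum(pred == 1 & truth == 1),
                 fn = sum(pred == 0 & truth == 1),
                 fp = sum(pred == 1 & truth == 0),
                 tn = sum(pred == 0 & truth == 0)),
            class = "confusion_table")
}

#' Build a confusion table directly from its four cells
#' @param tp,fn,fp,tn nonnegative integer counts.
#' @return A `confusion_table`.
#' @export
confusion_from_counts <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("counts must be nonnegative integers")
  structure(lapply(cells, as.integer), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(pred = c("pos", "neg"), truth = c("pos", "neg")))
  print(m)
  invisible(x)
}

#' Sensitivity and specificity with exact 95% confidence intervals
#'
#' Point estimates `tp/(tp+fn)` and `tn/(tn+fp)` with exact
#' Clopper-Pearson binomial intervals, chosen for validity at the small
#' margins typical of pilot diagnostic studies.
#'
#' @param table a `confusion_table`.
#' @param conf_level confidence level (default 0.95).
#' @param allow_undefined report `NA` instead of raising when a margin is
#'   empty (used for single-class batches).
#' @return A `diagnostic_metrics` list with `sensitivity`, `specificity`
#'   (each `estimate`, `lower`, `upper`) and the table.
#' @export
#' @examples
#' sensitivity_specificity(confusion_from_counts(tp = 5, fn = 0, fp = 14, tn = 69))
sensitivity_specificity <- function(table, conf_level = 0.95,
                                    allow_undefined = FALSE) {
  stopifnot(inherits(table, "confusion_table"))
  one <- function(x, n, what) {
    if (n < 1) {
      if (allow_undefined)
        return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                    n = n))
      stop("undefined metric: ", what, " has an empty margin")
    }
    ci <- binom.test(x, n, conf.level = conf_level)$conf.int
    list(estimate = x / n, lower = ci[1], upper = ci[2], n = n)
  }
  structure(list(sensitivity = one(table$tp, table$tp + table$fn, "sensitivity"),
                 specificity = one(table$tn, table$tn + table$fp, "specificity"),
                 conf_level = conf_level, table = table),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  f <- function(m, nm)
    cat(sprintf("  %s %.2f%% (%d/%d), %g%% CI [%.2f%%, %.2f%%]\n", nm,
                100 * m$estimate, round(m$estimate * m$n), m$n,
                100 * x$conf_level, 100 * m$lower, 100 * m$upper))
  cat("<diagnostic_metrics>\n")
  f(x$sensitivity, "sensitivity")
  f(x$specificity, "specificity")
  invisible(x)
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with
#' observed agreement `p_o` and expected agreement `p_e` from the product of
#' the marginal label distributions.
#'
#' @param labels_a,labels_b equal-length label vectors (any common alphabet,
#'   length at least 2).
#' @return Kappa in \[-1, 1\].
#' @export
#' @examples
#' cohens_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0))   # 1
#' cohens_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0))   # 0
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("rating lengths differ")
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 paired ratings")
  if (anyNA(labels_a) || anyNA(labels_b)) stop("NA ratings not allowed")
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = lev)
  b <- factor(as.character(labels_b), levels = lev)
  po <- mean(a == b)
  pe <- sum((table(a) / n) * (table(b) / n))
  if (abs(1 - pe) < .Machine$double.eps * 8)
    stop("degenerate marginals: both raters are constant, kappa undefined")
  as.numeric((po - pe) / (1 - pe))
}

#' ROC curve and optimal cutoff for a continuous score
#'
#' Sweeps classification thresholds over the midpoints between consecutive
#' unique scores (plus sentinels below and above all scores), predicting
#' positive when `score >= threshold`. The area under the curve is computed
#' by the trapezoid rule and the operating cutoff maximises Youden's
#' J = sensitivity + specificity - 1; ties are broken toward the lower
#' threshold, i.e. toward sensitivity — the screen is built not to miss
#' infections.
#'
#' @param scores numeric scores (higher = more suspicious of infection).
#' @param truth 0/1 (or logical) ground-truth labels; both classes must be
#'   present.
#' @param criterion cutoff criterion; only `"youden"` is implemented.
#' @return A `roc_curve`: `points` data frame (`threshold`, `tpr`, `fpr`,
#'   `youden`), `auc`, `optimal_threshold`, `criterion`.
#' @export
roc_and_cutoff <- function(scores, truth, criterion = "youden") {
  criterion <- match.arg(criterion, "youden")
  truth <- as.integer(truth)
  if (length(scores) != length(truth)) stop("scores and truth lengths differ")
  if (anyNA(scores) || anyNA(truth) || !all(truth %in% 0:1))
    stop("invalid scores or labels")
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  if (npos == 0 || nneg == 0)
    stop("single-class truth: ROC undefined")
  u <- sort(unique(scores))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == 1) / npos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == 0) / nneg, numeric(1))
  pts <- data.frame(threshold = thr, tpr = tpr, fpr = fpr,
                    youden = tpr - fpr)
  ord <- order(pts$fpr, pts$tpr)   # sweep from (0,0) to (1,1)
  fx <- pts$fpr[ord]; ty <- pts$tpr[ord]
  auc <- sum(diff(fx) * (ty[-1] + ty[-length(ty)]) / 2)
  best <- which(pts$youden == max(pts$youden))
  opt <- min(pts$threshold[best])  # tie toward sensitivity
  structure(list(points = pts, auc = auc,
                 optimal_threshold = opt, criterion = criterion,
                 n_pos = npos, n_neg = nneg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.4f over %d pos / %d neg; %s-optimal threshold %.4f\n",
              x$auc, x$n_pos, x$n_neg, x$criterion, x$optimal_threshold))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  ord <- order(x$points$fpr, x$points$tpr)
  plot(x$points$fpr[ord], x$points$tpr[ord], type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3)
  i <- which.min(abs(x$points$threshold - x$optimal_threshold))
  points(x$points$fpr[i], x$points$tpr[i], pch = 19)
  invisible(x)
}

#' Evaluate predictions against ground truth in one call
#'
#' Convenience wrapper producing the full evaluation block: confusion
#' table, sensitivity/specificity with CIs, kappa, and (when scores are
#' supplied and both classes are present) the ROC with its Youden cutoff.
#'
#' @param pred 0/1 predictions.
#' @param truth 0/1 ground truth.
#' @param scores optional continuous scores underlying `pred`.
#' @return A list `table`, `metrics`, `kappa`, `roc` (`NULL` if not
#'   computable).
#' @export
evaluate_predictions <- function(pred, truth, scores = NULL) {
  tab <- confusion_table(pred, truth)
  metrics <- sensitivity_specificity(tab, allow_undefined = TRUE)
  kap <- tryCatch(cohens_kappa(pred, truth), error = function(e) NA_real_)
  roc <- NULL
  if (!is.null(scores) && length(unique(truth)) == 2)
    roc <- roc_and_cutoff(scores, truth)
  list(table = tab, metrics = metrics, kappa = kap, roc = roc)
}
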