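#' 2x2 confusion table (positive = progression / abnormal call)
#'
#' @param tp,fp,tn,fn nonnegative counts.
#' @return list of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), class = "confusion_table")
}

#' Confusion table from predicted and observed binary labels
#'
#' @param predicted,observed logical vectors (TRUE = positive).
#' @return a [confusion_table()].
#' @export
confusion_from_calls <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  confusion_table(
    tp = sum(predicted & observed),
    fp = sum(predicted & !observed),
    tn = sum(!predicted & !observed),
    fn = sum(!predicted & observed)
  )
}

#' Diagnostic metrics of a confusion table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), accuracy (tp+tn)/total,
#' false-positive rate 1 - specificity, false-negative rate 1 - sensitivity.
#' Percentages are also reported rounded to 0.1%. An empty margin leaves the
#' affected metric `NA`.
#'
#' @param table a [confusion_table()].
#' @return list of class `diagnostic_report` with the metric fractions and
#'   `*_pct` fields.
#' @export
confusion_metrics <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  tp <- table$tp; fp <- table$fp; tn <- table$tn; fn <- table$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion table")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / total
  out <- list(
    sensitivity = sens, specificity = spec, accuracy = acc,
    false_positive_rate = 1 - spec, false_negative_rate = 1 - sens,
    sensitivity_pct = round(100 * sens, 1),
    specificity_pct = round(100 * spec, 1),
    accuracy_pct = round(100 * acc, 1),
    n = total, table = table
  )
  class(out) <- "diagnostic_report"
  out
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%  (n = %d)\n",
    x$sensitivity_pct, x$specificity_pct, x$accuracy_pct, x$n
  ))
  invisible(x)
}

#' ROC curve and AUC for a continuous score
#'
#' Higher scores indicate the positive class. The curve steps through every
#' distinct score threshold (tied scores move the curve diagonally in a single
#' step) and the AUC is the trapezoidal area, equal to the rank-based
#' concordance probability.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) class labels, TRUE = positive.
#' @return list: `auc`, `points` (data.frame `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(scores)),
            !any(is.na(labels)))
  if (!any(labels) || all(labels)) {
    stop("both classes must be present to compute a ROC curve")
  }
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  pts <- data.frame(
    threshold = r$thresholds,
    fpr = 1 - r$specificities,
    tpr = r$sensitivities
  )
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  list(auc = as.numeric(r$auc), points = pts)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood rule (sum of hypergeometric
#' probabilities of all margin-fixed tables no more probable than the
#' observed one). The odds ratio reported is the sample cross-product
#' (ad)/(bc); a zero off-diagonal cell makes it undefined and flagged.
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @return list: `p_value`, `odds_ratio`, `odds_ratio_defined`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  if (sum(table) == 0) stop("all-zero table")
  p <- stats::fisher.test(table)$p.value
  bc <- table[1, 2] * table[2, 1]
  or_def <- bc > 0
  or <- if (or_def) (table[1, 1] * table[2, 2]) / bc else NA_real_
  list(p_value = p, odds_ratio = or, odds_ratio_defined = or_def)
}

#' Pearson's chi-squared test on an r x c table
#'
#' No continuity correction. A zero expected cell is flagged.
#'
#' @param table matrix of nonnegative counts with positive margins.
#' @return list: `statistic`, `df`, `p_value`, `zero_expected` flag.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0))
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  zero_expected <- any(expected == 0)
  if (zero_expected) {
    warning("zero expected cell count; statistic undefined")
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                zero_expected = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, zero_expected = FALSE)
}

#' Mann-Whitney U test
#'
#' U statistic for `x` with midrank ties; exact p-value by enumeration when
#' both samples have at most 20 observations and there are no ties, normal
#' approximation with tie correction otherwise.
#'
#' @param x,y numeric samples.
#' @return list: `u`, `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- any(duplicated(c(x, y)))
  exact <- length(x) <= 20 && length(y) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  list(u = unname(wt$statistic), p_value = wt$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks with a t-approximation p-value. A constant
#' vector leaves rho undefined.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list: `rho`, `p_value`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
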