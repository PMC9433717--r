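#' Matthews correlation coefficient
#'
#' Standard MCC with the square-rooted denominator product,
#' \eqn{(TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.
#' When any marginal of the confusion matrix is zero the coefficient is
#' defined as 0 (chance level), which keeps downstream coverage-weighted
#' scores defined for degenerate tools. Vectorised over its arguments.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return MCC in \[-1, 1\].
#' @export
#' @examples
#' mcc(10, 10, 0, 0) # 1
#' mcc(6, 4, 2, 3)   # ~0.327
mcc <- function(tp, tn, fp, fn) {
  stopifnot(all(tp >= 0, tn >= 0, fp >= 0, fn >= 0))
  num <- tp * tn - fp * fn
  # products as doubles to avoid integer overflow on large cohorts
  den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  out <- ifelse(den == 0, 0, num / den)
  as.numeric(out)
}

#' Coverage-weighted normalized MCC
#'
#' The package's headline ranking metric: MCC rescaled to \[0, 1\] via
#' `(mcc + 1) / 2`, then multiplied by tool coverage (the fraction of
#' presented variants the tool actually scored). A tool that separates
#' classes perfectly but scores only half the variants gets 0.5, the same as
#' a chance-level tool with full coverage — missingness is a first-class
#' penalty, not an excuse.
#'
#' @param mcc_value MCC in \[-1, 1\].
#' @param coverage Fraction of scored variants in \[0, 1\].
#' @return Weighted normalized MCC in \[0, 1\].
#' @export
weighted_norm_mcc <- function(mcc_value, coverage) {
  stopifnot(all(mcc_value >= -1 & mcc_value <= 1, na.rm = TRUE),
            all(coverage >= 0 & coverage <= 1, na.rm = TRUE))
  coverage * (mcc_value + 1) / 2
}

#' F-beta score
#'
#' \eqn{F_\beta = (1+\beta^2) P R / (\beta^2 P + R)}. Beta weights the
#' precision/recall balance: beta = 1 is the F1 score, beta < 1 favours
#' precision (fewer false positives), beta > 1 favours recall (fewer false
#' negatives). Returns 0 when precision and recall are both 0, and treats an
#' undefined precision (no predicted positives) as yielding 0.
#'
#' @param precision,recall Values in \[0, 1\] (`NA` allowed for undefined).
#' @param beta Positive weight on recall.
#' @return F-beta in \[0, 1\].
#' @export
#' @examples
#' f_beta(0.5, 1, beta = 1) # 2/3
f_beta <- function(precision, recall, beta) {
  stopifnot(beta > 0)
  p <- ifelse(is.na(precision), 0, precision)
  r <- ifelse(is.na(recall), 0, recall)
  den <- beta^2 * p + r
  ifelse(den == 0, 0, (1 + beta^2) * p * r / den)
}

classify_calls <- function(scores, threshold, comparator) {
  comparator <- match.arg(comparator, c("strict_greater", "strict_less"))
  if (comparator == "strict_greater") scores > threshold else scores < threshold
}

#' Confusion matrix and derived metrics at a fixed threshold
#'
#' Classifies each scored variant against a decision threshold with a strict
#' comparator (`strict_greater`, or `strict_less` for lower-is-pathogenic
#' tools; scores exactly at the threshold are called benign) and tabulates
#' TP/TN/FP/FN together with sensitivity, specificity, precision, MCC,
#' normalized MCC and the coverage-weighted normalized MCC. Missing scores
#' are excluded from the confusion matrix but still count towards `n_total`,
#' so `coverage = n_scored / n_total` records the tool's missingness.
#' Ratio metrics with a zero denominator are `NA` (written as "." in TSV
#' reports); MCC with a zero marginal is 0.
#'
#' @param scores Numeric scores, `NA` = missing.
#' @param labels Character/factor vector of `"pathogenic"`/`"benign"`, aligned
#'   with `scores`.
#' @param threshold Decision threshold.
#' @param comparator `"strict_greater"` or `"strict_less"`.
#' @return One-row tibble: `n_total`, `n_scored`, `coverage`, `tp`, `tn`,
#'   `fp`, `fn`, `sensitivity`, `specificity`, `precision`, `mcc`,
#'   `normalized_mcc`, `weighted_norm_mcc`.
#' @export
#' @examples
#' confusion_at_threshold(c(0.9, 0.8, 0.1, 0.2),
#'                        c("pathogenic", "pathogenic", "benign", "benign"),
#'                        threshold = 0.5, comparator = "strict_greater")
confusion_at_threshold <- function(scores, labels, threshold,
                                   comparator = "strict_greater") {
  if (length(scores) != length(labels)) {
    abort("scores and labels must have the same length")
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("pathogenic", "benign"))) {
    abort("labels must be 'pathogenic' or 'benign'")
  }
  if (length(scores) == 0) abort("at least one labelled variant is required")
  n_total <- length(scores)
  scored <- !is.na(scores)
  n_scored <- sum(scored)
  call_path <- classify_calls(scores[scored], threshold, comparator)
  is_path <- labels[scored] == "pathogenic"
  tp <- sum(call_path & is_path)
  tn <- sum(!call_path & !is_path)
  fp <- sum(call_path & !is_path)
  fn <- sum(!call_path & is_path)
  mcc_v <- mcc(tp, tn, fp, fn)
  coverage <- n_scored / n_total
  tibble::tibble(
    n_total = n_total, n_scored = n_scored, coverage = coverage,
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, tn + fp),
    precision = safe_ratio(tp, tp + fp),
    mcc = mcc_v,
    normalized_mcc = (mcc_v + 1) / 2,
    weighted_norm_mcc = weighted_norm_mcc(mcc_v, coverage)
  )
}

safe_ratio <- function(num, den) {
  if (den == 0) NA_real_ else num / den
}

#' Rank-transform scores to \[0, 1\]
#'
#' Replaces non-missing scores by their fractional rank rescaled to \[0, 1\]
#' (mean rank for ties), after sign-inverting lower-is-pathogenic tools so
#' that larger always means more pathogenic. Missing scores stay missing.
#' This puts every tool's scores on a common monotone scale before ROC
#' analysis. A single non-missing score maps to 0.5.
#'
#' @param scores Numeric scores with `NA` for missing.
#' @param direction `"higher_is_pathogenic"` or `"lower_is_pathogenic"`.
#' @return Numeric vector in \[0, 1\] with the same missingness pattern.
#' @export
#' @examples
#' rank_transform(c(1, 2, 3), "higher_is_pathogenic") # 0, 0.5, 1
#' rank_transform(c(1, 2, 3), "lower_is_pathogenic")  # 1, 0.5, 0
rank_transform <- function(scores, direction = "higher_is_pathogenic") {
  direction <- match.arg(direction,
                         c("higher_is_pathogenic", "lower_is_pathogenic"))
  if (all(is.na(scores))) abort("rank_transform: all scores are missing")
  x <- if (direction == "lower_is_pathogenic") -scores else scores
  ok <- !is.na(x)
  n <- sum(ok)
  out <- rep(NA_real_, length(x))
  out[ok] <- if (n == 1) 0.5 else (rank(x[ok], ties.method = "average") - 1) / (n - 1)
  out
}

#' ROC curve and auROC
#'
#' Builds the ROC curve over all distinct score cutpoints (ties grouped at
#' one cutpoint) using only scored variants, and integrates it with the
#' trapezoidal rule. The resulting auROC equals the Mann-Whitney probability
#' that a random pathogenic variant outscores a random benign one, with ties
#' half-counted; it is invariant under any strictly monotone transform of the
#' scores, so raw and rank-transformed scores give identical areas.
#'
#' @inheritParams confusion_at_threshold
#' @param direction Score direction; lower-is-pathogenic scores are inverted
#'   before curve construction.
#' @return An object of class `roc_summary`: list with `points` (tibble of
#'   `fpr`, `tpr`), `auroc`, `n_scored`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' r <- roc_and_auroc(c(0.9, 0.4, 0.5, 0.1),
#'                    c("pathogenic", "pathogenic", "benign", "benign"))
#' r$auroc # 0.75
roc_and_auroc <- function(scores, labels, direction = "higher_is_pathogenic") {
  if (length(scores) != length(labels)) {
    abort("scores and labels must have the same length")
  }
  labels <- as.character(labels)
  direction <- match.arg(direction,
                         c("higher_is_pathogenic", "lower_is_pathogenic"))
  x <- if (direction == "lower_is_pathogenic") -scores else scores
  ok <- !is.na(x)
  x <- x[ok]
  y <- labels[ok] == "pathogenic"
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    abort("roc_and_auroc: both classes must be present among scored variants")
  }
  # sweep thresholds from +Inf down through each distinct score; ties grouped
  ord <- order(x, decreasing = TRUE)
  x <- x[ord]; y <- y[ord]
  grp <- cumsum(!duplicated(x))
  tp_cum <- cumsum(y)
  fp_cum <- cumsum(!y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp_cum[last] / n_pos)
  fpr <- c(0, fp_cum[last] / n_neg)
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(
    list(
      points = tibble::tibble(fpr = fpr, tpr = tpr),
      auroc = auroc, n_scored = length(x), n_pos = n_pos, n_neg = n_neg
    ),
    class = "roc_summary"
  )
}

#' @export
print.roc_summary <- function(x, ...) {
  cat("<roc_summary> auROC = ", format(x$auroc, digits = 4),
      " (", x$n_pos, " pathogenic vs ", x$n_neg, " benign, ",
      x$n_scored, " scored)\n", sep = "")
  invisible(x)
}

#' @export
autoplot.roc_summary <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "1 - specificity (false positive rate)",
      y = "Sensitivity (true positive rate)",
      title = sprintf("ROC curve (auROC = %.3f)", object$auroc)
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
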