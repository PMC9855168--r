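# Evaluation metrics for binary song detection: confusion counts,
# accuracy, precision, recall and F1; Cohen's kappa for inter-observer
# agreement; and Shapiro-gated paired comparisons between configurations.

#' Confusion counts and classification metrics
#'
#' Accuracy is the fraction of positives and negatives classified
#' correctly; precision is tp / (tp + fp); recall (sensitivity) is
#' tp / (tp + fn); F1 is the harmonic mean of precision and recall.
#' Degenerate denominators (no predicted positives, or no true positives)
#' make precision/recall undefined: they are reported as `NA` with a flag,
#' and F1 is 0 whenever either ingredient is undefined or zero.
#'
#' @param predicted,truth Equal-length binary (0/1) vectors.
#' @return A `metric_set`: list with `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `precision`, `recall`, `f1`, `precision_defined`, `recall_defined`.
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
compute_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("'predicted' and 'truth' must have equal length", call. = FALSE)
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("labels must be binary (0/1)", call. = FALSE)
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  tn <- sum(predicted == 0 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  acc <- (tp + tn) / (tp + fp + tn + fn)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0)
    2 * prec * rec / (prec + rec) else 0
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = acc, precision = prec, recall = rec, f1 = f1,
                 precision_defined = tp + fp > 0,
                 recall_defined = tp + fn > 0),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> tp %d fp %d tn %d fn %d | acc %.4f prec %s rec %s f1 %.4f\n",
              x$tp, x$fp, x$tn, x$fn, x$accuracy,
              ifelse(is.na(x$precision), "NA", sprintf("%.4f", x$precision)),
              ifelse(is.na(x$recall), "NA", sprintf("%.4f", x$recall)), x$f1))
  invisible(x)
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with
#' observed agreement `p_o` and chance agreement `p_e` computed from the
#' raters' marginal label frequencies. When both raters are constant and
#' identical (`p_e = 1`), agreement is perfect and kappa is defined as 1.
#'
#' @param labels_a,labels_b Equal-length binary (0/1) vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length", call. = FALSE)
  if (!all(labels_a %in% c(0, 1)) || !all(labels_b %in% c(0, 1)))
    stop("labels must be binary (0/1)", call. = FALSE)
  n <- length(labels_a)
  p_o <- mean(labels_a == labels_b)
  pa1 <- mean(labels_a == 1); pb1 <- mean(labels_b == 1)
  p_e <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  if (p_e >= 1) {
    if (p_o == 1) return(1)
    stop("chance agreement is 1 but observed agreement is not: kappa undefined",
         call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Shapiro-gated paired comparison of two metric series
#'
#' Tests whether a metric differs between two paired configurations (e.g.
#' the same cross-validation folds before and after augmentation). The
#' normality of the paired differences is checked with a Shapiro-Wilk
#' test; if normality is not rejected at `alpha` a paired t-test is used,
#' otherwise a Wilcoxon signed-rank test. All-zero differences are
#' reported as "no difference" without running either test, and constant
#' nonzero differences take the Wilcoxon branch (their normality is
#' degenerate).
#'
#' @param values_a,values_b Equal-length paired numeric vectors (length
#'   >= 3), e.g. per-fold metric values.
#' @param alpha Significance level for the normality gate (default 0.05).
#' @return A `comparison_result`: list with `test` ("paired-t",
#'   "wilcoxon" or "none"), `statistic`, `p_value`, `shapiro_p`,
#'   `mean_difference` (b - a), `alpha`, `n`.
#' @export
compare_paired <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(values_a) < 3L)
    stop("need at least 3 pairs", call. = FALSE)
  d <- values_b - values_a
  out <- list(n = length(d), alpha = alpha, mean_difference = mean(d),
              shapiro_p = NA_real_)
  if (all(d == 0)) {
    out$test <- "none"; out$statistic <- NA_real_; out$p_value <- NA_real_
    out$note <- "all paired differences are zero: no difference"
    class(out) <- "comparison_result"
    return(out)
  }
  if (stats::sd(d) == 0) {
    out$test <- "wilcoxon"
    wt <- suppressWarnings(stats::wilcox.test(values_b, values_a, paired = TRUE))
    out$statistic <- unname(wt$statistic); out$p_value <- wt$p.value
  } else {
    sw <- stats::shapiro.test(d)
    out$shapiro_p <- sw$p.value
    if (sw$p.value > alpha) {
      tt <- stats::t.test(values_b, values_a, paired = TRUE)
      out$test <- "paired-t"
      out$statistic <- unname(tt$statistic); out$p_value <- tt$p.value
    } else {
      wt <- suppressWarnings(stats::wilcox.test(values_b, values_a, paired = TRUE))
      out$test <- "wilcoxon"
      out$statistic <- unname(wt$statistic); out$p_value <- wt$p.value
    }
  }
  class(out) <- "comparison_result"
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: stat %s, p %s (shapiro p %s, mean diff %+.4f, n %d)\n",
              x$test,
              ifelse(is.na(x$statistic), "NA", sprintf("%.3f", x$statistic)),
              ifelse(is.na(x$p_value), "NA", format.pval(x$p_value, digits = 3)),
              ifelse(is.na(x$shapiro_p), "NA", sprintf("%.3f", x$shapiro_p)),
              x$mean_difference, x$n))
  invisible(x)
}
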