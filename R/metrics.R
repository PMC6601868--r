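#' Pearson correlation with a Student-t p-value
#'
#' Product-moment correlation between two numeric vectors together with
#' the two-sided p-value of the test statistic
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom.
#' The tail probability is evaluated in log space so that extreme
#' p-values (down to the denormal range, e.g. 1e-131 at n = 2754) are
#' representable rather than underflowing to zero.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return A list of class `correlation_result` with fields `r`, `n`,
#'   `p` and `log10p`.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- x + rnorm(50)
#' pearson_with_pvalue(x, y)
#' @export
pearson_with_pvalue <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("undefined correlation: constant input")
  r <- cor(x, y)
  p_from_r(r, n)
}

#' Two-sided p-value for a given correlation and sample size
#'
#' The analytic t-transform used by [pearson_with_pvalue()], exposed
#' directly so that printed correlations can be calibrated against their
#' sample size without access to the underlying data.
#'
#' @param r Pearson correlation in \[-1, 1\].
#' @param n Sample size, >= 3.
#' @return A `correlation_result` list with `r`, `n`, `p`, `log10p`.
#' @export
p_from_r <- function(r, n) {
  stopifnot(is.numeric(r), length(r) == 1, abs(r) <= 1, n >= 3)
  if (abs(r) == 1) {
    res <- list(r = r, n = as.integer(n), p = 0, log10p = -Inf)
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    logp <- log(2) + pt(-abs(tstat), df = n - 2, log.p = TRUE)
    res <- list(r = r, n = as.integer(n), p = exp(logp),
                log10p = logp / log(10))
  }
  class(res) <- "correlation_result"
  res
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d, two-sided P = %.3g)\n",
              x$r, x$n, x$p))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counting one half (the rank-sum
#' formulation, equivalent to the Mann-Whitney U statistic scaled by the
#' number of positive-negative pairs).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (logical, or coercible 0/1) of the same
#'   length; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 1))  # 2/3
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  lab <- as.logical(labels)
  if (anyNA(lab) || anyNA(scores)) stop("missing values not allowed")
  npos <- sum(lab); nneg <- sum(!lab)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  rk <- rank(scores, ties.method = "average")
  (sum(rk[lab]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Confusion-matrix summary
#'
#' Bundles the four cells of a binary confusion matrix with the derived
#' sensitivity, specificity and balanced accuracy.
#'
#' @param tn,fn,tp,fp Non-negative counts.
#' @return A list of class `confusion_summary`.
#' @export
confusion_summary <- function(tn, fn, tp, fp) {
  counts <- c(tn = tn, fn = fn, tp = tp, fp = fp)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (tp + fn == 0 || tn + fp == 0) stop("empty class: cannot summarize")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  res <- list(tn = tn, fn = fn, tp = tp, fp = fp,
              sensitivity = sens, specificity = spec,
              balanced_accuracy = (sens + spec) / 2)
  class(res) <- "confusion_summary"
  res
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("TN=%d FN=%d TP=%d FP=%d | sens=%.2f spec=%.2f balanced acc=%.2f\n",
              x$tn, x$fn, x$tp, x$fp,
              x$sensitivity, x$specificity, x$balanced_accuracy))
  invisible(x)
}

#' Balanced accuracy of a confusion summary
#'
#' Mean of sensitivity and specificity; robust to class imbalance.
#'
#' @param cs A `confusion_summary` (or list with fields tn, fn, tp, fp).
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(cs) {
  if (!is(cs, "confusion_summary"))
    cs <- confusion_summary(cs$tn, cs$fn, cs$tp, cs$fp)
  cs$balanced_accuracy
}
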