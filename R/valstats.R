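## Assay-validation statistics: exact binomial confidence intervals,
## concordance metrics against an orthogonal assay, and replicate
## reproducibility (coefficient of variation).

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Bounds from the inverse incomplete-beta relations of the binomial tails:
#' lower = `qbeta(alpha/2, k, n-k+1)` (0 when k = 0), upper =
#' `qbeta(1-alpha/2, k+1, n-k)` (1 when k = n). Values are kept at full
#' precision; rounding happens only in the print method.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param level confidence level.
#' @return object of class `proportion_ci`: k, n, point, lower, upper, level.
#' @examples
#' clopper_pearson(94, 100)   # 87.4-97.8% at one-decimal presentation
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stop_arg("need integer counts with 0 <= k <= n and n >= 1")
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  structure(list(k = as.integer(k), n = as.integer(n), point = k / n,
                 lower = lower, upper = upper, level = level),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, digits = 1, ...) {
  cat(sprintf("%d/%d = %.*f%% (%.0f%% CI: %.*f-%.*f%%)\n",
              x$k, x$n, digits, 100 * x$point, 100 * x$level,
              digits, 100 * x$lower, digits, 100 * x$upper))
  invisible(x)
}

#' Confusion counts for concordance against an orthogonal assay
#'
#' @param TP,FP,TN,FN non-negative integer counts. A true positive is called
#'   by both assays, a true negative by neither, a false positive only by
#'   this assay, a false negative only by the orthogonal assay.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP = 0L, FP = 0L, TN = 0L, FN = 0L) {
  v <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(v < 0) || any(v != round(v)))
    stop_arg("confusion counts must be non-negative integers")
  structure(as.list(as.integer(v)), names = names(v),
            class = "confusion_counts")
}

#' Concordance metrics with exact confidence intervals
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), positive predictive
#' agreement PPA = TP/(TP+FP), negative predictive agreement NPA =
#' TN/(TN+FN); each with its Clopper-Pearson interval on the
#' (numerator, denominator) pair. Metrics with a zero denominator are
#' reported as undefined (`NA`).
#'
#' @param counts a [confusion_counts()] object (or list with TP/FP/TN/FN).
#' @param level confidence level for the intervals.
#' @return data.frame: metric, numerator, denominator, value, lower, upper.
#' @export
concordance_metrics <- function(counts, level = 0.95) {
  num <- c(sensitivity = counts$TP, specificity = counts$TN,
           PPA = counts$TP, NPA = counts$TN)
  den <- c(sensitivity = counts$TP + counts$FN,
           specificity = counts$TN + counts$FP,
           PPA = counts$TP + counts$FP,
           NPA = counts$TN + counts$FN)
  rows <- lapply(names(num), function(m) {
    if (den[[m]] == 0)
      return(data.frame(metric = m, numerator = num[[m]], denominator = 0L,
                        value = NA_real_, lower = NA_real_, upper = NA_real_))
    ci <- clopper_pearson(num[[m]], den[[m]], level = level)
    data.frame(metric = m, numerator = num[[m]], denominator = den[[m]],
               value = ci$point, lower = ci$lower, upper = ci$upper)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coefficient of variation of replicate measurements
#'
#' Sample standard deviation (n-1 denominator) divided by the mean; the
#' standard reproducibility summary for replicate VAF measurements.
#'
#' @param replicate_values numeric vector of at least 2 replicates.
#' @return the CV (`NA` when the mean is not positive).
#' @examples
#' coefficient_of_variation(c(1, 2, 3))   # sd 1 / mean 2 = 0.5
#' @export
coefficient_of_variation <- function(replicate_values) {
  if (length(replicate_values) < 2L)
    stop_arg("need at least 2 replicates")
  m <- mean(replicate_values)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  stats::sd(replicate_values) / m
}
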