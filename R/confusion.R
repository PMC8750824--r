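# 2x2 confusion tables and the accuracy-metric bundle behind every
# tool x standard comparison.

#' Build a 2x2 confusion table
#'
#' Cross-tabulates a dichotomized test result against the reference-standard
#' verdict. Inputs must be complete-case aligned logical vectors of equal
#' length (drop exclusions before calling).
#'
#' @param test_abnormal logical, screening test abnormal per patient.
#' @param unfit logical, reference standard unfit per patient.
#' @return a `confusion_table`: counts `tp` (abnormal & unfit), `fn`, `fp`,
#'   `tn`.
#' @export
build_confusion <- function(test_abnormal, unfit) {
  if (length(test_abnormal) != length(unfit))
    stop("test_abnormal and unfit must have equal length")
  if (!length(unfit)) stop("empty input")
  if (anyNA(test_abnormal) || anyNA(unfit))
    stop("inputs must be complete-case aligned (no NA); drop exclusions first")
  test_abnormal <- as.logical(test_abnormal)
  unfit <- as.logical(unfit)
  confusion_table(tp = sum(test_abnormal & unfit),
                  fn = sum(!test_abnormal & unfit),
                  fp = sum(test_abnormal & !unfit),
                  tn = sum(!test_abnormal & !unfit))
}

#' Construct a confusion table from cell counts
#'
#' @param tp,fn,fp,tn non-negative integer counts; `tp` counts
#'   test-abnormal condition-unfit patients.
#' @return a `confusion_table`.
#' @export
confusion_table <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop("empty table")
  structure(as.list(cells), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(test = c("abnormal", "normal"),
                              condition = c("unfit", "fit")))
  print(m)
  invisible(x)
}

#' Confidence interval for a binomial proportion
#'
#' `"exact"` is the Clopper-Pearson interval from beta quantiles;
#' `"wilson"` is the Wilson score interval (no continuity correction).
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (> 0).
#' @param method `"exact"` or `"wilson"`.
#' @param conf_level confidence level, default 0.95.
#' @return numeric vector `c(lower, upper)` within \[0, 1\].
#' @export
proportion_ci <- function(k, n, method = c("exact", "wilson"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(n > 0, k >= 0, k <= n)
  a <- 1 - conf_level
  if (method == "exact") {
    lo <- if (k == 0) 0 else qbeta(a / 2, k, n - k + 1)
    hi <- if (k == n) 1 else qbeta(1 - a / 2, k + 1, n - k)
  } else {
    z <- qnorm(1 - a / 2)
    p <- k / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- max(0, ctr - hw); hi <- min(1, ctr + hw)
  }
  c(lower = lo, upper = hi)
}

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Computes the full per-table metric bundle: sensitivity, specificity,
#' PPV and NPV with binomial confidence intervals, likelihood ratios, the
#' unadjusted odds ratio with Wald confidence interval and p-value on the
#' log scale (no continuity correction), and the condition prevalence.
#' With any zero cell the odds ratio and its inference are flagged
#' non-estimable (`NA`) rather than silently corrected.
#'
#' @param x a `confusion_table`.
#' @param ci_method CI method for proportions, `"exact"` (Clopper-Pearson,
#'   default) or `"wilson"`.
#' @param conf_level confidence level.
#' @return an `accuracy_report` list: `sensitivity`, `specificity`, `ppv`,
#'   `npv` (each `c(estimate, lower, upper)`), `lr_pos`, `lr_neg`,
#'   `odds_ratio`, `or_ci`, `or_p`, `prevalence`, `n`, `table`.
#' @export
accuracy_report <- function(x, ci_method = c("exact", "wilson"),
                            conf_level = 0.95) {
  stopifnot(inherits(x, "confusion_table"))
  ci_method <- match.arg(ci_method)
  tp <- x$tp; fn <- x$fn; fp <- x$fp; tn <- x$tn
  npos <- tp + fn; nneg <- fp + tn
  if (npos == 0 || nneg == 0)
    stop("both condition-positive and condition-negative patients required")
  prop <- function(k, n) {
    if (n == 0) return(c(estimate = NA, lower = NA, upper = NA))
    c(estimate = k / n, proportion_ci(k, n, ci_method, conf_level))
  }
  sens <- prop(tp, npos)
  spec <- prop(tn, nneg)
  ppv <- prop(tp, tp + fp)
  npv <- prop(tn, tn + fn)
  lr_pos <- if (spec[["estimate"]] < 1) sens[["estimate"]] / (1 - spec[["estimate"]]) else Inf
  lr_neg <- if (spec[["estimate"]] > 0) (1 - sens[["estimate"]]) / spec[["estimate"]] else NaN
  zero_cell <- any(c(tp, fn, fp, tn) == 0)
  if (zero_cell) {
    or <- or_ci <- c(NA_real_, NA_real_); or_p <- NA_real_
    or <- NA_real_; or_ci <- c(lower = NA_real_, upper = NA_real_)
  } else {
    or <- (tp * tn) / (fn * fp)
    se <- sqrt(1 / tp + 1 / fn + 1 / fp + 1 / tn)
    z <- qnorm(1 - (1 - conf_level) / 2)
    or_ci <- c(lower = exp(log(or) - z * se), upper = exp(log(or) + z * se))
    or_p <- 2 * pnorm(-abs(log(or) / se))
  }
  structure(list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
                 lr_pos = lr_pos, lr_neg = lr_neg,
                 odds_ratio = or, or_ci = or_ci,
                 or_p = if (zero_cell) NA_real_ else or_p,
                 or_estimable = !zero_cell,
                 prevalence = npos / (npos + nneg),
                 n = npos + nneg, ci_method = ci_method, table = x),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, digits = 3, ...) {
  pct <- function(v) sprintf("%.1f%% (%.1f-%.1f)", 100 * v[1], 100 * v[2], 100 * v[3])
  cat(sprintf("n = %d, prevalence = %.1f%%  [%s CI]\n", x$n,
              100 * x$prevalence, x$ci_method))
  cat("  sensitivity:", pct(x$sensitivity), "\n")
  cat("  specificity:", pct(x$specificity), "\n")
  cat(sprintf("  PPV: %.1f%%   NPV: %.1f%%\n",
              100 * x$ppv[["estimate"]], 100 * x$npv[["estimate"]]))
  cat(sprintf("  LR+: %.2f   LR-: %.2f\n", x$lr_pos, x$lr_neg))
  if (x$or_estimable)
    cat(sprintf("  OR: %.2f (%.2f-%.2f), p = %.3g\n", x$odds_ratio,
                x$or_ci[["lower"]], x$or_ci[["upper"]], x$or_p))
  else cat("  OR: non-estimable (zero cell)\n")
  invisible(x)
}

# rebuild a table from summary quantities, rounding cells to integers
.confusion_from_summary <- function(n, prevalence, sensitivity, specificity) {
  npos <- round(n * prevalence); nneg <- n - npos
  tp <- round(npos * sensitivity); tn <- round(nneg * specificity)
  confusion_table(tp = tp, fn = npos - tp, fp = nneg - tn, tn = tn)
}
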