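# Paired comparisons of two dichotomized tools on the same patients:
# McNemar chi-squared on discordant pairs, and equality of univariate
# logistic regression coefficients with pairing-robust covariance.

#' McNemar's chi-squared test for paired binary classifications
#'
#' Compares two tools' dichotomized results within a stratum of patients
#' (the condition-unfit stratum compares sensitivities, the condition-fit
#' stratum specificities). The statistic is (b - c)^2 / (b + c) over the
#' discordant counts, referred to chi-squared with 1 df, without continuity
#' correction. With no discordant pairs the statistic is 0 and p = 1.
#'
#' @param flags_a,flags_b logical test-abnormal flags per patient (already
#'   restricted to the stratum of interest).
#' @return a `paired_test_result` with `method = "mcnemar"`, discordant
#'   counts `b` (a abnormal, b normal) and `c`.
#' @export
mcnemar_paired <- function(flags_a, flags_b) {
  if (length(flags_a) != length(flags_b)) stop("flag vectors must align")
  if (!length(flags_a)) stop("empty stratum")
  if (anyNA(flags_a) || anyNA(flags_b)) stop("complete cases required")
  b <- sum(flags_a & !flags_b)
  cc <- sum(!flags_a & flags_b)
  if (b + cc == 0) {
    stat <- 0; p <- 1
  } else {
    stat <- (b - cc)^2 / (b + cc)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(method = "mcnemar", statistic = stat, p_value = p,
                 b = b, c = cc, n = length(flags_a)),
            class = "paired_test_result")
}

#' Test equality of two tools' logistic regression coefficients
#'
#' The association between each tool's abnormal flag and the unfit verdict
#' is a univariate logistic regression; this tests whether the two log odds
#' ratios are equal. The two models are fit jointly on a stacked data set
#' (each patient duplicated with a tool indicator) and the flag-by-tool
#' interaction is tested with a cluster-robust (patient-level) covariance,
#' so the within-patient pairing of the two tools is respected. A paired
#' nonparametric bootstrap of the coefficient difference is available as a
#' cross-check.
#'
#' @param abnormal_a,abnormal_b logical abnormal flags per patient.
#' @param unfit logical condition per patient.
#' @param method `"robust"` (stacked model, cluster-robust Wald) or
#'   `"bootstrap"` (patient-resampled difference of the two fits).
#' @param B bootstrap replicates for `method = "bootstrap"`.
#' @return a `paired_test_result` with `method = "coef_equality"`, the
#'   estimated log-OR difference `delta`, its standard error, `statistic`
#'   (z) and `p_value`; `estimable = FALSE` when a fit separates.
#' @export
coefficient_equality_test <- function(abnormal_a, abnormal_b, unfit,
                                      method = c("robust", "bootstrap"),
                                      B = 500) {
  method <- match.arg(method)
  n <- length(unfit)
  if (length(abnormal_a) != n || length(abnormal_b) != n)
    stop("both tools must be scored on the same patients")
  if (anyNA(abnormal_a) || anyNA(abnormal_b) || anyNA(unfit))
    stop("complete cases required")
  dat <- data.frame(
    unfit = rep(as.integer(unfit), 2),
    flag = as.integer(c(abnormal_a, abnormal_b)),
    tool = rep(c(0L, 1L), each = n),
    id = rep(seq_len(n), 2))
  fit <- suppressWarnings(
    glm(unfit ~ flag * tool, family = binomial(), data = dat))
  cf <- coef(fit)
  if (!fit$converged || any(abs(cf) > 15, na.rm = TRUE) || anyNA(cf)) {
    return(structure(list(method = "coef_equality", statistic = NA_real_,
                          p_value = NA_real_, delta = NA_real_, se = NA_real_,
                          estimable = FALSE),
                     class = "paired_test_result"))
  }
  delta <- cf[["flag:tool"]]
  if (identical(as.logical(abnormal_a), as.logical(abnormal_b))) {
    return(structure(list(method = "coef_equality", statistic = 0,
                          p_value = 1, delta = 0, se = NA_real_,
                          estimable = TRUE),
                     class = "paired_test_result"))
  }
  if (method == "robust") {
    vc <- sandwich::vcovCL(fit, cluster = dat$id)
    se <- sqrt(vc["flag:tool", "flag:tool"])
  } else {
    diffs <- replicate(B, {
      idx <- sample.int(n, n, replace = TRUE)
      fa <- suppressWarnings(glm(unfit[idx] ~ abnormal_a[idx], family = binomial()))
      fb <- suppressWarnings(glm(unfit[idx] ~ abnormal_b[idx], family = binomial()))
      ca <- coef(fa)[2]; cb <- coef(fb)[2]
      if (any(abs(c(ca, cb)) > 15)) NA_real_ else cb - ca
    })
    se <- sd(diffs, na.rm = TRUE)
  }
  if (identical(abnormal_a, abnormal_b) || se < .Machine$double.eps) {
    z <- if (abs(delta) < 1e-10) 0 else NA_real_
    p <- if (abs(delta) < 1e-10) 1 else NA_real_
  } else {
    z <- delta / se
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(method = "coef_equality", statistic = z, p_value = p,
                 delta = delta, se = se, estimable = TRUE),
            class = "paired_test_result")
}
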