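# ROC curves, AUROC via midranks (Mann-Whitney with half-credit ties),
# DeLong variance/covariance, the DeLong-Clarke-Pearson paired test,
# and cutoff-selection policies.

.as_risk <- function(scores, direction = c("higher_worse", "lower_worse")) {
  direction <- match.arg(direction)
  if (direction == "lower_worse") -scores else scores
}

# midrank placement values; risk oriented so larger = more likely unfit.
# V10[i] = Pr(risk of unfit i exceeds a random fit patient, ties 1/2)
.placements <- function(risk, unfit) {
  pos <- risk[unfit]; neg <- risk[!unfit]
  m <- length(pos); n0 <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(pos, ties.method = "average")) / n0
  v01 <- 1 - (r_all[m + seq_len(n0)] - rank(neg, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, auc = sum(v10) / m)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney concordance probability: the chance that a randomly
#' chosen unfit patient carries a more abnormal score than a randomly
#' chosen fit patient, with tied scores counting one half. `direction`
#' states the risk orientation of the score (`"lower_worse"` for the G8,
#' `"higher_worse"` for the modified G8).
#'
#' @param scores numeric score per patient.
#' @param unfit logical condition per patient (both classes required).
#' @param direction risk orientation of the score.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, unfit, direction = c("higher_worse", "lower_worse")) {
  risk <- .as_risk(scores, direction)
  .check_two_class(risk, unfit)
  .placements(risk, unfit)$auc
}

.check_two_class <- function(scores, unfit) {
  if (length(scores) != length(unfit)) stop("scores and unfit must align")
  if (anyNA(scores) || anyNA(unfit)) stop("complete cases required")
  if (!any(unfit) || all(unfit))
    stop("both classes (fit and unfit) must be present")
  invisible(TRUE)
}

#' DeLong variance of a single AUROC
#'
#' Placement-value (structural components) variance estimate; also used for
#' the AUROC confidence interval.
#'
#' @inheritParams auroc
#' @param conf_level confidence level for the returned interval.
#' @return list with `auc`, `var`, `ci`.
#' @export
auroc_ci <- function(scores, unfit, direction = c("higher_worse", "lower_worse"),
                     conf_level = 0.95) {
  risk <- .as_risk(scores, direction)
  .check_two_class(risk, unfit)
  pl <- .placements(risk, unfit)
  v <- var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, pl$auc + c(-1, 1) * z * sqrt(v)))
  list(auc = pl$auc, var = v, ci = c(lower = ci[1], upper = ci[2]))
}

#' Empirical ROC curve
#'
#' One operating point per distinct observed score, oriented so the curve
#' runs from (0, 0) to (1, 1) in (1 - specificity, sensitivity) space.
#' Reported cutoffs sit at midpoints between adjacent distinct scores
#' (infinite at the ends) on the original score scale, with the test-
#' positive rule implied by `direction` (`<= cutoff` abnormal when
#' `"lower_worse"`, `>= cutoff` when `"higher_worse"`).
#'
#' @inheritParams auroc
#' @param conf_level confidence level for the AUROC interval.
#' @return a `frail_roc`: list with `points` (data frame `cutoff`,
#'   `sensitivity`, `fpr`), `auc`, `auc_ci`, `direction`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, unfit, direction = c("higher_worse", "lower_worse"),
                      conf_level = 0.95) {
  direction <- match.arg(direction)
  risk <- .as_risk(scores, direction)
  .check_two_class(risk, unfit)
  v <- sort(unique(risk), decreasing = TRUE)
  # thresholds on the risk scale: test positive iff risk >= t
  mids <- if (length(v) > 1) (v[-1] + v[-length(v)]) / 2 else numeric(0)
  thr <- c(Inf, mids, -Inf)
  sens <- vapply(thr, function(t) mean(risk[unfit] >= t), 0)
  fpr <- vapply(thr, function(t) mean(risk[!unfit] >= t), 0)
  cutoff <- if (direction == "lower_worse") -thr else thr
  aci <- auroc_ci(scores, unfit, direction, conf_level)
  structure(list(points = data.frame(cutoff = cutoff, sensitivity = sens,
                                     fpr = fpr),
                 auc = aci$auc, auc_ci = aci$ci, direction = direction,
                 n_pos = sum(unfit), n_neg = sum(!unfit)),
            class = "frail_roc")
}

#' @export
print.frail_roc <- function(x, ...) {
  cat(sprintf("ROC: %d unfit / %d fit, %d operating points\n",
              x$n_pos, x$n_neg, nrow(x$points)))
  cat(sprintf("AUROC = %.3f (%.3f-%.3f)\n", x$auc,
              x$auc_ci[["lower"]], x$auc_ci[["upper"]]))
  invisible(x)
}

#' @export
plot.frail_roc <- function(x, add = FALSE, col = 1, ...) {
  if (!add) {
    plot(x$points$fpr, x$points$sensitivity, type = "l", col = col,
         xlab = "1 - specificity", ylab = "sensitivity",
         xlim = c(0, 1), ylim = c(0, 1), ...)
    abline(0, 1, lty = 3, col = "grey")
  } else lines(x$points$fpr, x$points$sensitivity, col = col, ...)
  invisible(x)
}

#' Trapezoidal area under a `frail_roc`
#'
#' Numerical integral of the empirical curve; equal to the Mann-Whitney
#' AUROC (ties half-credit) and used as an internal consistency check.
#'
#' @param curve a `frail_roc`.
#' @return area in \[0, 1\].
#' @export
auc_trapezoid <- function(curve) {
  stopifnot(inherits(curve, "frail_roc"))
  xx <- curve$points$fpr; yy <- curve$points$sensitivity
  sum(diff(xx) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' DeLong-Clarke-Pearson paired AUROC test
#'
#' Compares the AUROCs of two scores measured on the same patients, using
#' the placement-value covariance between the tools:
#' z = (AUC_a - AUC_b) / sqrt(var_a + var_b - 2 cov), two-sided normal
#' p-value. Also returns each tool's DeLong confidence interval.
#'
#' @param scores_a,scores_b numeric scores per patient (same patients).
#' @param unfit logical condition per patient.
#' @param direction_a,direction_b risk orientation of each score.
#' @param conf_level confidence level for per-tool AUROC intervals.
#' @return a `paired_test_result` with `method = "delong"`, fields
#'   `auc_a`, `auc_b`, `auc_ci_a`, `auc_ci_b`, `delta`, `var_delta`,
#'   `statistic` (z), `p_value`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, unfit,
                        direction_a = c("higher_worse", "lower_worse"),
                        direction_b = c("higher_worse", "lower_worse"),
                        conf_level = 0.95) {
  if (length(scores_a) != length(scores_b))
    stop("both tools must be scored on the same patients")
  ra <- .as_risk(scores_a, direction_a)
  rb <- .as_risk(scores_b, direction_b)
  .check_two_class(ra, unfit); .check_two_class(rb, unfit)
  pa <- .placements(ra, unfit); pb <- .placements(rb, unfit)
  m <- sum(unfit); n0 <- sum(!unfit)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  va <- s10[1, 1] / m + s01[1, 1] / n0
  vb <- s10[2, 2] / m + s01[2, 2] / n0
  cab <- s10[1, 2] / m + s01[1, 2] / n0
  vd <- va + vb - 2 * cab
  delta <- pa$auc - pb$auc
  degenerate <- vd <= .Machine$double.eps
  z <- if (degenerate) NA_real_ else delta / sqrt(vd)
  p <- if (degenerate) {
    if (abs(delta) < .Machine$double.eps) 1 else NA_real_
  } else 2 * pnorm(-abs(z))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- function(auc, v) pmin(1, pmax(0, auc + c(-1, 1) * zq * sqrt(v)))
  structure(list(method = "delong", auc_a = pa$auc, auc_b = pb$auc,
                 auc_ci_a = ci(pa$auc, va), auc_ci_b = ci(pb$auc, vb),
                 var_a = va, var_b = vb, cov_ab = cab,
                 delta = delta, var_delta = vd, statistic = z, p_value = p,
                 degenerate = degenerate),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("Paired test [%s]: statistic = %s, p = %s\n", x$method,
              format(x$statistic, digits = 4), format(x$p_value, digits = 4)))
  if (x$method == "delong")
    cat(sprintf("  AUC a = %.3f (%.3f-%.3f) vs AUC b = %.3f (%.3f-%.3f)\n",
                x$auc_a, x$auc_ci_a[1], x$auc_ci_a[2],
                x$auc_b, x$auc_ci_b[1], x$auc_ci_b[2]))
  invisible(x)
}

#' Select an operating cutoff from a ROC curve
#'
#' Two deterministic policies. `"youden"` (default) maximizes Youden's J
#' (sensitivity + specificity - 1) and breaks ties towards the higher
#' sensitivity. `"sens_floor"` maximizes specificity among points with
#' sensitivity >= `sens_floor` (falling back to the most sensitive point if
#' none reaches the floor) -- a cutoff policy that prioritizes sensitivity,
#' as screening applications require.
#'
#' @param curve a `frail_roc`.
#' @param policy `"youden"` or `"sens_floor"`.
#' @param sens_floor minimum sensitivity for the `"sens_floor"` policy.
#' @return one-row data frame: `cutoff`, `sensitivity`, `specificity`,
#'   `youden`.
#' @export
optimal_cutoff <- function(curve, policy = c("youden", "sens_floor"),
                           sens_floor = 0.80) {
  stopifnot(inherits(curve, "frail_roc"))
  policy <- match.arg(policy)
  pts <- curve$points
  pts$specificity <- 1 - pts$fpr
  pts$youden <- pts$sensitivity + pts$specificity - 1
  idx <- if (policy == "youden") {
    best <- pts$youden >= max(pts$youden) - 1e-12
    cand <- which(best)
    cand[which.max(pts$sensitivity[cand])]
  } else {
    ok <- which(pts$sensitivity >= sens_floor)
    if (!length(ok)) which.max(pts$sensitivity)
    else ok[which.max(pts$specificity[ok])]
  }
  pts[idx, c("cutoff", "sensitivity", "specificity", "youden")]
}
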