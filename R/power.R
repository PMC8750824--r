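# Monte-Carlo power for the paired DeLong AUROC comparison under a
# binormal paired-scores model.

#' Power of the paired DeLong test under a binormal model
#'
#' Simulates paired screening scores for two tools under a binormal model:
#' fit patients' scores are standard bivariate normal, unfit patients'
#' scores are shifted by mu_t = sqrt(2) * qnorm(auc_t) for tool t, and the
#' two tools share a within-class score correlation. Each replicate draws a
#' cohort of size `n` with the given unfit prevalence, runs [delong_test()],
#' and power is the rejection fraction at level `alpha`. A vector
#' `correlation` returns the power-correlation profile.
#'
#' @param n cohort size per replicate.
#' @param auc_a,auc_b true AUROCs (0.5 <= auc < 1).
#' @param prevalence unfit prevalence (0 < prevalence < 1).
#' @param correlation within-class score correlation between the tools;
#'   may be a vector to profile power over correlations.
#' @param alpha two-sided significance level.
#' @param reps Monte-Carlo replicates per correlation value.
#' @param seed integer seed for reproducibility.
#' @return data frame with `correlation`, `power`, `mc_se`, `reps`, `n`.
#' @export
power_paired_auroc <- function(n, auc_a, auc_b, prevalence, correlation,
                               alpha = 0.05, reps = 1000, seed = 1L) {
  stopifnot(auc_a >= 0.5, auc_a < 1, auc_b >= 0.5, auc_b < 1,
            prevalence > 0, prevalence < 1,
            all(correlation > -1), all(correlation < 1))
  mu_a <- sqrt(2) * qnorm(auc_a)
  mu_b <- sqrt(2) * qnorm(auc_b)
  out <- lapply(correlation, function(rho) {
    set.seed(seed + round(1e4 * rho))
    rej <- vapply(seq_len(reps), function(i) {
      repeat {
        npos <- rbinom(1, n, prevalence)
        if (npos > 1 && npos < n - 1) break
      }
      z1 <- rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
      unfit <- c(rep(TRUE, npos), rep(FALSE, n - npos))
      sa <- z1 + ifelse(unfit, mu_a, 0)
      sb <- z2 + ifelse(unfit, mu_b, 0)
      tst <- delong_test(sa, sb, unfit)
      isTRUE(tst$p_value < alpha)
    }, logical(1))
    p <- mean(rej)
    data.frame(correlation = rho, power = p,
               mc_se = sqrt(p * (1 - p) / reps), reps = reps, n = n)
  })
  do.call(rbind, out)
}
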