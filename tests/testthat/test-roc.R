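test_that("AUROC edge cases: perfect separation, pure ties, orientation", {
  unfit <- rep(c(TRUE, FALSE), each = 5)
  expect_equal(auroc(c(6:10, 1:5), unfit), 1)
  expect_equal(auroc(rep(3, 10), unfit), 0.5)
  # G8 orientation: lower scores are the risky ones
  expect_equal(auroc(c(1:5, 6:10), unfit, "lower_worse"), 1)
  expect_error(auroc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUROC equals the brute-force pairwise oracle, with ties", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(8:50, 1)
    scores <- sample(0:12, n, replace = TRUE)   # heavy ties
    unfit <- runif(n) < 0.6
    if (!any(unfit)) unfit[1] <- TRUE
    if (all(unfit)) unfit[1] <- FALSE
    expect_equal(auroc(scores, unfit), oracle_auc(scores, unfit),
                 tolerance = 1e-13)
  }
})

test_that("ROC curve runs (0,0) to (1,1), is monotone, trapezoid = Mann-Whitney", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 17, 0.5), n, replace = TRUE)
    unfit <- runif(n) < 0.5
    if (!any(unfit)) unfit[1] <- TRUE
    if (all(unfit)) unfit[1] <- FALSE
    cv <- roc_curve(scores, unfit, "lower_worse")
    pts <- cv$points
    expect_equal(c(pts$fpr[1], pts$sensitivity[1]), c(0, 0))
    expect_equal(c(pts$fpr[nrow(pts)], pts$sensitivity[nrow(pts)]), c(1, 1))
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$sensitivity) >= 0))
    expect_equal(auc_trapezoid(cv), cv$auc, tolerance = 1e-12)
    # each interior cutoff reproduces its printed operating point
    j <- sample(2:(nrow(pts) - 1), 1)
    abn <- scores <= pts$cutoff[j]
    expect_equal(mean(abn[unfit]), pts$sensitivity[j])
    expect_equal(mean(abn[!unfit]), pts$fpr[j])
  }
})

test_that("AUROC and DeLong variance agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(47)
  for (i in 1:10) {
    n <- sample(30:80, 1)
    unfit <- runif(n) < 0.5
    if (!any(unfit)) unfit[1] <- TRUE
    if (all(unfit)) unfit[1] <- FALSE
    sa <- rnorm(n) + 1.2 * unfit
    sb <- sample(0:20, n, replace = TRUE) + 4 * unfit
    ra <- suppressMessages(pROC::roc(unfit, sa, direction = "<", quiet = TRUE))
    rb <- suppressMessages(pROC::roc(unfit, sb, direction = "<", quiet = TRUE))
    expect_equal(auroc(sa, unfit), as.numeric(pROC::auc(ra)), tolerance = 1e-12)
    ci <- auroc_ci(sa, unfit)
    expect_equal(unname(ci$ci),
                 as.numeric(pROC::ci.auc(ra, method = "delong"))[c(1, 3)],
                 tolerance = 1e-10)
    tst <- delong_test(sa, sb, unfit)
    ref <- pROC::roc.test(ra, rb, method = "delong", quiet = TRUE)
    expect_equal(tst$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("DeLong placements match hand enumeration on a small fixture", {
  scores_a <- c(3, 5, 5, 8, 1, 2, 5, 9, 4, 7)
  scores_b <- c(2, 6, 4, 9, 2, 1, 6, 8, 3, 6)
  unfit <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  pl <- frailscreen:::.placements(scores_a, unfit)
  or <- oracle_placements(scores_a, unfit)
  expect_equal(pl$v10, or$v10)
  expect_equal(pl$v01, or$v01)
  expect_equal(pl$auc, mean(or$v10))
  # paired variance from explicit covariance of the oracle placements
  pla <- oracle_placements(scores_a, unfit); plb <- oracle_placements(scores_b, unfit)
  va <- var(pla$v10) / 5 + var(pla$v01) / 5
  vb <- var(plb$v10) / 5 + var(plb$v01) / 5
  cab <- cov(pla$v10, plb$v10) / 5 + cov(pla$v01, plb$v01) / 5
  tst <- delong_test(scores_a, scores_b, unfit)
  expect_equal(tst$var_delta, va + vb - 2 * cab)
  expect_equal(tst$statistic,
               (mean(pla$v10) - mean(plb$v10)) / sqrt(va + vb - 2 * cab))
})

test_that("identical scores give a null DeLong comparison", {
  set.seed(53)
  s <- rnorm(40); unfit <- rep(c(TRUE, FALSE), 20)
  tst <- delong_test(s, s, unfit)
  expect_equal(tst$delta, 0)
  expect_equal(tst$p_value, 1)
})

test_that("DeLong variance of one AUROC tracks the bootstrap variance", {
  set.seed(59)
  n <- 500
  unfit <- runif(n) < 0.6
  scores <- rnorm(n) + 1.1 * unfit
  v_delong <- auroc_ci(scores, unfit)$var
  boots <- replicate(2000, {
    idx <- sample.int(n, n, replace = TRUE)
    if (!any(unfit[idx]) || all(unfit[idx])) return(NA_real_)
    auroc(scores[idx], unfit[idx])
  })
  v_boot <- var(boots, na.rm = TRUE)
  expect_lt(abs(v_delong - v_boot) / v_boot, 0.10)
})

test_that("cutoff selection policies are deterministic and documented", {
  mk_curve <- function(cutoff, sens, fpr) {
    structure(list(points = data.frame(cutoff = cutoff, sensitivity = sens,
                                       fpr = fpr),
                   auc = NA, auc_ci = c(lower = NA, upper = NA),
                   direction = "higher_worse", n_pos = 10, n_neg = 10),
              class = "frail_roc")
  }
  # a strictly dominating interior point wins under both policies
  cv <- mk_curve(c(Inf, 5, 3, -Inf), c(0, 0.9, 0.95, 1), c(0, 0.1, 0.3, 1))
  expect_equal(optimal_cutoff(cv, "youden")$cutoff, 5)
  expect_equal(optimal_cutoff(cv, "sens_floor", sens_floor = 0.8)$cutoff, 5)
  # tie on Youden's J: the more sensitive point is returned
  cv2 <- mk_curve(c(Inf, 7, 4, -Inf), c(0, 0.7, 0.9, 1), c(0, 0.1, 0.3, 1))
  expect_equal(optimal_cutoff(cv2, "youden")$cutoff, 4)
  expect_equal(optimal_cutoff(cv2, "youden")$sensitivity, 0.9)
  # Youden optimum and sensitivity-prioritized cutoffs can differ
  cv3 <- mk_curve(c(Inf, 8, 5, -Inf), c(0, 0.75, 0.92, 1), c(0, 0.05, 0.35, 1))
  expect_equal(optimal_cutoff(cv3, "youden")$cutoff, 8)
  expect_equal(optimal_cutoff(cv3, "sens_floor", sens_floor = 0.9)$cutoff, 5)
})

test_that("McNemar: closed form, symmetry, degenerate agreement", {
  a <- rep(c(TRUE, TRUE, FALSE, FALSE), c(30, 10, 2, 8))
  b <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 2, 8))
  tst <- mcnemar_paired(a, b)
  expect_equal(tst$statistic, 16 / 3, tolerance = 1e-12)
  expect_equal(tst$p_value, pchisq(16 / 3, 1, lower.tail = FALSE))
  expect_equal(round(tst$p_value, 3), 0.021)
  expect_equal(mcnemar_paired(b, a)$p_value, tst$p_value)
  expect_equal(mcnemar_paired(a, a)$p_value, 1)
  bal <- mcnemar_paired(rep(c(TRUE, FALSE), c(5, 5)), rep(c(FALSE, TRUE), c(5, 5)))
  expect_equal(bal$statistic, 0)
  # cross-check against the standard implementation (no correction)
  ref <- mcnemar.test(table(a, b), correct = FALSE)
  expect_equal(tst$p_value, ref$p.value)
})
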