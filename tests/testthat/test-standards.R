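test_that("GA impairment-count standard follows k and signals exclusions", {
  co <- fit_cohort(3)
  co$adl[2] <- 5                      # exactly one impairment
  co$adl[3] <- 5; co$mmse[3] <- 20    # two impairments
  r1 <- classify_ga_count(ga_cohort(co), k = 1)
  r2 <- classify_ga_count(ga_cohort(co), k = 2)
  expect_equal(r1$unfit, c(FALSE, TRUE, TRUE))
  expect_equal(r2$unfit, c(FALSE, FALSE, TRUE))
  co$mna[1] <- NA
  r <- classify_ga_count(ga_cohort(co), k = 1)
  expect_true(is.na(r$unfit[1]))
  expect_match(r$excluded_reason[1], "incomplete")
})

test_that("intervention standard: any prescribed intervention means unfit", {
  co <- fit_cohort(3)
  co$intervention_nutritional[1] <- TRUE
  co$intervention_treatment_adaptation[3] <- TRUE
  r <- classify_intervention(ga_cohort(co))
  expect_equal(r$unfit, c(TRUE, FALSE, TRUE))
  expect_match(r$detail[1], "nutritional")
  expect_match(r$detail[3], "treatment_adaptation")
})

test_that("Balducci: fit requires independence, low comorbidity and no syndromes", {
  co <- fit_cohort(4)
  co$syndrome_falls[2] <- TRUE        # only deficit: falls
  co$iadl[3] <- 7                     # IADL dependence
  co$cirs_g_max_grade[4] <- 3         # severe comorbidity, no syndrome
  r <- classify_balducci(ga_cohort(co))
  expect_equal(r$unfit, c(FALSE, TRUE, TRUE, TRUE))
  expect_match(r$detail[2], "geriatric_syndrome")
  expect_match(r$detail[3], "iadl_dependent")
  # literal conjunctive reading: comorbidity alone or a syndrome alone
  # stays fit (the comorbidity-and-syndrome pair is required)
  rl <- classify_balducci(ga_cohort(co), rule = "literal")
  expect_equal(rl$unfit, c(FALSE, FALSE, TRUE, FALSE))
  co$cirs_g_max_grade[2] <- 3   # falls + severe comorbidity: now unfit
  expect_true(classify_balducci(ga_cohort(co), rule = "literal")$unfit[2])
  # rule-trace completeness: unfit rows name a criterion, fit rows none
  expect_true(all(nchar(gsub("criteria=\\{|\\}", "", r$detail[r$unfit])) > 0))
  expect_true(all(gsub("criteria=\\{|\\}", "", r$detail[!r$unfit]) == ""))
})

test_that("SIOG: weight-loss, IADL-mode and comorbidity rules", {
  co <- fit_cohort(3)
  co$weight_loss_1mo_pct[1] <- 5.0    # >= 5% in one month: unfit
  r <- classify_siog(ga_cohort(co))
  expect_equal(r$unfit, c(TRUE, FALSE, FALSE))
  expect_match(r$detail[1], "malnutrition")

  m <- fit_cohort(2)
  m$sex <- "male"; m$iadl <- 7; m$iadl4 <- 3
  expect_true(all(classify_siog(ga_cohort(m), iadl_mode = "sex_specific")$unfit))
  expect_true(all(classify_siog(ga_cohort(m), iadl_mode = "uniform8")$unfit))
  # male with iadl4 = 4 but iadl = 7: sex-specific mode is the lenient one
  m2 <- fit_cohort(1); m2$sex <- "male"; m2$iadl <- 7; m2$iadl4 <- 4
  expect_false(classify_siog(ga_cohort(m2), iadl_mode = "sex_specific")$unfit)
  expect_true(classify_siog(ga_cohort(m2), iadl_mode = "uniform8")$unfit)
  # boundary: 4.9%/9.9% losses stay fit
  co2 <- fit_cohort(1)
  co2$weight_loss_1mo_pct <- 4.9; co2$weight_loss_6mo_pct <- 9.9
  expect_false(classify_siog(ga_cohort(co2))$unfit)
  co2$weight_loss_6mo_pct <- 10
  expect_true(classify_siog(ga_cohort(co2))$unfit)
})

test_that("LCT posterior: symmetry, dominance, and softmax oracle", {
  co <- ga_cohort(fit_cohort(1))
  eq4 <- structure(list(classes = lapply(1:4, function(k)
    list(name = paste0("c", k), intercept = 0, coef = c()))),
    class = "lct_config")
  post <- lct_posterior(co, eq4)
  expect_equal(as.numeric(post), rep(0.25, 4))
  expect_true(classify_lct(co, eq4)$unfit)   # 0.25 < 0.5

  dom <- eq4; dom$classes[[1]]$intercept <- 10
  expect_false(classify_lct(co, dom)$unfit)
  expect_gt(lct_posterior(co, dom)[1, 1], 0.99)

  # random configs vs direct exp/normalize computation
  set.seed(9)
  for (i in 1:10) {
    cfg <- structure(list(classes = lapply(1:3, function(k)
      list(name = paste0("c", k), intercept = rnorm(1),
           coef = c(mmse = rnorm(1, 0, 0.1), adl = rnorm(1))))),
      class = "lct_config")
    r <- ga_cohort(fit_record())
    r$mmse <- sample(0:30, 1); r$adl <- sample(seq(0, 6, 0.5), 1)
    lp <- vapply(cfg$classes, function(cl)
      cl$intercept + cl$coef[["mmse"]] * r$mmse + cl$coef[["adl"]] * r$adl, 0)
    expect_equal(as.numeric(lct_posterior(r, cfg)), exp(lp) / sum(exp(lp)),
                 tolerance = 1e-12)
  }
  # config referencing an absent field errors and names it
  bad <- eq4; bad$classes[[2]]$coef <- c(nonexistent_field = 1)
  expect_error(lct_posterior(co, bad), "nonexistent_field")
})

test_that("LCT configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("classes:",
               "  - name: c1", "    intercept: 0", "    coef: {}",
               "  - name: c2", "    intercept: 2.5",
               "    coef: {mna: -0.1}"), path)
  cfg <- load_lct_config(path)
  co <- ga_cohort(fit_record())          # mna = 27
  post <- lct_posterior(co, cfg)
  lp2 <- 2.5 - 0.1 * 27
  expect_equal(as.numeric(post), c(1, exp(lp2)) / (1 + exp(lp2)))
})

test_that("frailty index: ratio of deficits present to assessed, cutoff 0.3", {
  co <- fit_cohort(4, n_deficits = 52)
  dcols <- paste0("deficit_", 1:52)
  co[2, dcols] <- 1                                  # all deficits
  co[3, dcols] <- c(rep(1, 16), rep(0, 36))          # 16/52 = 0.308
  co[4, dcols] <- c(rep(1, 13), rep(0, 13), rep(NA, 26))  # 13/26 = 0.5
  spec <- frailty_index_spec(min_assessed_fraction = 0.5)
  r <- compute_frailty_index(ga_cohort(co), spec)
  expect_equal(r$unfit, c(FALSE, TRUE, TRUE, TRUE))
  expect_match(r$detail[1], "fi=0.0000")
  expect_match(r$detail[2], "fi=1.0000")
  expect_match(r$detail[4], "fi=0.5000")
  # 15/52 = 0.288 stays fit
  co[3, dcols] <- c(rep(1, 15), rep(0, 37))
  r2 <- compute_frailty_index(ga_cohort(co), spec)
  expect_false(r2$unfit[3])
  # default min_assessed_fraction 0.8 excludes the half-missing patient
  r3 <- compute_frailty_index(ga_cohort(co))
  expect_true(is.na(r3$unfit[4]))
  expect_match(r3$excluded_reason[4], "too few")
  expect_warning(frailty_index_spec(n_deficits = 20), "at least 30")
})

test_that("every classifier is monotone: added deficits never flip unfit to fit", {
  set.seed(21)
  degrade <- function(co) {
    co <- as.data.frame(co)
    pick <- sample(c("adl", "iadl", "cirs", "syn", "wl", "mna", "gds"), 1)
    switch(pick,
           adl = co$adl <- max(0, co$adl - sample(1:4, 1) * 0.5),
           iadl = co$iadl <- max(0, co$iadl - sample(1:4, 1)),
           cirs = co$cirs_g_max_grade <- min(4, co$cirs_g_max_grade + 1),
           syn = co[[sample(grep("^syndrome_", names(co), value = TRUE), 1)]] <- TRUE,
           wl = co$weight_loss_1mo_pct <- min(40, co$weight_loss_1mo_pct + 6),
           mna = co$mna <- max(0, co$mna - 5),
           gds = co$mini_gds <- min(4, co$mini_gds + 2))
    co
  }
  for (i in 1:25) {
    r <- fit_record(n_deficits = 52)
    r$adl <- sample(seq(3, 6, 0.5), 1); r$iadl <- sample(4:8, 1)
    r$cirs_g_max_grade <- sample(0:4, 1); r$mna <- sample(seq(15, 30, 0.5), 1)
    r[paste0("deficit_", 1:52)] <- as.list(rbinom(52, 1, 0.35))
    worse <- degrade(r)
    for (st in c("ga1", "ga2", "balducci", "siog")) {
      before <- classify_standard(ga_cohort(r), st)$unfit
      after <- classify_standard(ga_cohort(worse), st)$unfit
      if (isTRUE(before)) expect_true(after, label = paste(st, "monotone"))
    }
    # frailty index: setting one extra deficit never lowers the index
    r$deficit_3 <- 0; worse_fi <- r; worse_fi$deficit_3 <- 1
    fi_b <- classify_standard(ga_cohort(r), "frailty_index")$unfit
    fi_a <- classify_standard(ga_cohort(worse_fi), "frailty_index")$unfit
    if (isTRUE(fi_b)) expect_true(fi_a)
  }
})

test_that("ga1 prevalence on a simulated cohort matches the analytic value", {
  spec <- cohort_sim_spec(n = 20000, seed = 303)
  co <- generate_cohort(spec)
  target <- sim_ga1_prevalence(spec)
  got <- mean(classify_ga_count(co, 1)$unfit)
  mc_se <- sqrt(target * (1 - target) / spec$n)
  expect_lt(abs(got - target), 3 * mc_se)
})
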