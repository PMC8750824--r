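test_that("cohort CSV round-trips and validates", {
  co <- ga_cohort(fit_cohort(3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_s3_class(back, "ga_cohort")
  expect_equal(nrow(back), 3)
  expect_equal(back$patient_id, co$patient_id)
  expect_equal(back$adl, co$adl)
  expect_equal(back$syndrome_falls, co$syndrome_falls)
})

test_that("unparseable and missing cells become NA with a warning", {
  df <- fit_cohort(2)
  path <- withr::local_tempfile(fileext = ".csv")
  df$mmse <- c("28", "not a number")
  write.csv(df, path, row.names = FALSE, na = "")
  expect_warning(co <- read_cohort(path), "mmse")
  expect_true(is.na(co$mmse[2]))
  expect_equal(co$mmse[1], 28)
})

test_that("out-of-range values and identity problems are hard errors", {
  df <- fit_cohort(2)
  df$mmse[2] <- 35
  expect_error(ga_cohort(df), "mmse.*row.*2|row.*2.*mmse")
  df2 <- fit_cohort(2)
  df2$patient_id <- c("a", "a")
  expect_error(ga_cohort(df2), "duplicated")
  df3 <- fit_cohort(1)
  df3$patient_id <- NULL
  expect_error(ga_cohort(df3), "patient_id")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), path, row.names = FALSE)
  expect_error(read_cohort(path), "id column")
})

test_that("the seven impairment thresholds flip at their printed boundaries", {
  # (field, impaired value, fit value, flag) straddling each cutoff
  cases <- list(
    list("adl", 5, 5.5, "adl_impaired"),
    list("iadl", 7, 8, "iadl_impaired"),
    list("tug_seconds", 20.5, 20, "tug_impaired"),   # strict > 20
    list("mmse", 23, 24, "mmse_impaired"),
    list("mini_gds", 1, 0, "gds_impaired"),
    list("mna", 23.5, 24, "mna_impaired"),
    list("cirs_g_max_grade", 3, 2, "cirs_impaired"))
  for (cs in cases) {
    bad <- fit_record("imp"); bad[[cs[[1]]]] <- cs[[2]]
    ok <- fit_record("fit"); ok[[cs[[1]]]] <- cs[[3]]
    prof <- impairment_profile(ga_cohort(rbind(bad, ok)))
    expect_true(prof[[cs[[4]]]][1], label = paste(cs[[1]], "impaired side"))
    expect_false(prof[[cs[[4]]]][2], label = paste(cs[[1]], "fit side"))
    # exactly one flag flipped
    expect_equal(prof$n_impaired, c(1, 0))
    expect_equal(prof$n_assessed, c(7, 7))
  }
})

test_that("a fully fit record has no impairments; enumerated boundary combos count correctly", {
  prof <- impairment_profile(ga_cohort(fit_record()))
  expect_equal(prof$n_impaired, 0)
  expect_equal(prof$n_assessed, 7)

  r <- fit_record(); r$adl <- 5; r$mmse <- 23
  expect_equal(impairment_profile(ga_cohort(r))$n_impaired, 2)

  # hand-coded oracle over all 2^7 boundary combinations
  bounds_bad <- list(adl = 5, iadl = 7, tug_seconds = 21, mmse = 23,
                     mini_gds = 1, mna = 23.5, cirs_g_max_grade = 3)
  for (rep_i in 1:20) {
    pick <- runif(7) < 0.5
    r <- fit_record()
    for (j in which(pick)) r[[names(bounds_bad)[j]]] <- bounds_bad[[j]]
    expect_equal(impairment_profile(ga_cohort(r))$n_impaired, sum(pick))
  }
})

test_that("missing domains are excluded from the count, not imputed", {
  r <- fit_record(); r$mna <- NA; r$adl <- 5
  prof <- impairment_profile(ga_cohort(r))
  expect_true(is.na(prof$mna_impaired))
  expect_equal(prof$n_impaired, 1)
  expect_equal(prof$n_assessed, 6)
  # TUG 'unable' flag counts as impaired even without a time
  r2 <- fit_record(); r2$tug_seconds <- NA; r2$tug_unable <- TRUE
  expect_true(impairment_profile(ga_cohort(r2))$tug_impaired)
})

test_that("worsening any single domain never decreases n_impaired", {
  set.seed(11)
  worsen <- list(adl = function(v) max(0, v - 0.5),
                 iadl = function(v) max(0, v - 1),
                 tug_seconds = function(v) v + 5,
                 mmse = function(v) max(0, v - 3),
                 mini_gds = function(v) min(4, v + 1),
                 mna = function(v) max(0, v - 2),
                 cirs_g_max_grade = function(v) min(4, v + 1))
  for (i in 1:40) {
    r <- fit_record()
    r$adl <- sample(seq(0, 6, 0.5), 1); r$iadl <- sample(0:8, 1)
    r$tug_seconds <- runif(1, 5, 40); r$mmse <- sample(0:30, 1)
    r$mini_gds <- sample(0:4, 1); r$mna <- sample(seq(0, 30, 0.5), 1)
    r$cirs_g_max_grade <- sample(0:4, 1)
    base <- impairment_profile(ga_cohort(r))$n_impaired
    f <- sample(names(worsen), 1)
    r2 <- r; r2[[f]] <- worsen[[f]](r[[f]])
    expect_gte(impairment_profile(ga_cohort(r2))$n_impaired, base)
  }
})
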