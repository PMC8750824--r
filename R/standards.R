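# The seven fit/unfit reference standards.
#
# Each classifier returns one row per patient with a logical `unfit`
# verdict, a `detail` payload sufficient to re-derive it, and an explicit
# `excluded_reason` (never a silent drop) when required fields are missing.

.std_result <- function(patient_id, standard, unfit, detail,
                        excluded_reason = NA_character_) {
  data.frame(patient_id = patient_id, standard = standard, unfit = unfit,
             detail = detail, excluded_reason = excluded_reason,
             stringsAsFactors = FALSE)
}

#' Classify by GA impairment count
#'
#' Reference standards 1 and 2: unfit when at least `k` of the seven GA
#' domains are impaired (`k = 1` or `2`). Complete-case: patients with any
#' unassessed domain are excluded with a reason, since their impairment
#' count is not comparable.
#'
#' @param cohort a `ga_cohort` (or the output of [impairment_profile()]).
#' @param k impairment-count threshold, 1 or 2.
#' @return standard-result data frame (`patient_id`, `standard`, `unfit`,
#'   `detail`, `excluded_reason`).
#' @export
classify_ga_count <- function(cohort, k = 1) {
  stopifnot(k %in% c(1, 2))
  prof <- if (!is.null(cohort$n_assessed)) cohort else impairment_profile(cohort)
  complete <- prof$n_assessed == 7
  unfit <- ifelse(complete, prof$n_impaired >= k, NA)
  .std_result(prof$patient_id, paste0("ga", k), unfit,
              detail = sprintf("n_impaired=%d/%d", prof$n_impaired, prof$n_assessed),
              excluded_reason = ifelse(complete, NA_character_,
                                       "incomplete GA (fewer than 7 domains assessed)"))
}

#' Classify by prescribed geriatric interventions
#'
#' Reference standard 3: unfit when the geriatrician prescribed at least one
#' intervention among the five considered domains (nutritional, home,
#' neuropsychological, social support, anticancer-treatment adaptation).
#' A patient with at least one TRUE flag is unfit even if other flags are
#' missing; a patient with no TRUE flag and any missing flag is excluded.
#'
#' @param cohort a `ga_cohort`.
#' @return standard-result data frame.
#' @export
classify_intervention <- function(cohort) {
  cohort <- ga_cohort(cohort)
  m <- as.matrix(cohort[, .intervention_fields])
  any_true <- rowSums(m, na.rm = TRUE) > 0
  any_na <- rowSums(is.na(m)) > 0
  unfit <- ifelse(any_true, TRUE, ifelse(any_na, NA, FALSE))
  fired <- apply(m, 1, function(r)
    paste(sub("^intervention_", "", .intervention_fields[which(r)]), collapse = "+"))
  .std_result(cohort$patient_id, "intervention", unfit,
              detail = sprintf("interventions={%s}", fired),
              excluded_reason = ifelse(is.na(unfit), "intervention flags missing",
                                       NA_character_))
}

.collapse_criteria <- function(mat) {
  apply(mat, 1, function(r) {
    if (anyNA(r)) return(NA_character_)
    paste(colnames(mat)[which(r)], collapse = "+")
  })
}

#' Classify by the Balducci expert rules
#'
#' Reference standard 5. Fit patients are functionally independent (no ADL
#' or IADL dependence), free of serious comorbidity (all CIRS-G grades
#' <= 2) and free of geriatric syndromes (dementia, delirium, depression,
#' urinary/fecal incontinence, falls within 6 months). The default rule
#' classifies unfit as the complement of fit (disjunction of the four
#' criteria). `rule = "literal"` instead requires a severe comorbidity to be
#' accompanied by a geriatric syndrome, an alternative conjunctive reading
#' of the unfit side of the definition.
#'
#' @param cohort a `ga_cohort`.
#' @param rule `"complement"` (default) or `"literal"`.
#' @return standard-result data frame.
#' @export
classify_balducci <- function(cohort, rule = c("complement", "literal")) {
  rule <- match.arg(rule)
  cohort <- ga_cohort(cohort)
  syn <- as.matrix(cohort[, .syndrome_fields])
  any_syndrome <- ifelse(rowSums(syn, na.rm = TRUE) > 0, TRUE,
                         ifelse(rowSums(is.na(syn)) > 0, NA, FALSE))
  crit <- cbind(adl_dependent  = cohort$adl <= 5,
                iadl_dependent = cohort$iadl <= 7,
                severe_comorbidity = cohort$cirs_g_max_grade >= 3,
                geriatric_syndrome = any_syndrome)
  unfit <- if (rule == "complement") {
    crit[, 1] | crit[, 2] | crit[, 3] | crit[, 4]
  } else {
    crit[, 1] | crit[, 2] | (crit[, 3] & crit[, 4])
  }
  missing_any <- rowSums(is.na(crit)) > 0
  unfit[missing_any] <- NA
  .std_result(cohort$patient_id, "balducci", unfit,
              detail = sprintf("criteria={%s}", .collapse_criteria(crit)),
              excluded_reason = ifelse(missing_any,
                                       "missing ADL/IADL/CIRS-G/syndrome data",
                                       NA_character_))
}

#' Classify by the SIOG task-force rules
#'
#' Reference standard 6. Unfit when dependent in ADL (<= 5/6) or IADL,
#' and/or carrying a severe comorbidity (CIRS-G grade 3 or 4), and/or
#' malnourished (weight loss >= 5% in the last month and/or >= 10% within
#' the last 6 months). IADL dependence has two categorizations:
#' `"uniform8"` uses IADL <= 7/8 for everyone; `"sex_specific"` uses
#' <= 7/8 for women and the four-item scale <= 3/4 for men (requires
#' `iadl4` and `sex`).
#'
#' @param cohort a `ga_cohort`.
#' @param iadl_mode `"uniform8"` (default) or `"sex_specific"`.
#' @return standard-result data frame.
#' @export
classify_siog <- function(cohort, iadl_mode = c("uniform8", "sex_specific")) {
  iadl_mode <- match.arg(iadl_mode)
  cohort <- ga_cohort(cohort)
  iadl_dep <- if (iadl_mode == "uniform8") {
    cohort$iadl <= 7
  } else {
    ifelse(is.na(cohort$sex), NA,
           ifelse(cohort$sex == "male", cohort$iadl4 <= 3, cohort$iadl <= 7))
  }
  wl1 <- cohort$weight_loss_1mo_pct
  wl6 <- cohort$weight_loss_6mo_pct
  # malnutrition is a disjunction: one TRUE branch decides even if the
  # other is missing
  malnut <- ifelse(!is.na(wl1) & wl1 >= 5, TRUE,
            ifelse(!is.na(wl6) & wl6 >= 10, TRUE,
            ifelse(is.na(wl1) | is.na(wl6), NA, FALSE)))
  crit <- cbind(adl_dependent  = cohort$adl <= 5,
                iadl_dependent = iadl_dep,
                severe_comorbidity = cohort$cirs_g_max_grade >= 3,
                malnutrition = malnut)
  unfit <- rowSums(crit, na.rm = TRUE) > 0
  missing_any <- rowSums(is.na(crit)) > 0
  unfit[missing_any & !unfit] <- NA   # a TRUE criterion decides despite NAs
  excl <- is.na(unfit)
  .std_result(cohort$patient_id, "siog", unfit,
              detail = sprintf("criteria={%s}", .collapse_criteria(crit)),
              excluded_reason = ifelse(excl, "missing ADL/IADL/CIRS-G/weight-loss data",
                                       NA_character_))
}

#' Toy latent-class-typology scoring config
#'
#' The latent class typology classifies a patient as fit when the posterior
#' probability of membership in class 1 (relatively healthy) is at least
#' 50%. The published scoring equations are not redistributable; this toy
#' config (four classes, linear predictors over ADL, IADL, MMSE, mini-GDS
#' and MNA) exercises the scorer with the right structure and a sensible
#' orientation (healthier values push towards class 1) for tests and
#' simulated cohorts. Supply your own config for real analyses.
#'
#' @return an `lct_config`: list with a `classes` list, each class holding
#'   `name`, `intercept` and a named `coef` vector over cohort fields.
#' @export
lct_toy_config <- function() {
  structure(list(classes = list(
    list(name = "class1_relatively_healthy", intercept = 0, coef = c()),
    list(name = "class2_malnourished", intercept = 12.0,
         coef = c(mna = -0.55, adl = -0.15)),
    list(name = "class3_cognitive_mood", intercept = 10.0,
         coef = c(mmse = -0.35, mini_gds = 0.60, iadl = -0.25)),
    list(name = "class4_globally_impaired", intercept = 16.0,
         coef = c(adl = -1.15, iadl = -0.55, mmse = -0.16, mna = -0.14))
  )), class = "lct_config")
}

#' Load a latent-class scoring config from YAML
#'
#' @param path YAML file with a `classes` list (`name`, `intercept`,
#'   `coef` mapping of cohort field to coefficient).
#' @return an `lct_config`.
#' @export
load_lct_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$classes <- lapply(cfg$classes, function(cl) {
    cl$coef <- if (length(cl$coef)) unlist(cl$coef) else c()
    cl
  })
  structure(cfg[c("classes")], class = "lct_config")
}

#' Posterior class probabilities for a latent-class typology
#'
#' Evaluates each class's configured linear predictor on the cohort fields
#' and normalizes via the multinomial-logit (softmax) transform. Rows with
#' missing values in any referenced field get NA posteriors.
#'
#' @param cohort a `ga_cohort`.
#' @param config an `lct_config` ([lct_toy_config()] or [load_lct_config()]).
#' @return matrix, one row per patient, one column per class; rows sum to 1.
#' @export
lct_posterior <- function(cohort, config = lct_toy_config()) {
  stopifnot(inherits(config, "lct_config"))
  cohort <- ga_cohort(cohort)
  fields <- unique(unlist(lapply(config$classes, function(cl) names(cl$coef))))
  missing_cols <- setdiff(fields, names(cohort))
  if (length(missing_cols))
    stop("lct config references field(s) absent from the cohort: ",
         paste(missing_cols, collapse = ", "))
  lp <- vapply(config$classes, function(cl) {
    v <- rep(cl$intercept, nrow(cohort))
    for (f in names(cl$coef)) v <- v + cl$coef[[f]] * cohort[[f]]
    v
  }, numeric(nrow(cohort)))
  lp <- matrix(lp, nrow = nrow(cohort))
  colnames(lp) <- vapply(config$classes, `[[`, "", "name")
  # stabilized softmax
  m <- apply(lp, 1, max)
  e <- exp(lp - m)
  post <- e / rowSums(e)
  rownames(post) <- cohort$patient_id
  post
}

#' Classify by latent-class-typology posterior
#'
#' Reference standard 4: fit when P(class 1) >= 0.5, unfit when < 0.5.
#'
#' @inheritParams lct_posterior
#' @return standard-result data frame; `detail` carries the class-1
#'   posterior probability.
#' @export
classify_lct <- function(cohort, config = lct_toy_config()) {
  post <- lct_posterior(cohort, config)
  p1 <- post[, 1]
  unfit <- p1 < 0.5
  .std_result(ga_cohort(cohort)$patient_id, "lct", unfit,
              detail = sprintf("p_class1=%.4f", p1),
              excluded_reason = ifelse(is.na(unfit),
                                       "missing fields required by LCT scoring",
                                       NA_character_))
}

#' Frailty-index specification
#'
#' Settings for the Rockwood cumulative-deficit frailty index: the number
#' of deficit indicators combined (each coded in \[0, 1\], graded codings
#' allowed), the fit/unfit cutoff on the index, and the minimum fraction of
#' deficits that must be assessed for the index to be computed. Searle's
#' construction guidance recommends at least 30 deficits; fewer triggers a
#' warning, not an error.
#'
#' @param n_deficits number of deficit columns (`deficit_1`..`deficit_n`).
#' @param cutoff unfit when index >= cutoff (default 0.3).
#' @param min_assessed_fraction minimum non-missing fraction (default 0.8).
#' @return a `frailty_index_spec`.
#' @export
frailty_index_spec <- function(n_deficits = 52, cutoff = 0.3,
                               min_assessed_fraction = 0.8) {
  stopifnot(cutoff > 0, cutoff < 1,
            min_assessed_fraction > 0, min_assessed_fraction <= 1)
  if (n_deficits < 30)
    warning("fewer than 30 deficits; the cumulative-deficit index is ",
            "recommended to combine at least 30")
  structure(list(n_deficits = n_deficits, cutoff = cutoff,
                 min_assessed_fraction = min_assessed_fraction),
            class = "frailty_index_spec")
}

#' Compute the GA frailty index and classify
#'
#' Reference standard 7. The index is the mean of the assessed
#' (non-missing) deficit codes -- deficits present divided by deficits
#' assessed, following the cumulative-deficit ratio convention -- ranging 0
#' (no deficit) to 1 (all deficits). Unfit when the index >= the cutoff
#' (default 0.3). Patients with fewer than `min_assessed_fraction` of
#' deficits assessed are excluded.
#'
#' @param cohort a `ga_cohort` with `deficit_*` columns.
#' @param spec a [frailty_index_spec()].
#' @return standard-result data frame; `detail` carries the index value.
#' @export
compute_frailty_index <- function(cohort, spec = frailty_index_spec()) {
  stopifnot(inherits(spec, "frailty_index_spec"))
  cohort <- ga_cohort(cohort)
  cols <- paste0("deficit_", seq_len(spec$n_deficits))
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks deficit column(s): ",
         paste(head(missing_cols, 5), collapse = ", "),
         if (length(missing_cols) > 5) " ...")
  m <- as.matrix(cohort[, cols])
  n_assessed <- rowSums(!is.na(m))
  ok <- n_assessed >= spec$min_assessed_fraction * spec$n_deficits
  index <- ifelse(ok & n_assessed > 0, rowSums(m, na.rm = TRUE) / n_assessed, NA)
  unfit <- index >= spec$cutoff
  .std_result(cohort$patient_id, "frailty_index", unfit,
              detail = sprintf("fi=%.4f (assessed %d/%d)", index, n_assessed,
                               spec$n_deficits),
              excluded_reason = ifelse(ok, NA_character_,
                                       "too few deficits assessed"))
}

#' Classify a cohort under one reference standard
#'
#' Dispatcher over the seven reference standards by identifier:
#' `"ga1"`, `"ga2"` (impairment counts), `"intervention"`, `"balducci"`,
#' `"siog"`, `"lct"`, `"frailty_index"`.
#'
#' @param cohort a `ga_cohort`.
#' @param standard standard identifier.
#' @param ... options forwarded to the specific classifier
#'   (`rule`, `iadl_mode`, `config`, `spec`).
#' @return standard-result data frame.
#' @export
classify_standard <- function(cohort,
                              standard = c("ga1", "ga2", "intervention",
                                           "balducci", "siog", "lct",
                                           "frailty_index"), ...) {
  standard <- match.arg(standard)
  switch(standard,
         ga1 = classify_ga_count(cohort, k = 1),
         ga2 = classify_ga_count(cohort, k = 2),
         intervention = classify_intervention(cohort),
         balducci = classify_balducci(cohort, ...),
         siog = classify_siog(cohort, ...),
         lct = classify_lct(cohort, ...),
         frailty_index = compute_frailty_index(cohort, ...))
}

#' Identifiers of the seven reference standards
#' @return character vector.
#' @export
reference_standards <- function() {
  c("ga1", "ga2", "intervention", "balducci", "siog", "lct", "frailty_index")
}
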