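# End-to-end evaluation: classify -> screen -> paired accuracy, with
# explicit exclusion accounting and a reproducibility manifest.

.score_column <- c(g8 = "g8_score", mg8 = "mg8_score")

#' Run the full screening-evaluation pipeline
#'
#' For every requested tool x standard pair: classifies the cohort,
#' restricts to the analysis population, and computes the confusion table
#' and accuracy bundle at the official cutoff and at a policy-selected
#' optimal cutoff, the ROC curve and AUROC with DeLong confidence interval,
#' the DeLong paired comparison between the two tools, McNemar paired
#' comparisons of sensitivity (among unfit) and specificity (among fit),
#' and the logistic coefficient-equality test. Per-standard exclusions are
#' counted, never silently dropped.
#'
#' @param cohort a `ga_cohort`; alternatively pass `sim_spec` to simulate.
#' @param sim_spec optional [cohort_sim_spec()] used when `cohort` is NULL.
#' @param tools screening tools to evaluate (`"g8"`, `"mg8"`); scores are
#'   taken from the `g8_score` / `mg8_score` columns.
#' @param standards reference standards to evaluate (see
#'   [reference_standards()]); must be non-empty.
#' @param standard_opts named list of per-standard option lists forwarded
#'   to [classify_standard()] (e.g.
#'   `list(siog = list(iadl_mode = "sex_specific"))`).
#' @param cutoff_policy policy for the optimal operating point
#'   (see [optimal_cutoff()]).
#' @param sens_floor sensitivity floor for `cutoff_policy = "sens_floor"`.
#' @param official_for standards evaluated at the official cutoff in the
#'   performance table (the screening convention: the development standard
#'   keeps the official cutoff, others get the optimized one).
#' @param ci_method proportion CI method (`"exact"` or `"wilson"`).
#' @param population `"common"` restricts every comparison to patients
#'   classifiable under all requested standards with all tool scores
#'   (mirrors a common complete-case population); `"per_standard"` uses
#'   each standard's own complete cases.
#' @param seed seed recorded in the manifest and used when simulating.
#' @param out_dir optional directory: writes association/performance/AUROC
#'   tables as CSV and the full metric set as JSON.
#' @return a `frailscreen_eval` list; see components in the description.
#' @export
run_pipeline <- function(cohort = NULL, sim_spec = NULL,
                         tools = c("g8", "mg8"),
                         standards = reference_standards(),
                         standard_opts = list(),
                         cutoff_policy = c("youden", "sens_floor"),
                         sens_floor = 0.80,
                         official_for = "ga1",
                         ci_method = c("exact", "wilson"),
                         population = c("common", "per_standard"),
                         seed = NULL, out_dir = NULL) {
  cutoff_policy <- match.arg(cutoff_policy)
  ci_method <- match.arg(ci_method)
  population <- match.arg(population)
  if (!length(tools)) stop("at least one tool must be requested")
  if (!length(standards)) stop("at least one standard must be requested")
  tools <- match.arg(tools, c("g8", "mg8"), several.ok = TRUE)
  standards <- match.arg(standards, reference_standards(), several.ok = TRUE)
  if (is.null(cohort)) {
    if (is.null(sim_spec)) stop("supply a cohort or a sim_spec")
    cohort <- generate_cohort(sim_spec, seed = seed)
  }
  cohort <- ga_cohort(cohort)
  n <- nrow(cohort)

  cls <- lapply(standards, function(st)
    do.call(classify_standard,
            c(list(cohort = cohort, standard = st),
              standard_opts[[st]] %||% list())))
  names(cls) <- standards
  unfit_mat <- vapply(cls, `[[`, logical(n), "unfit")
  score_mat <- vapply(tools, function(tl) cohort[[.score_column[[tl]]]],
                      numeric(n))
  scores_ok <- rowSums(is.na(score_mat)) == 0

  exclusions <- data.frame(
    standard = standards,
    n_excluded_standard = colSums(is.na(unfit_mat)),
    row.names = NULL, stringsAsFactors = FALSE)

  common_idx <- scores_ok & rowSums(is.na(unfit_mat)) == 0

  assoc <- perf <- aucs <- paired <- list()
  for (st in standards) {
    idx <- if (population == "common") common_idx else
      scores_ok & !is.na(unfit_mat[, st])
    if (sum(idx) == 0) stop("no analyzable patients for standard ", st)
    unfit <- unfit_mat[idx, st]
    if (!any(unfit) || all(unfit))
      stop("standard ", st, " is single-class in the analysis population")
    prev <- mean(unfit)

    tool_res <- list()
    for (tl in tools) {
      sc <- score_mat[idx, tl]
      dir <- .tool_direction(tl)
      curve <- roc_curve(sc, unfit, direction = dir)
      official_cut <- .tool_meta[[tl]]$cutoff
      use_official <- st %in% official_for
      opt <- optimal_cutoff(curve, policy = cutoff_policy,
                            sens_floor = sens_floor)
      eval_cut <- if (use_official) official_cut else opt$cutoff
      abn_official <- screen_score(tl, sc)$abnormal
      abn_eval <- screen_score(tl, sc, cutoff = eval_cut)$abnormal
      rep_official <- accuracy_report(build_confusion(abn_official, unfit),
                                      ci_method = ci_method)
      rep_eval <- accuracy_report(build_confusion(abn_eval, unfit),
                                  ci_method = ci_method)
      tool_res[[tl]] <- list(curve = curve, official_cutoff = official_cut,
                             eval_cutoff = eval_cut,
                             abn_official = abn_official, abn_eval = abn_eval,
                             report_official = rep_official,
                             report_eval = rep_eval)
      assoc[[paste(st, tl)]] <- data.frame(
        standard = st, tool = tl, n = sum(idx), n_unfit = sum(unfit),
        unfit_normal_score = rep_official$table$fn,
        unfit_abnormal_score = rep_official$table$tp,
        odds_ratio = rep_official$odds_ratio,
        or_lower = rep_official$or_ci[["lower"]],
        or_upper = rep_official$or_ci[["upper"]],
        or_p = rep_official$or_p, stringsAsFactors = FALSE)
      aucs[[paste(st, tl)]] <- data.frame(
        standard = st, tool = tl, auroc = curve$auc,
        auroc_lower = curve$auc_ci[["lower"]],
        auroc_upper = curve$auc_ci[["upper"]], stringsAsFactors = FALSE)
      perf[[paste(st, tl)]] <- data.frame(
        standard = st, prevalence = prev, tool = tl, cutoff = eval_cut,
        sensitivity = rep_eval$sensitivity[["estimate"]],
        sens_lower = rep_eval$sensitivity[["lower"]],
        sens_upper = rep_eval$sensitivity[["upper"]],
        specificity = rep_eval$specificity[["estimate"]],
        spec_lower = rep_eval$specificity[["lower"]],
        spec_upper = rep_eval$specificity[["upper"]],
        ppv = rep_eval$ppv[["estimate"]], npv = rep_eval$npv[["estimate"]],
        lr_pos = rep_eval$lr_pos, lr_neg = rep_eval$lr_neg,
        stringsAsFactors = FALSE)
    }

    if (all(c("g8", "mg8") %in% tools)) {
      a <- tool_res[["g8"]]; b <- tool_res[["mg8"]]
      dl <- delong_test(score_mat[idx, "g8"], score_mat[idx, "mg8"], unfit,
                        direction_a = "lower_worse",
                        direction_b = "higher_worse")
      mc_sens <- mcnemar_paired(a$abn_eval[unfit], b$abn_eval[unfit])
      mc_spec <- mcnemar_paired(!a$abn_eval[!unfit], !b$abn_eval[!unfit])
      ce <- coefficient_equality_test(a$abn_official, b$abn_official, unfit)
      paired[[st]] <- data.frame(
        standard = st,
        auroc_g8 = dl$auc_a, auroc_mg8 = dl$auc_b,
        delong_p = dl$p_value,
        mcnemar_sens_p = mc_sens$p_value, mcnemar_spec_p = mc_spec$p_value,
        coef_equality_p = ce$p_value, stringsAsFactors = FALSE)
    }
  }

  cfg <- list(tools = tools, standards = standards,
              standard_opts = standard_opts, cutoff_policy = cutoff_policy,
              sens_floor = sens_floor, official_for = official_for,
              ci_method = ci_method, population = population, seed = seed)
  res <- structure(list(
    n = n, population = population,
    n_common = sum(common_idx),
    classifications = cls,
    exclusions = exclusions,
    associations = do.call(rbind, assoc),
    performance = do.call(rbind, perf),
    auroc = do.call(rbind, aucs),
    paired = if (length(paired)) do.call(rbind, paired) else NULL,
    config = cfg,
    manifest = .manifest(cfg, n, seed)),
    class = "frailscreen_eval")
  rownames(res$associations) <- rownames(res$performance) <-
    rownames(res$auroc) <- NULL
  if (!is.null(res$paired)) rownames(res$paired) <- NULL
  if (!is.null(out_dir)) write_eval(res, out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.manifest <- function(cfg, n, seed) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(cfg, tf, version = 2)
  list(config_hash = unname(tools::md5sum(tf)),
       seed = seed, n = n,
       package_version = as.character(utils::packageVersion("frailscreen")),
       timestamp = NULL)
}

#' @export
print.frailscreen_eval <- function(x, ...) {
  cat(sprintf("Screening evaluation: %d patients (%d in common population)\n",
              x$n, x$n_common))
  cat("\nAssociations (official cutoffs):\n")
  print(transform(x$associations,
                  odds_ratio = round(odds_ratio, 2),
                  or_lower = round(or_lower, 2), or_upper = round(or_upper, 2),
                  or_p = signif(or_p, 2)), row.names = FALSE)
  cat("\nPerformance:\n")
  pf <- x$performance
  pf[-(1:4)] <- round(pf[-(1:4)], 3)
  pf$prevalence <- round(pf$prevalence, 3)
  print(pf, row.names = FALSE)
  if (!is.null(x$paired)) {
    cat("\nPaired comparisons (G8 vs modified G8):\n")
    pd <- x$paired
    pd[-1] <- signif(pd[-1], 3)
    print(pd, row.names = FALSE)
  }
  invisible(x)
}

#' Write evaluation tables to disk
#'
#' Emits `associations.csv`, `performance.csv`, `auroc.csv`,
#' `paired_tests.csv`, `exclusions.csv` and `metrics.json` (all metrics
#' plus the manifest) into `dir`.
#'
#' @param x a `frailscreen_eval`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval <- function(x, dir) {
  stopifnot(inherits(x, "frailscreen_eval"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(x$associations, file.path(dir, "associations.csv"), row.names = FALSE)
  write.csv(x$performance, file.path(dir, "performance.csv"), row.names = FALSE)
  write.csv(x$auroc, file.path(dir, "auroc.csv"), row.names = FALSE)
  if (!is.null(x$paired))
    write.csv(x$paired, file.path(dir, "paired_tests.csv"), row.names = FALSE)
  write.csv(x$exclusions, file.path(dir, "exclusions.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(manifest = x$manifest, associations = x$associations,
         performance = x$performance, auroc = x$auroc, paired = x$paired,
         exclusions = x$exclusions),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
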