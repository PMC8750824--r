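# Synthetic GA cohort generator.
#
# One shared latent frailty severity Z ~ N(0,1) drives everything: each GA
# domain has a probit loading on Z (marginal impairment prevalences are
# exact by construction), instrument totals are a noisy linear transform of
# Z discretized onto the instrument grid, interventions are Bernoulli given
# the impairment count, and the frailty-index deficits are probit
# indicators on Z. The single-factor structure induces the strong positive
# dependence between tools and standards that real GA data show, and makes
# every conditional probability analytic (given Z), which is what the
# calibration routines exploit.

.default_domain_prev <- c(adl = 0.316, iadl = 0.585, tug = 0.382,
                          mmse = 0.251, gds = 0.334, mna = 0.643,
                          cirs = 0.631)
.default_syndrome_prev <- c(dementia = 0.15, delirium = 0.05,
                            depression = 0.32, incontinence = 0.20,
                            falls = 0.321)
# marginal P(prescribed); intercepts solved so that, combined with the
# impairment-count slope, these marginals hold under the default spec
.default_intervention_prev <- c(nutritional = 0.745, home = 0.652,
                                neuropsych = 0.386, social = 0.635,
                                treatment_adaptation = 0.232)

#' Specification of a synthetic GA cohort
#'
#' Defaults emulate a large geriatric-oncology cohort: domain impairment
#' prevalences follow the published ELCAPA-like marginals, the shared
#' latent loading and the tool models are calibrated so that, at the
#' official cutoffs, both instruments show realistic operating points
#' against the >= 1-impairment standard, and the deficit model puts the
#' frailty-index unfit fraction near 0.89.
#'
#' @param n cohort size.
#' @param seed integer seed; the same spec and seed give identical cohorts.
#' @param loading shared probit loading of every domain/deficit/syndrome
#'   latent on the severity factor (0 < loading < 1).
#' @param domain_prevalence named vector of marginal impairment
#'   probabilities for the seven GA domains (adl, iadl, tug, mmse, gds,
#'   mna, cirs).
#' @param domain_shift common shift added to all domain probit intercepts
#'   (the knob [calibrate_spec()] tunes for a target unfit prevalence).
#' @param iadl4_prevalence marginal P(4-item IADL <= 3) used for men.
#' @param syndrome_prevalence named vector for the five geriatric syndromes.
#' @param weight_loss_prevalence named vector `c(wl1 =, wl6 =)`: marginal
#'   probabilities of >= 5% loss in 1 month and >= 10% in 6 months.
#' @param g8,mg8 tool models `list(loc, slope, sd, cutoff)`: the continuous
#'   score is `loc -/+ slope * Z + sd * noise` (minus for the G8, whose
#'   low scores are abnormal), then discretized and clamped to the
#'   instrument grid.
#' @param intervention_prevalence named marginal prescription probabilities
#'   per intervention domain.
#' @param intervention_slope log-odds increase per GA impairment in the
#'   prescription model.
#' @param fi frailty-index deficit model: `list(n_deficits, base_prevalence,
#'   shift, n_graded, cutoff)`; deficits are probit indicators on Z, the
#'   first `n_graded` coded 0/0.5/1.
#' @param male_fraction marginal P(male).
#' @return a `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n = 1136, seed = 1L,
                            loading = 0.72,
                            domain_prevalence = .default_domain_prev,
                            domain_shift = 0.2264,
                            iadl4_prevalence = 0.45,
                            syndrome_prevalence = .default_syndrome_prev,
                            weight_loss_prevalence = c(wl1 = 0.15, wl6 = 0.22),
                            g8 = list(loc = 10.73, slope = 2.4, sd = 1.99,
                                      cutoff = 14),
                            mg8 = list(loc = 11.50, slope = 5.4, sd = 1.88,
                                       cutoff = 6),
                            intervention_prevalence = .default_intervention_prev,
                            intervention_slope = 0.55,
                            fi = list(n_deficits = 52,
                                      base_prevalence = seq(0.15, 0.75,
                                                            length.out = 52),
                                      shift = 0.589, n_graded = 6, cutoff = 0.3),
                            male_fraction = 0.517) {
  stopifnot(n >= 1, loading > 0, loading < 1,
            all(domain_prevalence > 0), all(domain_prevalence < 1),
            all(syndrome_prevalence > 0), all(syndrome_prevalence < 1),
            all(weight_loss_prevalence > 0), all(weight_loss_prevalence < 1),
            all(fi$base_prevalence > 0), all(fi$base_prevalence < 1),
            length(fi$base_prevalence) == fi$n_deficits,
            g8$sd > 0, mg8$sd > 0)
  if (!all(names(.default_domain_prev) %in% names(domain_prevalence)))
    stop("domain_prevalence must name all seven domains: ",
         paste(names(.default_domain_prev), collapse = ", "))
  structure(list(n = n, seed = as.integer(seed), loading = loading,
                 domain_prevalence = domain_prevalence,
                 domain_shift = domain_shift,
                 iadl4_prevalence = iadl4_prevalence,
                 syndrome_prevalence = syndrome_prevalence,
                 weight_loss_prevalence = weight_loss_prevalence,
                 g8 = g8, mg8 = mg8,
                 intervention_prevalence = intervention_prevalence,
                 intervention_slope = intervention_slope,
                 fi = fi, male_fraction = male_fraction),
            class = "cohort_sim_spec")
}

#' @export
print.cohort_sim_spec <- function(x, ...) {
  cat(sprintf("Cohort simulation spec: n = %d, seed = %d, loading = %.2f\n",
              x$n, x$seed, x$loading))
  cat(sprintf("  analytic GA >=1 impairment prevalence: %.3f\n",
              sim_ga1_prevalence(x)))
  invisible(x)
}

# probit thresholds after the common shift
.domain_thresholds <- function(spec) {
  qnorm(1 - spec$domain_prevalence[names(.default_domain_prev)]) - spec$domain_shift
}

# Gauss-grid integration helpers: all conditional probabilities are
# analytic given Z, so population summaries are deterministic integrals.
.z_grid <- function(step = 0.005, lim = 8) {
  z <- seq(-lim, lim, by = step)
  list(z = z, w = dnorm(z) * step)
}

.p_impaired_given_z <- function(spec, z) {
  lam <- spec$loading; s <- sqrt(1 - lam^2)
  t <- .domain_thresholds(spec)
  vapply(t, function(ti) pnorm((lam * z - ti) / s), numeric(length(z)))
}

.p_unfit_given_z <- function(spec, z, k = 1) {
  p <- .p_impaired_given_z(spec, z)
  if (k == 1) return(1 - apply(1 - p, 1, prod))
  # P(at least k): exact Poisson-binomial over the 7 domains given z,
  # by iterated convolution (numerically safe at extreme z)
  pmf <- matrix(0, length(z), 8)
  pmf[, 1] <- 1
  for (d in seq_len(ncol(p))) {
    shifted <- cbind(0, pmf[, 1:7]) * p[, d]
    pmf <- pmf * (1 - p[, d]) + shifted
  }
  pmax(0, 1 - rowSums(pmf[, seq_len(k), drop = FALSE]))
}

# P(test abnormal | z) at a given cutoff, respecting discretization:
# G8 totals are half-point grids (score <= c  <=>  raw < c + 0.25),
# modified G8 integer (score >= c  <=>  raw >= c - 0.5)
.p_abnormal_given_z <- function(spec, tool, z, cutoff = NULL) {
  tm <- spec[[tool]]
  if (is.null(cutoff)) cutoff <- tm$cutoff
  if (tool == "g8") {
    pnorm((cutoff + 0.25 - (tm$loc - tm$slope * z)) / tm$sd)
  } else {
    1 - pnorm((cutoff - 0.5 - (tm$loc + tm$slope * z)) / tm$sd)
  }
}

#' Analytic unfit prevalence of the GA impairment-count standard
#'
#' Population (infinite-sample) prevalence of the >= k-impairment standard
#' implied by a simulation spec, by integrating the conditional probability
#' over the latent severity.
#'
#' @param spec a [cohort_sim_spec()].
#' @param k impairment-count threshold (1 or 2).
#' @return probability.
#' @export
sim_ga1_prevalence <- function(spec, k = 1) {
  g <- .z_grid()
  sum(.p_unfit_given_z(spec, g$z, k) * g$w)
}

#' Analytic operating point of a tool against the GA >= 1 standard
#'
#' Population sensitivity and specificity of a simulated tool, at its
#' official (or a supplied) cutoff, against the >= 1-impairment standard.
#'
#' @param spec a [cohort_sim_spec()].
#' @param tool `"g8"` or `"mg8"`.
#' @param cutoff optional alternative cutoff.
#' @return named vector `c(sensitivity, specificity)`.
#' @export
sim_tool_operating_point <- function(spec, tool = c("g8", "mg8"),
                                     cutoff = NULL) {
  tool <- match.arg(tool)
  g <- .z_grid()
  pu <- .p_unfit_given_z(spec, g$z)
  pa <- .p_abnormal_given_z(spec, tool, g$z, cutoff)
  sens <- sum(pa * pu * g$w) / sum(pu * g$w)
  spc <- sum((1 - pa) * (1 - pu) * g$w) / sum((1 - pu) * g$w)
  c(sensitivity = sens, specificity = spc)
}

# deterministic quantile map of a latent value onto discrete score levels.
# levels ordered healthiest-first (normal side) / mildest-first (impaired).
.quantile_levels <- function(u, lo, hi, levels) {
  frac <- (u - lo) / (hi - lo)
  idx <- pmax(1, pmin(length(levels), floor(frac * length(levels)) + 1))
  levels[idx]
}

.run_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic GA cohort
#'
#' Draws a complete cohort (every field the seven reference standards and
#' both screening tools consume) under the one-factor latent severity
#' model of a [cohort_sim_spec()]. Identical spec and seed give identical
#' cohorts; the global random-number state is left untouched.
#'
#' @param spec a [cohort_sim_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return a validated `ga_cohort` with an additional numeric column
#'   `severity` (the latent factor, for diagnostics; classifiers ignore it).
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  if (is.null(seed)) seed <- spec$seed
  .run_with_seed(seed, .generate_cohort_impl(spec))
}

.generate_cohort_impl <- function(spec) {
  n <- spec$n
  lam <- spec$loading; s <- sqrt(1 - lam^2)
  z <- rnorm(n)
  t <- .domain_thresholds(spec)
  L <- vapply(t, function(ti) lam * z + s * rnorm(n), numeric(n))
  colnames(L) <- names(t)
  U <- pnorm(L)                     # uniform marginals
  Ft <- pnorm(t)                    # P(not impaired) per domain
  imp <- sweep(U, 2, Ft, `>`)

  two_sided <- function(dom, normal_levels, impaired_levels) {
    u <- U[, dom]; f <- Ft[[dom]]
    ifelse(imp[, dom],
           .quantile_levels(u, f, 1, impaired_levels),
           .quantile_levels(u, 0, f, normal_levels))
  }

  adl  <- two_sided("adl",  c(6, 5.5), c(5, 4.5, 4, 3, 2, 1, 0))
  iadl <- two_sided("iadl", 8, 7:0)
  mmse <- two_sided("mmse", 30:24, 23:8)
  gds  <- two_sided("gds", 0, 1:4)
  mna  <- two_sided("mna", seq(30, 24, by = -0.5), seq(23.5, 10, by = -0.5))
  cirs <- two_sided("cirs", c(0, 1, 2), c(3, 4))
  tug_seconds <- pmin(180, pmax(4, round(20 * exp(0.45 * (L[, "tug"] - t[["tug"]])), 1)))

  # 4-item IADL (used by the sex-specific SIOG variant): same latent as
  # IADL, stricter threshold
  t4 <- qnorm(1 - spec$iadl4_prevalence) - spec$domain_shift
  iadl4 <- ifelse(U[, "iadl"] > pnorm(t4),
                  .quantile_levels(U[, "iadl"], pnorm(t4), 1, 3:0), 4)

  syn <- vapply(spec$syndrome_prevalence, function(p) {
    lam * z + s * rnorm(n) > qnorm(1 - p)
  }, logical(n))
  colnames(syn) <- paste0("syndrome_", names(spec$syndrome_prevalence))

  wl_draw <- function(p, floor_pct, minor_max) {
    Lw <- lam * z + s * rnorm(n)
    tw <- qnorm(1 - p)
    uw <- pnorm(Lw)
    ifelse(Lw > tw,
           round(floor_pct + (uw - pnorm(tw)) / (1 - pnorm(tw)) * floor_pct, 1),
           round(uw / pnorm(tw) * minor_max, 1))
  }
  wl1 <- wl_draw(spec$weight_loss_prevalence[["wl1"]], 5, 4.9)
  wl6 <- wl_draw(spec$weight_loss_prevalence[["wl6"]], 10, 9.9)

  g8_raw <- spec$g8$loc - spec$g8$slope * z + spec$g8$sd * rnorm(n)
  g8_score <- pmin(17, pmax(0, round(g8_raw * 2) / 2))
  mg8_raw <- spec$mg8$loc + spec$mg8$slope * z + spec$mg8$sd * rnorm(n)
  mg8_score <- pmin(35, pmax(0, round(mg8_raw)))

  n_imp <- rowSums(imp)
  iv <- vapply(names(spec$intervention_prevalence), function(j) {
    a <- .intervention_intercept(spec, j)
    runif(n) < plogis(a + spec$intervention_slope * n_imp)
  }, logical(n))
  colnames(iv) <- paste0("intervention_", colnames(iv))

  fi <- spec$fi
  tf <- qnorm(1 - fi$base_prevalence) - fi$shift
  def <- vapply(seq_len(fi$n_deficits), function(j) {
    Lj <- lam * z + s * rnorm(n)
    if (j <= fi$n_graded) {
      # graded deficit: 0 / 0.5 / 1, upper half of the deficit mass full
      t_hi <- qnorm(1 - fi$base_prevalence[j] / 2) - fi$shift
      ifelse(Lj > t_hi, 1, ifelse(Lj > tf[j], 0.5, 0))
    } else as.numeric(Lj > tf[j])
  }, numeric(n))
  colnames(def) <- paste0("deficit_", seq_len(fi$n_deficits))

  df <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    sex = ifelse(runif(n) < spec$male_fraction, "male", "female"),
    age = pmin(104, 70 + round(rgamma(n, shape = 2.4, scale = 4.4))),
    adl = adl, iadl = iadl, iadl4 = iadl4,
    tug_seconds = tug_seconds, tug_unable = FALSE,
    mmse = mmse, mini_gds = gds, mna = mna, cirs_g_max_grade = cirs,
    weight_loss_1mo_pct = wl1, weight_loss_6mo_pct = wl6,
    g8_score = g8_score, mg8_score = mg8_score,
    stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(syn), as.data.frame(iv), as.data.frame(def))
  out <- ga_cohort(df)
  out$severity <- z
  out
}

# intercept giving the requested marginal prescription probability under
# the spec's impairment-count distribution (solved analytically on the
# z grid: n_imp | z is Poisson-binomial; we use its exact distribution)
.intervention_intercept <- function(spec, domain) {
  target <- spec$intervention_prevalence[[domain]]
  g <- .z_grid(step = 0.02)
  p <- .p_impaired_given_z(spec, g$z)  # len(z) x 7
  # exact Poisson-binomial pmf over 0..7 for each z, by iterated convolution
  pmf <- matrix(0, length(g$z), 8)
  pmf[, 1] <- 1
  for (d in seq_len(ncol(p))) {
    shifted <- cbind(0, pmf[, 1:7]) * p[, d]
    pmf <- pmf * (1 - p[, d]) + shifted
  }
  marg_nimp <- colSums(pmf * g$w)      # P(n_imp = 0..7)
  f <- function(a) sum(plogis(a + spec$intervention_slope * (0:7)) * marg_nimp) - target
  uniroot(f, c(-20, 20), tol = 1e-8)$root
}

#' Write a cohort in the canonical CSV schema
#'
#' @param cohort a `ga_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- ga_cohort(cohort)
  cohort$severity <- NULL
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Calibrate a simulation spec to summary targets
#'
#' One-dimensional root-finding on the spec's intercept/noise knobs so the
#' population summaries implied by the spec hit stated targets:
#'
#' * `ga1_prevalence` — tunes `domain_shift` (analytic integral over the
#'   latent severity);
#' * `g8` / `mg8` — `list(sensitivity =, specificity =, cutoff =)` against
#'   the >= 1-impairment standard; tunes the tool's location (sensitivity,
#'   inner root) nested inside its noise sd (specificity, outer root);
#' * `fi_prevalence` — tunes the deficit-model shift by root-finding on a
#'   large fixed-noise simulation (common random numbers keep the objective
#'   monotone).
#'
#' Targets outside (0, 1) or unreachable within the search bracket are
#' rejected as infeasible.
#'
#' @param targets named list of targets (see above).
#' @param base the starting [cohort_sim_spec()].
#' @param tol root-finding tolerance on the target scale.
#' @return the calibrated `cohort_sim_spec`.
#' @export
calibrate_spec <- function(targets, base = cohort_sim_spec(), tol = 1e-4) {
  spec <- base
  if (!is.null(targets$ga1_prevalence)) {
    pg <- targets$ga1_prevalence
    if (pg <= 0 || pg >= 1) stop("infeasible ga1_prevalence target: ", pg)
    f <- function(d) {
      s2 <- spec; s2$domain_shift <- d
      sim_ga1_prevalence(s2) - pg
    }
    lo <- -4; hi <- 4
    if (f(lo) * f(hi) > 0)
      stop("ga1_prevalence target ", pg, " not reachable by intercept shift")
    spec$domain_shift <- uniroot(f, c(lo, hi), tol = tol)$root
  }
  for (tool in c("g8", "mg8")) {
    tg <- targets[[tool]]
    if (is.null(tg)) next
    if (any(c(tg$sensitivity, tg$specificity) <= 0) ||
        any(c(tg$sensitivity, tg$specificity) >= 1))
      stop("infeasible operating-point target for ", tool)
    cutoff <- if (is.null(tg$cutoff)) spec[[tool]]$cutoff else tg$cutoff
    loc_for_sens <- function(sd_val) {
      s2 <- spec; s2[[tool]]$sd <- sd_val
      f_loc <- function(loc) {
        s2[[tool]]$loc <- loc
        sim_tool_operating_point(s2, tool, cutoff)[["sensitivity"]] - tg$sensitivity
      }
      uniroot(f_loc, c(-80, 120), tol = tol)$root
    }
    f_sd <- function(sd_val) {
      s2 <- spec; s2[[tool]]$sd <- sd_val; s2[[tool]]$loc <- loc_for_sens(sd_val)
      sim_tool_operating_point(s2, tool, cutoff)[["specificity"]] - tg$specificity
    }
    lo <- 0.05 * spec[[tool]]$slope; hi <- 8 * spec[[tool]]$slope
    if (f_sd(lo) * f_sd(hi) > 0)
      stop("operating-point target for ", tool,
           " not reachable by location/noise tuning (profile does not bracket)")
    sd_star <- uniroot(f_sd, c(lo, hi), tol = tol)$root
    spec[[tool]]$sd <- sd_star
    spec[[tool]]$loc <- loc_for_sens(sd_star)
  }
  if (!is.null(targets$fi_prevalence)) {
    pf <- targets$fi_prevalence
    if (pf <= 0 || pf >= 1) stop("infeasible fi_prevalence target: ", pf)
    spec$fi$shift <- .run_with_seed(190101, .calibrate_fi_shift(spec, pf))
  }
  spec
}

.calibrate_fi_shift <- function(spec, target, nsim = 40000) {
  lam <- spec$loading; s <- sqrt(1 - lam^2)
  fi <- spec$fi
  z <- rnorm(nsim)
  E <- matrix(rnorm(nsim * fi$n_deficits), nsim)
  Lmat <- lam * z + s * E
  f <- function(shift) {
    tf <- qnorm(1 - fi$base_prevalence) - shift
    vals <- vapply(seq_len(fi$n_deficits), function(j) {
      if (j <= fi$n_graded) {
        t_hi <- qnorm(1 - fi$base_prevalence[j] / 2) - shift
        ifelse(Lmat[, j] > t_hi, 1, ifelse(Lmat[, j] > tf[j], 0.5, 0))
      } else as.numeric(Lmat[, j] > tf[j])
    }, numeric(nsim))
    mean(rowMeans(vals) >= fi$cutoff) - target
  }
  if (f(-4) * f(4) > 0)
    stop("fi_prevalence target ", target, " not reachable by deficit shift")
  uniroot(f, c(-4, 4), tol = 1e-4)$root
}
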