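---
title: "Methods: screening-tool accuracy under multiple frailty standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening-tool accuracy under multiple frailty standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailscreen)
```

## The problem

Older patients with cancer are screened with short questionnaires — the G8
(8 items, total 0–17, abnormal when ≤ 14) and the modified G8 (6 items,
total 0–35, abnormal when ≥ 6) — to decide who needs a full multidimensional
geriatric assessment (GA). Whether a screening tool "works" depends on the
reference standard chosen to define the target condition, and frailty has no
single accepted operationalization. `frailscreen` implements seven of them
side by side and the complete paired-accuracy machinery needed to compare
two tools against each of them on the same patients.

The seven standards are:

1. **`ga1` / `ga2`** — at least 1 (or 2) of seven impaired GA domains:
   ADL ≤ 5/6, IADL ≤ 7/8, Timed Get-Up-and-Go > 20 s, MMSE ≤ 23/30,
   mini-GDS ≥ 1/4, MNA ≤ 23.5/30, and at least one CIRS-G comorbidity of
   grade 3–4. All comparisons are on the stated scale with the stated
   direction; e.g. MNA = 23.5 is impaired while TUG = 20.0 s is not
   (the TUG rule is strict).
2. **`intervention`** — at least one geriatric intervention prescribed
   across five domains (nutritional, home, neuropsychological, social
   support, anticancer-treatment adaptation).
3. **`balducci`** — fit requires full ADL and IADL independence, no
   comorbidity above CIRS-G grade 2, and none of five geriatric syndromes
   (dementia, delirium, depression, incontinence, falls within 6 months).
4. **`siog`** — unfit on ADL or IADL dependence, severe comorbidity, or
   malnutrition (≥ 5% weight loss in 1 month and/or ≥ 10% in 6 months).
   IADL dependence has a uniform 8-item categorization and a sex-specific
   one (8-item ≤ 7 for women, 4-item ≤ 3 for men).
5. **`lct`** — a latent-class-typology scorer: configured per-class linear
   predictors are softmax-normalized into posterior membership
   probabilities; fit means P(class 1, relatively healthy) ≥ 0.5.
6. **`frailty_index`** — the Rockwood cumulative-deficit ratio: deficits
   present divided by deficits assessed over (by default) 52 indicators
   coded in [0, 1]; unfit when the index ≥ 0.3.

### Design choices on the standards

* **Balducci combination rule.** The fit side of the definition is a
  conjunction of four requirements, which makes unfit their disjunction;
  that complement rule is the default. A stricter conjunctive reading —
  severe comorbidity counts only together with a geriatric syndrome — is
  available as `rule = "literal"`. The two differ exactly for patients
  whose only deficit is a severe comorbidity or only a syndrome.
* **Missing data.** No imputation anywhere. A missing GA domain produces a
  missing flag, is excluded from the impairment count and decrements the
  assessed count; the impairment-count standards require all 7 domains.
  Each classifier returns an explicit `excluded_reason` instead of
  dropping rows. The pipeline's default `population = "common"` restricts
  every comparison to patients classifiable under *all* requested
  standards (mirroring a common complete-case population); per-standard
  complete cases are available as an option. For disjunctive rules (SIOG,
  interventions) one TRUE criterion decides even if another criterion is
  missing, because the verdict cannot be changed by the missing value.
* **Frailty-index denominator.** Assessed (non-missing) deficits, per the
  standard construction guidance; at least 80% of deficits must be
  assessed (configurable), and fewer than 30 deficits triggers a warning.
  Graded deficit codings (0/0.5/1) are supported.
* **Configuration as data.** Instrument item weights and LCT scoring
  coefficients ship as editable configs. The bundled modified-G8 config
  carries the published six-item structure with *synthetic placeholder
  weights* (the published regression-derived weights are not
  redistributable), and the bundled LCT config is an explicitly toy
  example; both are for tests and simulations, and real analyses should
  drop in site configs.

## The accuracy engine

Every tool × standard comparison reduces to a 2×2 table of the
dichotomized tool against the fit/unfit verdict, plus the score-level ROC.

* **Proportion CIs** default to exact Clopper–Pearson (beta quantiles),
  with Wilson available. The choice is testable: from the reconstructed
  table of the ≥ 1-impairment standard (947/1044 unfit patients abnormal),
  only the exact interval reproduces the published 88.8–92.4 bounds to one
  decimal, which is how the default was fixed.
* **Odds ratios** are (tp·tn)/(fn·fp) with a Wald interval on the log
  scale and no continuity correction; a zero cell flags the OR
  non-estimable rather than silently correcting it. The same reconstructed
  tables reproduce the published OR and bounds exactly, validating this
  choice.
* **AUROC** is the Mann–Whitney concordance probability with tied scores
  counting one half, computed from midranks in O(n log n); the empirical
  ROC curve places reported cutoffs at midpoints between adjacent distinct
  scores, and its trapezoid integral equals the Mann–Whitney value
  identically (a property the suite checks to 1e-12, ties included).
  Orientation matters and is explicit throughout: low G8 scores are risky,
  high modified-G8 scores are risky.
* **Paired AUROC comparison** uses the DeLong–Clarke-Pearson placement
  -value covariance: z = (AUC_a − AUC_b)/√(var_a + var_b − 2 cov). The
  implementation is checked against hand-enumerated placements and an
  independent implementation (pROC), and its type-I error is measured
  under an exchangeable null (n = 200, 5000 replicates).
* **McNemar's test** on discordant pairs, (b−c)²/(b+c) with 1 df and no
  continuity correction, applied among unfit patients for sensitivities
  and among fit patients for specificities; b + c = 0 yields statistic 0,
  p = 1.
* **Coefficient equality** between the two tools' univariate logistic
  log-ORs is tested by stacking the data with a tool indicator and testing
  the flag × tool interaction with a cluster-robust (patient-level)
  covariance, so the within-patient pairing is respected; a paired
  bootstrap of the coefficient difference is available as a cross-check.
  Separated fits are flagged non-estimable.
* **Cutoff selection** offers two deterministic policies: Youden's J with
  ties broken towards sensitivity (default), and maximum specificity
  subject to a sensitivity floor (default 0.80) — the latter is the
  natural formalization of "prioritizing sensitivity" for a screening
  instrument. In the pipeline's performance table the development standard
  (`ga1` by default) keeps the official cutoffs; the other standards get
  the policy-selected optimum.
* **Power** for the paired design is Monte-Carlo under a binormal model:
  class-conditional unit-variance normals with shift √2·Φ⁻¹(AUC) and a
  shared within-class correlation between the tools. The between-tool
  correlation is a required input, because published power statements
  leave it implicit; the function therefore profiles power over a
  correlation vector rather than pretending to a single number.

## The synthetic cohort

Restricted patient-level data cannot ship, so the generator makes the full
analysis testable. A single latent severity Z ~ N(0,1) drives:

* seven domain latents `L_d = λZ + √(1−λ²)ε`, impaired when `L_d`
  exceeds the probit threshold of the domain's target marginal prevalence
  (shifted by a common calibration intercept); observed scores are
  quantile-mapped from the latent onto each instrument's discrete grid on
  both sides of the cutoff, so every threshold is exercised;
* instrument totals `loc ∓ slope·Z + sd·ε` discretized to the G8
  half-point grid and the modified-G8 integer grid (item-level simulation
  is deliberately out of scope — the classifiers consume totals);
* five syndrome indicators, two weight-loss fields, a stricter 4-item IADL
  threshold for men, Bernoulli intervention flags whose log-odds increase
  with the impairment count, and 52 deficit indicators (six of them graded
  0/0.5/1) for the frailty index.

The one-factor structure is a modeling choice, not an empirical claim: it
is the simplest mechanism that produces the strong positive dependence
among domains, tools and standards seen in real GA cohorts, and it makes
every population summary an analytic integral over Z. The default
parameters are fixed at study-like conditions: n = 1136; Table-1-like
domain marginals with the common shift and loading calibrated so the
≥ 1-impairment prevalence is 0.919 (the loading, 0.72, also gives a
between-tool rank correlation near 0.7 — a documented assumption, since
the real inter-tool correlation is unpublished); tool models calibrated so
the official-cutoff operating points against that standard are ≈ 0.91/0.54
(G8) and ≈ 0.91/0.75 (modified G8); deficit-model shift calibrated so the
frailty-index unfit fraction is ≈ 0.888. These defaults were set once by
the calibration routine and hard-coded; they are conditions, not tuning
knobs.

`calibrate_spec()` exposes the same machinery to users: 1-D root-finding
on the common domain intercept for a target prevalence (analytic
objective), nested root-finding on a tool's location (sensitivity) inside
its noise sd (specificity), and root-finding on the deficit shift against
a large fixed-noise simulation with common random numbers. Infeasible
targets (probabilities at 0 or 1, operating points above the model's
discrimination ceiling) are rejected with an error rather than silently
approximated.

**What the simulator does not emulate:** item-level instrument responses,
cancer-site mix and treatment decisions, longitudinal change, informative
missingness (generated cohorts are complete), and any multi-factor
dependence structure. Passing tests on synthetic cohorts therefore
demonstrate the correctness of the scoring, classification and inference
machinery under a known generative model — not the clinical performance of
the instruments on real patients.

## Numerical choices and degenerate inputs

* Discretization boundaries are handled half-openly
  (`round(x·2)/2 ≤ 14 ⇔ x < 14.25`), which the calibration integrals use
  exactly; clamping to the instrument range never crosses a cutoff.
* Ties in scores get half credit in the AUROC and midpoint cutoffs in the
  ROC; a degenerate DeLong variance (identical placements) is flagged, and
  identical inputs short-circuit to p = 1 exactly.
* Single-class inputs, empty strata, zero cells, separation in logistic
  fits, and out-of-range scores all raise or flag explicitly; nothing is
  imputed or corrected silently.
* Reproducibility: cohort generation restores the caller's RNG state;
  the pipeline manifest records a hash of the full configuration and the
  seed, and identical configurations reproduce identical outputs.

## Problem sizes used in the checks

The bundled verification suite works at sizes chosen to keep Monte-Carlo
error well inside the tolerances being asserted: 200 random ROC fixtures
(n ≤ 50) for oracle equivalence; 5000 replicates of n = 200 for the DeLong
null size; n = 100,000 cohorts for calibration recovery (binomial SE
≈ 0.001 at the targets, against a 0.01 tolerance); n = 50,000 for the
noise-monotonicity property; and 300–1000 replicates per point for power
profiles (SE ≈ 0.015).

## Known limitations

* The bundled modified-G8 weights and LCT coefficients are placeholders
  (see above); results with the bundled configs characterize the engine,
  not the published instruments' item content.
* The latent-class scorer only scores; it does not fit the latent class
  model.
* No covariate adjustment (the design is univariate by construction) and
  no prognostic/outcome validation.
* The frailty-index deficit list is configurable but the default names are
  synthetic placeholders matching count and coding conventions.
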