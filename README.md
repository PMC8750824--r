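# frailscreen

Paired diagnostic-accuracy analysis of geriatric-oncology screening tools
— the G8 and the modified G8 — against seven operational definitions of
frailty.

## The problem

Short screening questionnaires decide which older cancer patients get a
full multidimensional geriatric assessment (GA). But "frail" has no single
reference standard: an abnormal GA can be defined by impairment counts, by
what the geriatrician actually prescribed, by expert rule sets, by a
latent-class health typology, or by a cumulative-deficit frailty index —
and a tool's measured accuracy depends on that choice. `frailscreen`
implements the whole comparison: it scores both instruments, classifies
patients fit/unfit under seven standards, and computes every paired
accuracy statistic needed to compare two tools on the same cohort.

**Screening tools.** G8: 8 items, total score 0–17, abnormal when ≤ 14
(lower is worse). Modified G8: 6 items, total 0–35, abnormal when ≥ 6
(higher is worse). Scoring works from item responses (config-driven
weights) or precomputed totals, at official or alternative cutoffs.

**Reference standards.** (1) ≥ 1 and (2) ≥ 2 impaired GA domains (ADL ≤ 5/6,
IADL ≤ 7/8, TUG > 20 s, MMSE ≤ 23/30, mini-GDS ≥ 1/4, MNA ≤ 23.5/30,
CIRS-G grade ≥ 3); (3) ≥ 1 prescribed geriatric intervention; (4) latent
class typology (posterior P(class 1) < 0.5); (5) Balducci and (6) SIOG
expert classifications; (7) Rockwood frailty index (deficits present /
deficits assessed, unfit ≥ 0.3).

**Statistics.** For a 2×2 table of test against condition: Se = TP/(TP+FN),
Sp = TN/(TN+FP), PPV, NPV, LR+ = Se/(1−Sp), LR− = (1−Se)/Sp, with exact
(Clopper–Pearson) or Wilson intervals; OR = (TP·TN)/(FN·FP) with the Wald
log-scale interval. At score level: the empirical ROC and the
Mann–Whitney AUROC (ties half-credit), the DeLong–Clarke-Pearson paired
test z = (AUC₁−AUC₂)/√(V₁+V₂−2C) from placement-value covariances,
McNemar's (b−c)²/(b+c) for paired sensitivities/specificities, a
pairing-robust test of equality of the two univariate logistic
coefficients, deterministic cutoff-selection policies, and Monte-Carlo
power for paired AUROC designs under a binormal model.

**Synthetic cohorts.** A one-factor latent severity model generates
complete cohorts with realistic dependence between domains, tools and
standards, plus calibration routines that hit stated prevalence and
operating-point targets by root-finding — so the full pipeline is testable
without restricted patient data.

## Worked example

Accuracy metrics from a 2×2 table (a published-scale example: 1044 unfit
and 92 fit patients, original G8 at its official cutoff):

```r
library(frailscreen)
accuracy_report(confusion_table(tp = 947, fn = 97, fp = 42, tn = 50))
#> n = 1136, prevalence = 91.9%  [exact CI]
#>   sensitivity: 90.7% (88.8-92.4)
#>   specificity: 54.3% (43.6-64.8)
#>   PPV: 95.8%   NPV: 34.0%
#>   LR+: 1.99   LR-: 0.17
#>   OR: 11.62 (7.33-18.42), p = 1.58e-25
```

Reading: an abnormal G8 picks up 90.7% of unfit patients while clearing
54.3% of fit ones; an abnormal result multiplies the odds of being unfit
by 11.6.

End to end on a simulated cohort:

```r
spec <- cohort_sim_spec(n = 1136, seed = 42)   # study-like conditions
ev <- run_pipeline(sim_spec = spec,
                   standards = c("ga1", "siog", "frailty_index"),
                   seed = 42)
ev$paired
#>       standard auroc_g8 auroc_mg8 delong_p mcnemar_sens_p mcnemar_spec_p
#>            ga1    0.834     0.918 3.26e-09       7.15e-01       3.44e-06
#>           siog    0.825     0.885 1.70e-05       3.06e-18       2.23e-01
#>  frailty_index    0.893     0.967 6.44e-09       3.65e-20       1.09e-01
```

Each row compares the two tools on the same patients under one standard:
the AUROCs, the DeLong p-value for their difference, and McNemar p-values
for paired sensitivity and specificity at the evaluated cutoffs.
`ev$associations` and `ev$performance` carry the per-tool odds-ratio and
operating-point tables, `ev$exclusions` the per-standard complete-case
accounting, and `write_eval(ev, dir)` exports everything as CSV + JSON.

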