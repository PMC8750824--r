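Package: frailscreen
Title: Diagnostic Accuracy of Geriatric Screening Tools Against Multiple
    Frailty Reference Standards
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores the G8 and modified G8 geriatric-oncology screening
    instruments, classifies patients as fit or unfit under seven frailty
    reference standards (geriatric-assessment impairment counts, prescribed
    geriatric interventions, the Balducci and SIOG expert classifications, a
    latent class typology scorer, and a Rockwood cumulative-deficit frailty
    index), and computes paired diagnostic performance: confusion tables,
    sensitivity/specificity with exact or Wilson confidence intervals,
    predictive values, likelihood ratios, odds ratios, ROC curves and AUROC
    with the DeLong variance, the DeLong-Clarke-Pearson paired AUROC test,
    McNemar paired comparisons of sensitivity and specificity, logistic
    coefficient-equality testing with pairing-robust covariance, and
    Monte-Carlo power for paired AUROC comparisons. A one-factor latent
    severity simulator generates realistic synthetic cohorts, with
    calibration of prevalence and operating characteristics to stated
    targets, so the full pipeline is testable without restricted patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
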