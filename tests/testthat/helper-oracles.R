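# Independent brute-force oracles used across the suite.

# O(n^2) pairwise Mann-Whitney AUROC, ties half-credit
oracle_auc <- function(risk, unfit) {
  pos <- risk[unfit]; neg <- risk[!unfit]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# direct placement values by explicit enumeration
oracle_placements <- function(risk, unfit) {
  pos <- risk[unfit]; neg <- risk[!unfit]
  v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)), 0)
  v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)), 0)
  list(v10 = v10, v01 = v01)
}

oracle_confusion <- function(test, cond) {
  c(tp = sum(test & cond), fn = sum(!test & cond),
    fp = sum(test & !cond), tn = sum(!test & !cond))
}

# a minimal fully-observed healthy record, to be degraded by tests
fit_record <- function(id = "p1", n_deficits = 0) {
  df <- data.frame(
    patient_id = id, sex = "female", age = 78,
    adl = 6, iadl = 8, iadl4 = 4, tug_seconds = 12, tug_unable = FALSE,
    mmse = 28, mini_gds = 0, mna = 27, cirs_g_max_grade = 2,
    weight_loss_1mo_pct = 0, weight_loss_6mo_pct = 0,
    syndrome_dementia = FALSE, syndrome_delirium = FALSE,
    syndrome_depression = FALSE, syndrome_incontinence = FALSE,
    syndrome_falls = FALSE,
    intervention_nutritional = FALSE, intervention_home = FALSE,
    intervention_neuropsych = FALSE, intervention_social = FALSE,
    intervention_treatment_adaptation = FALSE,
    g8_score = 16, mg8_score = 2,
    stringsAsFactors = FALSE)
  if (n_deficits > 0)
    for (j in seq_len(n_deficits)) df[[paste0("deficit_", j)]] <- 0
  df
}

fit_cohort <- function(n, n_deficits = 0) {
  rows <- do.call(rbind, lapply(seq_len(n), function(i)
    fit_record(sprintf("p%03d", i), n_deficits)))
  rows
}
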