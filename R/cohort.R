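# Cohort data model: canonical columns, ranges, ingestion, validation.

# Canonical field ranges. Bounded scores must lie inside [lo, hi] or be NA.
.field_ranges <- list(
  age                 = c(0, 130),
  adl                 = c(0, 6),
  iadl                = c(0, 8),
  iadl4               = c(0, 4),
  tug_seconds         = c(0, Inf),
  mmse                = c(0, 30),
  mini_gds            = c(0, 4),
  mna                 = c(0, 30),
  cirs_g_max_grade    = c(0, 4),
  weight_loss_1mo_pct = c(0, 100),
  weight_loss_6mo_pct = c(0, 100),
  g8_score            = c(0, 17),
  mg8_score           = c(0, 35)
)

.syndrome_fields <- paste0("syndrome_",
  c("dementia", "delirium", "depression", "incontinence", "falls"))

.intervention_fields <- paste0("intervention_",
  c("nutritional", "home", "neuropsych", "social", "treatment_adaptation"))

.logical_fields <- c("tug_unable", .syndrome_fields, .intervention_fields)

#' Default column schema for cohort files
#'
#' Maps canonical field names to the column names used in a delimited cohort
#' file. The default is the identity mapping over the canonical names; pass
#' a named list/vector (canonical = file column) to override any subset.
#'
#' @param ... named overrides, e.g. `mmse = "MMSE_total"`.
#' @return named character vector, canonical name -> file column name.
#' @export
cohort_schema <- function(...) {
  canonical <- c("patient_id", "sex", names(.field_ranges), .logical_fields)
  schema <- setNames(canonical, canonical)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), canonical)
    if (length(bad))
      stop("unknown canonical field(s) in schema: ", paste(bad, collapse = ", "))
    schema[names(over)] <- vapply(over, as.character, character(1))
  }
  schema
}

.parse_numeric <- function(x, field) {
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    warning(sprintf("%d unparseable value(s) in '%s' set to missing", sum(bad), field),
            call. = FALSE)
  out
}

.parse_logical <- function(x, field) {
  x_chr <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x_chr))
  out[x_chr %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x_chr %in% c("false", "f", "0", "no", "n")] <- FALSE
  bad <- !is.na(x) & x_chr != "" & is.na(out)
  if (any(bad))
    warning(sprintf("%d unparseable value(s) in '%s' set to missing", sum(bad), field),
            call. = FALSE)
  out
}

#' Construct and validate a GA cohort
#'
#' Takes a data frame holding per-patient geriatric assessment results in
#' canonical columns and returns a validated `ga_cohort`. Only `patient_id`
#' is mandatory; any other canonical column that is absent is added as all
#' missing. Bounded scores are checked against their declared ranges
#' (ADL 0-6, IADL 0-8, MMSE 0-30, mini-GDS 0-4, MNA 0-30, CIRS-G grade 0-4,
#' G8 0-17, modified G8 0-35); a value outside its range is a hard error
#' naming the row and field. Deficit columns (`deficit_1`, `deficit_2`, ...)
#' for the frailty index must lie in \[0, 1\].
#'
#' @param df data frame of patients, one row each.
#' @return a `ga_cohort` (a data frame with canonical columns).
#' @export
ga_cohort <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df))
    stop("mandatory column 'patient_id' is missing")
  df$patient_id <- as.character(df$patient_id)
  if (anyNA(df$patient_id) || any(df$patient_id == ""))
    stop("patient_id contains missing values")
  if (anyDuplicated(df$patient_id))
    stop("duplicated patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))

  if (!"sex" %in% names(df)) df$sex <- NA_character_
  df$sex <- tolower(as.character(df$sex))
  bad_sex <- !is.na(df$sex) & !df$sex %in% c("male", "female")
  if (any(bad_sex))
    stop("invalid sex value(s) in row(s) ", paste(which(bad_sex), collapse = ", "),
         " (must be 'male' or 'female')")

  for (f in names(.field_ranges)) {
    if (!f %in% names(df)) df[[f]] <- NA_real_
    df[[f]] <- as.numeric(df[[f]])
    rng <- .field_ranges[[f]]
    bad <- !is.na(df[[f]]) & (df[[f]] < rng[1] | df[[f]] > rng[2])
    if (any(bad))
      stop(sprintf("field '%s' out of range [%g, %g] in row(s) %s (patient %s)",
                   f, rng[1], rng[2], paste(which(bad), collapse = ", "),
                   paste(df$patient_id[bad], collapse = ", ")))
  }
  for (f in .logical_fields) {
    if (!f %in% names(df)) df[[f]] <- NA
    df[[f]] <- as.logical(df[[f]])
  }
  dcols <- grep("^deficit_[0-9]+$", names(df), value = TRUE)
  for (f in dcols) {
    df[[f]] <- as.numeric(df[[f]])
    bad <- !is.na(df[[f]]) & (df[[f]] < 0 | df[[f]] > 1)
    if (any(bad))
      stop(sprintf("deficit column '%s' outside [0, 1] in row(s) %s",
                   f, paste(which(bad), collapse = ", ")))
  }
  class(df) <- c("ga_cohort", "data.frame")
  df
}

#' Read a cohort file
#'
#' Reads a delimited cohort table (one row per patient), renames columns
#' through a schema mapping, parses numeric/logical fields (unparseable
#' cells become missing with a warning), and validates via [ga_cohort()].
#'
#' @param path path to a delimited text file.
#' @param schema mapping from canonical names to file columns, as returned
#'   by [cohort_schema()]; columns absent from the file become all-missing.
#' @param missing_tokens character values treated as missing on input.
#' @param sep field separator.
#' @return a validated `ga_cohort`.
#' @export
read_cohort <- function(path, schema = cohort_schema(),
                        missing_tokens = c("", "NA"), sep = ",") {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  na.strings = missing_tokens, check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (!schema[["patient_id"]] %in% names(raw))
    stop("mandatory id column '", schema[["patient_id"]], "' not found in ", path)

  out <- data.frame(patient_id = raw[[schema[["patient_id"]]]],
                    stringsAsFactors = FALSE)
  if (schema[["sex"]] %in% names(raw)) out$sex <- raw[[schema[["sex"]]]]
  for (f in names(.field_ranges))
    if (schema[[f]] %in% names(raw))
      out[[f]] <- .parse_numeric(raw[[schema[[f]]]], f)
  for (f in .logical_fields)
    if (schema[[f]] %in% names(raw))
      out[[f]] <- .parse_logical(raw[[schema[[f]]]], f)
  dcols <- grep("^deficit_[0-9]+$", names(raw), value = TRUE)
  for (f in dcols) out[[f]] <- .parse_numeric(raw[[f]], f)

  stopifnot(nrow(out) == nrow(raw))
  ga_cohort(out)
}

#' @export
print.ga_cohort <- function(x, ...) {
  dcols <- grep("^deficit_[0-9]+$", names(x), value = TRUE)
  cat(sprintf("GA cohort: %d patients, %d deficit indicator(s)\n",
              nrow(x), length(dcols)))
  filled <- vapply(names(.field_ranges), function(f) mean(!is.na(x[[f]])), 0)
  cat("  field completeness: ",
      paste(sprintf("%s %.0f%%", names(filled), 100 * filled), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Derive the seven GA-domain impairment flags
#'
#' Applies the standard geriatric-assessment impairment thresholds to each
#' patient: ADL <= 5/6, IADL <= 7/8, Timed Get-Up-and-Go > 20 s (or unable),
#' MMSE <= 23/30, mini-GDS >= 1/4, MNA <= 23.5/30, and CIRS-G at least one
#' comorbidity of grade 3 or 4. A missing domain yields a missing flag,
#' is excluded from `n_impaired`, and decrements `n_assessed`.
#'
#' @param cohort a `ga_cohort`.
#' @return data frame with `patient_id`, one logical flag per domain,
#'   `n_impaired` (count of TRUE flags) and `n_assessed` (non-missing
#'   domains, 0-7).
#' @export
impairment_profile <- function(cohort) {
  cohort <- ga_cohort(cohort)
  tug <- ifelse(!is.na(cohort$tug_unable) & cohort$tug_unable, TRUE,
                cohort$tug_seconds > 20)
  flags <- data.frame(
    patient_id    = cohort$patient_id,
    adl_impaired  = cohort$adl <= 5,
    iadl_impaired = cohort$iadl <= 7,
    tug_impaired  = tug,
    mmse_impaired = cohort$mmse <= 23,
    gds_impaired  = cohort$mini_gds >= 1,
    mna_impaired  = cohort$mna <= 23.5,
    cirs_impaired = cohort$cirs_g_max_grade >= 3,
    stringsAsFactors = FALSE
  )
  m <- as.matrix(flags[, -1])
  flags$n_impaired <- rowSums(m, na.rm = TRUE)
  flags$n_assessed <- rowSums(!is.na(m))
  flags
}
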