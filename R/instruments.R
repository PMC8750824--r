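# Screening instruments: spec objects, config loading, scoring,
# dichotomization at official or alternative cutoffs.

# Official total-score metadata used when only precomputed totals are
# available. G8: 0-17, abnormal <= 14 (lower is worse). Modified G8: 0-35,
# abnormal >= 6 (higher is worse).
.tool_meta <- list(
  g8  = list(score_min = 0, score_max = 17, abnormal_direction = "<=", cutoff = 14),
  mg8 = list(score_min = 0, score_max = 35, abnormal_direction = ">=", cutoff = 6)
)

#' Instrument specification
#'
#' Builds a validated screening-instrument spec: ordered items with allowed
#' response levels and numeric weights, a declared score range, and the
#' dichotomization rule (direction plus cutoff). The declared range must
#' equal the range attainable by summing item weights, and the cutoff must
#' lie inside it.
#'
#' @param name instrument identifier (e.g. `"g8"`).
#' @param items list of items, each `list(id =, levels = named numeric)`.
#' @param score_min,score_max declared total-score range.
#' @param abnormal_direction `"<="` (low scores abnormal) or `">="`.
#' @param cutoff official dichotomization cutoff.
#' @return an `instrument_spec`.
#' @export
instrument_spec <- function(name, items, score_min, score_max,
                            abnormal_direction = c("<=", ">="), cutoff) {
  abnormal_direction <- match.arg(abnormal_direction)
  stopifnot(is.list(items), length(items) > 0)
  for (it in items) {
    if (is.null(it$id) || is.null(it$levels) || !length(it$levels))
      stop("each item needs an 'id' and a non-empty named 'levels' vector")
    if (is.null(names(it$levels)) || any(names(it$levels) == ""))
      stop("item '", it$id, "': all levels must be named")
  }
  lo <- sum(vapply(items, function(it) min(unlist(it$levels)), 0))
  hi <- sum(vapply(items, function(it) max(unlist(it$levels)), 0))
  if (!isTRUE(all.equal(c(lo, hi), c(score_min, score_max))))
    stop(sprintf("declared score range [%g, %g] != attainable range [%g, %g]",
                 score_min, score_max, lo, hi))
  if (cutoff < score_min || cutoff > score_max)
    stop("cutoff must lie within the score range")
  structure(list(name = name, items = items, score_min = score_min,
                 score_max = score_max, abnormal_direction = abnormal_direction,
                 cutoff = cutoff),
            class = "instrument_spec")
}

#' Load an instrument specification from a YAML config
#'
#' @param path YAML file; see the bundled configs under
#'   `system.file("extdata/instruments", package = "frailscreen")`.
#' @return an `instrument_spec`.
#' @export
load_instrument <- function(path) {
  if (!file.exists(path)) stop("instrument config not found: ", path)
  cfg <- yaml::read_yaml(path)
  items <- lapply(cfg$items, function(it)
    list(id = it$id, levels = unlist(it$levels)))
  instrument_spec(cfg$name, items, cfg$score_min, cfg$score_max,
                  cfg$abnormal_direction, cfg$cutoff)
}

#' Bundled default instrument specs
#'
#' `default_instrument("g8")` is the original G8 (8 items, 0-17, abnormal
#' <= 14). `default_instrument("mg8")` is the modified G8 six-item structure
#' (0-35, abnormal >= 6) with synthetic placeholder weights -- see the
#' bundled config header for why the published weights are not shipped.
#'
#' @param tool `"g8"` or `"mg8"`.
#' @return an `instrument_spec`.
#' @export
default_instrument <- function(tool = c("g8", "mg8")) {
  tool <- match.arg(tool)
  fn <- c(g8 = "g8.yaml", mg8 = "mg8_synthetic.yaml")[[tool]]
  load_instrument(system.file("extdata", "instruments", fn,
                              package = "frailscreen", mustWork = TRUE))
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("Instrument '%s': %d items, scores %g-%g, abnormal %s %g\n",
              x$name, length(x$items), x$score_min, x$score_max,
              x$abnormal_direction, x$cutoff))
  invisible(x)
}

.apply_rule <- function(score, direction, cutoff) {
  if (direction == "<=") score <= cutoff else score >= cutoff
}

#' Score an instrument from item responses
#'
#' Sums the level weights of a complete response vector and dichotomizes at
#' the instrument's official cutoff (instrument totals are undefined when
#' any item is unanswered, so missing items are an error, not NA).
#'
#' @param spec an [instrument_spec()].
#' @param responses named character vector/list, item id -> level name.
#' @return a `screening_result`: list with `tool`, `score`, `cutoff`,
#'   `abnormal`.
#' @export
score_instrument <- function(spec, responses) {
  stopifnot(inherits(spec, "instrument_spec"))
  responses <- unlist(responses)
  missing_items <- setdiff(vapply(spec$items, `[[`, "", "id"), names(responses))
  if (length(missing_items))
    stop("unanswered item(s): ", paste(missing_items, collapse = ", "))
  score <- 0
  for (it in spec$items) {
    lev <- as.character(responses[[it$id]])
    if (is.na(lev) || !lev %in% names(it$levels))
      stop(sprintf("item '%s': level '%s' not allowed (expected one of: %s)",
                   it$id, lev, paste(names(it$levels), collapse = ", ")))
    score <- score + it$levels[[lev]]
  }
  structure(list(tool = spec$name, score = score, cutoff = spec$cutoff,
                 direction = spec$abnormal_direction,
                 abnormal = .apply_rule(score, spec$abnormal_direction, spec$cutoff)),
            class = "screening_result")
}

#' Dichotomize a precomputed total score
#'
#' Cohort files often carry instrument totals rather than item responses.
#' This validates the total against the tool's declared range and applies
#' the official cutoff, or a caller-supplied alternative operating point
#' (e.g. G8 <= 13.5, modified G8 >= 8).
#'
#' @param tool `"g8"` or `"mg8"` (or an [instrument_spec()]).
#' @param score numeric total score(s); NA allowed and propagated.
#' @param cutoff alternative cutoff; default is the official one.
#' @return a `screening_result` (vectorized over `score`).
#' @export
screen_score <- function(tool, score, cutoff = NULL) {
  if (inherits(tool, "instrument_spec")) {
    meta <- tool[c("score_min", "score_max", "abnormal_direction", "cutoff")]
    names(meta)[3] <- "abnormal_direction"
    name <- tool$name
  } else {
    name <- match.arg(tool, names(.tool_meta))
    meta <- .tool_meta[[name]]
  }
  bad <- !is.na(score) & (score < meta$score_min | score > meta$score_max)
  if (any(bad))
    stop(sprintf("score out of range [%g, %g] for %s: %s", meta$score_min,
                 meta$score_max, name,
                 paste(score[bad], collapse = ", ")))
  if (is.null(cutoff)) cutoff <- meta$cutoff
  structure(list(tool = name, score = score, cutoff = cutoff,
                 direction = meta$abnormal_direction,
                 abnormal = .apply_rule(score, meta$abnormal_direction, cutoff)),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  if (length(x$score) == 1) {
    cat(sprintf("%s: score %g, abnormal (%s %g): %s\n", x$tool, x$score,
                x$direction, x$cutoff, x$abnormal))
  } else {
    cat(sprintf("%s: %d scores, abnormal (%s %g): %d / %d non-missing\n",
                x$tool, length(x$score), x$direction, x$cutoff,
                sum(x$abnormal, na.rm = TRUE), sum(!is.na(x$abnormal))))
  }
  invisible(x)
}

# risk orientation for ROC analyses: "higher_worse" if larger scores mean
# more frailty risk
.tool_direction <- function(tool) {
  if (inherits(tool, "instrument_spec"))
    return(if (tool$abnormal_direction == "<=") "lower_worse" else "higher_worse")
  switch(match.arg(tool, names(.tool_meta)),
         g8 = "lower_worse", mg8 = "higher_worse")
}
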