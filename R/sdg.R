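#' Classify countries against the SDG 2030 mortality targets
#'
#' Compares each country's forecast 2030 mortality level with the SDG
#' target for the outcome — 70 maternal deaths per 100,000 or 25 under-five
#' deaths per 1,000 live births. The comparison is inclusive (`<=`) on the
#' integer-rounded level, so a country printed exactly at the target counts
#' as an achiever. Countries flagged `Nil` (non-negative PHE-mortality
#' relationship, hence no forecast) are carried through with
#' `achieved = NA`: they are never counted as achieving or failing.
#'
#' @param values 2030 forecast levels: a named numeric vector (`NA` for Nil
#'   countries), a `forecast_table` fixture, or a list of `forecast_path`
#'   objects.
#' @param outcome `"maternal"` or `"child"`; taken from the object when it
#'   carries one.
#' @param nil logical vector flagging Nil countries; defaults to
#'   `is.na(values)` for numeric input.
#' @return A data frame of class `sdg_assessment` with columns `country`,
#'   `outcome`, `threshold`, `value_2030`, `nil`, `achieved`.
#' @export
classify_sdg <- function(values, outcome = NULL, nil = NULL) {
  UseMethod("classify_sdg")
}

#' @export
classify_sdg.default <- function(values, outcome = NULL, nil = NULL) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (is.null(outcome))
    stop("outcome must be given for numeric input", call. = FALSE)
  if (is.null(nil)) nil <- is.na(values)
  new_sdg_assessment(names(values), unname(values), outcome, nil)
}

#' @export
classify_sdg.forecast_table <- function(values, outcome = NULL, nil = NULL) {
  if (is.null(outcome)) outcome <- attr(values, "outcome")
  new_sdg_assessment(values$country, values$y2030, outcome, values$nil)
}

#' @export
classify_sdg.list <- function(values, outcome = NULL, nil = NULL) {
  stopifnot(all(vapply(values, inherits, logical(1), "forecast_path")))
  if (is.null(outcome)) outcome <- values[[1]]$outcome
  v <- vapply(values, function(p) {
    if (p$nil) NA_real_
    else unname(p$mortality[as.character(max(p$years))])
  }, numeric(1))
  new_sdg_assessment(vapply(values, `[[`, character(1), "country"),
                     v, outcome, vapply(values, `[[`, logical(1), "nil"))
}

new_sdg_assessment <- function(country, value, outcome, nil) {
  outcome <- match_outcome(outcome)
  thr <- sdg_threshold(outcome)
  nil <- as.logical(nil)
  if (any(!nil & (is.na(value) | value < 0)))
    stop("non-Nil countries need a non-negative 2030 value", call. = FALSE)
  structure(data.frame(
    country = as.character(country),
    outcome = outcome,
    threshold = thr,
    value_2030 = ifelse(nil, NA_real_, value),
    nil = nil,
    achieved = ifelse(nil, NA, round(value) <= thr)),
    class = c("sdg_assessment", "data.frame"))
}

#' Summarise a set of SDG assessments
#'
#' @param assessments an `sdg_assessment` for a single outcome.
#' @return List with `n`, `n_nil`, `n_achieved`, `achieved_countries`
#'   (sorted), `pct_achieved` (achievers as a percentage of the non-Nil
#'   countries — Nil countries have no 2030 value to compare), and
#'   `min_2030`/`max_2030` with the countries attaining them (`NA` when
#'   every row is Nil).
#' @export
summarize_sdg <- function(assessments) {
  stopifnot(inherits(assessments, "sdg_assessment"))
  if (nrow(assessments) == 0L) stop("empty assessment set", call. = FALSE)
  if (length(unique(assessments$outcome)) != 1L)
    stop("mixed outcomes in one summary", call. = FALSE)
  ok <- !assessments$nil
  ach <- ok & assessments$achieved %in% TRUE
  out <- list(
    outcome = assessments$outcome[1],
    n = nrow(assessments),
    n_nil = sum(assessments$nil),
    n_achieved = sum(ach),
    achieved_countries = sort(assessments$country[ach]),
    pct_achieved = if (any(ok)) 100 * sum(ach) / sum(ok) else NA_real_,
    min_2030 = if (any(ok)) min(assessments$value_2030[ok]) else NA_real_,
    max_2030 = if (any(ok)) max(assessments$value_2030[ok]) else NA_real_)
  out$min_country <- if (any(ok))
    assessments$country[ok][which.min(assessments$value_2030[ok])]
  else NA_character_
  out$max_country <- if (any(ok))
    assessments$country[ok][which.max(assessments$value_2030[ok])]
  else NA_character_
  out
}

#' Countries whose 2030 forecast exceeds a level
#'
#' @param assessments an `sdg_assessment` for a single outcome.
#' @param level mortality level; countries with an integer-rounded 2030
#'   value strictly above it are returned.
#' @return Sorted character vector of country names (Nil countries never
#'   appear).
#' @export
threshold_exceedance <- function(assessments, level) {
  stopifnot(inherits(assessments, "sdg_assessment"), is.numeric(level))
  if (length(unique(assessments$outcome)) > 1L)
    stop("mixed outcomes", call. = FALSE)
  ok <- !assessments$nil & round(assessments$value_2030) > level
  sort(assessments$country[ok])
}
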