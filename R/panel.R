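#' Construct a country panel
#'
#' A `country_panel` holds one country's annual series of public health
#' expenditure (PHE) per capita together with maternal mortality (deaths per
#' 100,000 live births) and under-five mortality (deaths per 1,000 live
#' births). All model fitting works on natural logs of these series, so every
#' value must be strictly positive, and the years must be consecutive.
#'
#' @param country country name (length-1 character).
#' @param years integer vector of consecutive calendar years.
#' @param phe PHE per capita, constant-currency units, one value per year.
#' @param maternal maternal deaths per 100,000 live births, one per year.
#' @param child under-five deaths per 1,000 live births, one per year.
#' @return An object of class `country_panel`: a data frame with columns
#'   `year`, `phe`, `maternal`, `child` and a `country` attribute.
#' @examples
#' p <- country_panel("Atlantis", 2000:2010,
#'                    phe = exp(seq(3, 4, length.out = 11)),
#'                    maternal = seq(400, 300, length.out = 11),
#'                    child = seq(90, 70, length.out = 11))
#' p
#' @export
country_panel <- function(country, years, phe, maternal, child) {
  stopifnot(is.character(country), length(country) == 1L, nzchar(country))
  years <- as.integer(years)
  n <- length(years)
  if (n < 2L)
    stop("panel for ", country, " needs at least 2 years", call. = FALSE)
  if (length(phe) != n || length(maternal) != n || length(child) != n)
    stop("panel for ", country, ": series lengths differ from years",
         call. = FALSE)
  ord <- order(years)
  years <- years[ord]
  if (anyDuplicated(years))
    stop("panel for ", country, ": duplicated years", call. = FALSE)
  gaps <- which(diff(years) != 1L)
  if (length(gaps))
    stop("panel for ", country, ": year gap between ",
         paste(sprintf("%d and %d", years[gaps], years[gaps + 1L]),
               collapse = ", "), call. = FALSE)
  df <- data.frame(year = years,
                   phe = as.numeric(phe)[ord],
                   maternal = as.numeric(maternal)[ord],
                   child = as.numeric(child)[ord])
  for (v in c("phe", "maternal", "child")) {
    bad <- !is.finite(df[[v]]) | df[[v]] <= 0
    if (any(bad))
      stop("panel for ", country, ": non-positive or missing ", v,
           " in year(s) ", paste(df$year[bad], collapse = ", "),
           " (log undefined)", call. = FALSE)
  }
  structure(df, country = country,
            class = c("country_panel", "data.frame"))
}

#' @export
print.country_panel <- function(x, ...) {
  cat("Country panel:", attr(x, "country"), "\n")
  cat(sprintf("  years %d-%d (n = %d)\n", min(x$year), max(x$year), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' @rdname country_panel
#' @param x object to test or extract from.
#' @export
is_country_panel <- function(x) inherits(x, "country_panel")

#' @rdname country_panel
#' @export
panel_country <- function(x) attr(x, "country")

#' Outcome selectors and SDG thresholds
#'
#' The two mortality outcomes and their Sustainable Development Goal 2030
#' targets: 70 maternal deaths per 100,000 live births (SDG 3.1) and 25
#' under-five deaths per 1,000 live births (SDG 3.2).
#'
#' @param outcome `"maternal"` or `"child"`.
#' @return `match_outcome()` returns the validated outcome string;
#'   `sdg_threshold()` its SDG 2030 target level; `outcome_units()` a label
#'   for the denominator.
#' @examples
#' sdg_threshold("maternal")  # 70
#' sdg_threshold("child")     # 25
#' @export
match_outcome <- function(outcome) {
  match.arg(outcome, c("maternal", "child"))
}

#' @rdname match_outcome
#' @export
sdg_threshold <- function(outcome) {
  switch(match_outcome(outcome), maternal = 70, child = 25)
}

#' @rdname match_outcome
#' @export
outcome_units <- function(outcome) {
  switch(match_outcome(outcome),
         maternal = "per 100,000 live births",
         child = "per 1,000 live births")
}

# outcome series of a panel, by selector
outcome_series <- function(panel, outcome) {
  panel[[match_outcome(outcome)]]
}

#' Read country panels from a long-format CSV
#'
#' The canonical input is a long CSV with one row per country-year and
#' columns for country, year, PHE per capita, maternal mortality and child
#' mortality. Wide layouts are not accepted. Column names can be remapped
#' through `dialect`.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param dialect named character vector mapping the canonical names
#'   (`country`, `year`, `phe`, `maternal`, `child`) to the file's column
#'   names. Defaults to the canonical names themselves.
#' @return A named list of [country_panel] objects, one per country,
#'   year-sorted.
#' @seealso [write_panels()] for the inverse operation.
#' @export
read_panels <- function(path, dialect = NULL) {
  canonical <- c("country", "year", "phe", "maternal", "child")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(dialect)) {
    if (is.null(names(dialect)) || !all(names(dialect) %in% canonical))
      stop("dialect names must be a subset of: ",
           paste(canonical, collapse = ", "), call. = FALSE)
    map[names(dialect)] <- dialect
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- map[!map %in% names(raw)]
  if (length(missing_cols))
    stop("input ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- data.frame(country = as.character(raw[[map["country"]]]),
                   year = raw[[map["year"]]],
                   phe = raw[[map["phe"]]],
                   maternal = raw[[map["maternal"]]],
                   child = raw[[map["child"]]],
                   stringsAsFactors = FALSE)
  panels <- lapply(split(df, df$country), function(d) {
    country_panel(d$country[1], d$year, d$phe, d$maternal, d$child)
  })
  panels[order(names(panels))]
}

#' Write country panels to a long-format CSV
#'
#' @param panels a list of [country_panel] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panels <- function(panels, path) {
  stopifnot(all(vapply(panels, is_country_panel, logical(1))))
  rows <- lapply(panels, function(p) {
    cbind(country = panel_country(p), as.data.frame(p))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
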