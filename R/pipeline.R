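#' Render forecast paths as a published-style table
#'
#' Lays out one scenario x outcome set of [recursive_forecast()] paths in
#' the shape of the published forecast tables: one row per country in
#' alphabetical order, integer-rounded mortality at the report years, and
#' an explicit `nil` flag (rendered as the "Nil" sentinel when written to
#' CSV).
#'
#' @param paths list of `forecast_path` objects for a single outcome and
#'   scenario.
#' @param years report years; all must lie inside the forecast horizon.
#' @return A `forecast_table` data frame (columns `country`,
#'   `y<year>`..., `nil`) with `outcome` and `growth` attributes.
#' @export
render_forecast_table <- function(paths, years = c(2021L, 2025L, 2030L)) {
  stopifnot(length(paths) > 0,
            all(vapply(paths, inherits, logical(1), "forecast_path")))
  outcomes <- unique(vapply(paths, `[[`, character(1), "outcome"))
  gs <- unique(vapply(paths, function(p) p$scenario$g, numeric(1)))
  if (length(outcomes) != 1L || length(gs) != 1L)
    stop("paths mix outcomes or scenarios", call. = FALSE)
  rows <- lapply(paths, function(p) {
    missing_years <- setdiff(years, p$years)
    if (length(missing_years))
      stop("report year(s) ", paste(missing_years, collapse = ", "),
           " outside forecast range for ", p$country, call. = FALSE)
    v <- if (p$nil) rep(NA_real_, length(years))
         else unname(p$mortality_rounded[as.character(years)])
    c(list(country = p$country),
      stats::setNames(as.list(v), paste0("y", years)),
      list(nil = p$nil))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df <- df[order(df$country), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, outcome = outcomes, growth = gs,
            class = c("forecast_table", "data.frame"))
}

#' Write / read a forecast table CSV with the Nil sentinel
#'
#' Nil rows are written with the literal sentinel `Nil` in every value
#' column (never 0 or an empty field); `parse_forecast_table()` restores
#' the numeric values and `nil` flags exactly, so rendering and re-parsing
#' round-trips.
#'
#' @param table a `forecast_table`.
#' @param path CSV path.
#' @return `write_forecast_table()` returns `path` invisibly;
#'   `parse_forecast_table()` a `forecast_table`.
#' @export
write_forecast_table <- function(table, path) {
  stopifnot(inherits(table, "forecast_table"))
  out <- as.data.frame(table)
  ycols <- grep("^y[0-9]{4}$", names(out), value = TRUE)
  for (v in ycols) {
    out[[v]] <- ifelse(out$nil, "Nil", format(out[[v]], trim = TRUE))
  }
  out$nil <- NULL
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}

#' @rdname write_forecast_table
#' @param outcome,growth attributes to attach on parse (optional).
#' @export
parse_forecast_table <- function(path, outcome = NULL, growth = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                         colClasses = "character")
  ycols <- grep("^y[0-9]{4}$", names(raw), value = TRUE)
  nil <- apply(raw[ycols] == "Nil", 1L, all)
  df <- data.frame(country = raw$country, stringsAsFactors = FALSE)
  for (v in ycols)
    df[[v]] <- ifelse(nil, NA_real_, suppressWarnings(as.numeric(raw[[v]])))
  df$nil <- nil
  structure(df, outcome = outcome, growth = growth,
            class = c("forecast_table", "data.frame"))
}

#' Render per-country fit summaries in the published layout
#'
#' One row per country with the intercept and lagged-log-PHE coefficient of
#' the maternal and child fits, their standard errors, and conventional
#' two-sided significance stars (1% ***, 5% **, 10% *).
#'
#' @param fits named list (by country) of lists with elements `maternal`
#'   and `child`, each a `predictive_fit`.
#' @return Data frame mirroring the published regression-summary layout.
#' @export
render_fit_table <- function(fits) {
  rows <- lapply(names(fits), function(cn) {
    f <- fits[[cn]]
    one <- function(fit) {
      stars <- significance_stars(
        c(fit$alpha, fit$beta), fit$std_errors[c(1, 2)], fit$df_residual)
      list(constant = fit$alpha, constant_se = unname(fit$std_errors[1]),
           constant_stars = stars[1],
           beta = fit$beta, beta_se = unname(fit$std_errors[2]),
           beta_stars = stars[2])
    }
    m <- one(f$maternal); k <- one(f$child)
    data.frame(country = cn,
               maternal_constant = m$constant,
               maternal_constant_se = m$constant_se,
               maternal_constant_stars = m$constant_stars,
               maternal_beta = m$beta, maternal_beta_se = m$beta_se,
               maternal_beta_stars = m$beta_stars,
               child_constant = k$constant,
               child_constant_se = k$constant_se,
               child_constant_stars = k$constant_stars,
               child_beta = k$beta, child_beta_se = k$beta_se,
               child_beta_stars = k$beta_stars,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$country), , drop = FALSE]
}

#' Run the full forecasting pipeline over a panel collection
#'
#' For every country and outcome: screen the PHE-mortality relationship
#' (full-sample fit), evaluate out-of-sample at the requested split
#' fractions against the benchmark models, project mortality to the
#' horizon under every PHE growth scenario, and classify the 2030 levels
#' against the SDG targets. Countries whose fit fails are logged with a
#' warning and skipped; the run continues. With a fixed `seed` (used only
#' when the inputs themselves were generated upstream, the pipeline itself
#' is deterministic) repeated runs produce identical outputs.
#'
#' @param panels named list of [country_panel] objects.
#' @param outcomes outcomes to run.
#' @param scenarios numeric vector of yearly PHE growth rates.
#' @param fractions split fractions for out-of-sample evaluation.
#' @param estimator `"FQGLS"` or `"OLS"`.
#' @param benchmarks benchmark models for [evaluate()].
#' @param end_year forecast horizon end.
#' @param report_years years printed in forecast tables.
#' @param out_dir optional directory; when given, all tables are written
#'   as CSV (fit summary, evaluation report, one forecast table per
#'   outcome x scenario, assessments) plus a plain-text run manifest.
#' @return List with `fits`, `screens`, `fit_table`, `evaluations` (data
#'   frame), `forecast_tables` (named list of `forecast_table`),
#'   `assessments` (data frame), and `summaries`.
#' @export
run_pipeline <- function(panels, outcomes = c("maternal", "child"),
                         scenarios = c(0.10, 0.20, 0.30),
                         fractions = c(0.50, 0.75),
                         estimator = c("FQGLS", "OLS"),
                         benchmarks = c("HA", "ARIMA"),
                         end_year = 2030L,
                         report_years = c(2021L, 2025L, 2030L),
                         out_dir = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(length(panels) > 0, !is.null(names(panels)),
            length(outcomes) > 0, length(scenarios) > 0,
            all(fractions > 0 & fractions < 1))
  outcomes <- vapply(outcomes, match_outcome, character(1))

  fits <- list(); screens <- list(); evals <- list(); paths <- list()
  for (cn in names(panels)) {
    panel <- panels[[cn]]
    res <- tryCatch({
      cf <- lapply(stats::setNames(outcomes, outcomes), function(oc) {
        if (estimator == "FQGLS") fit_fqgls(panel, oc)
        else fit_ols(panel, oc)
      })
      sc <- lapply(cf, screen_relationship, panel = panel)
      ev <- list()
      for (oc in outcomes) for (fr in fractions) {
        e <- evaluate(panel, oc, fr, estimator, benchmarks)
        ev[[paste(oc, fr)]] <- data.frame(
          country = cn, outcome = oc, fraction = fr, n = e$n,
          mse_unrestricted = e$mse_unrestricted,
          t(e$mse_restricted), t(e$oos_r2), check.names = FALSE)
      }
      base_year <- max(panel$year)
      fp <- list()
      for (oc in outcomes) for (g in scenarios) {
        spec <- scenario_spec(g, base_year, end_year)
        fp[[paste(oc, g)]] <- recursive_forecast(
          cf[[oc]], panel$phe[nrow(panel)],
          outcome_series(panel, oc)[nrow(panel)], spec,
          nil = sc[[oc]]$nil)
      }
      list(cf = cf, sc = sc, ev = ev, fp = fp)
    }, error = function(e) {
      warning("skipping ", cn, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) next
    fits[[cn]] <- res$cf; screens[[cn]] <- res$sc
    evals <- c(evals, res$ev); paths[[cn]] <- res$fp
  }
  if (length(fits) == 0L) stop("no country could be fitted", call. = FALSE)

  forecast_tables <- list()
  for (oc in outcomes) for (g in scenarios) {
    key <- paste(oc, g)
    forecast_tables[[sprintf("%s_g%02.0f", oc, 100 * g)]] <-
      render_forecast_table(lapply(paths, `[[`, key), years = report_years)
  }
  assessments <- do.call(rbind, lapply(names(forecast_tables), function(k) {
    tab <- forecast_tables[[k]]
    a <- classify_sdg(tab)
    a$growth <- attr(tab, "growth")
    a
  }))
  summaries <- lapply(forecast_tables, function(tab)
    summarize_sdg(classify_sdg(tab)))
  fit_table <- if (all(c("maternal", "child") %in% outcomes))
    render_fit_table(fits) else NULL
  evaluations <- do.call(rbind, evals)
  rownames(evaluations) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(fit_table))
      utils::write.csv(fit_table, file.path(out_dir, "fit_table.csv"),
                       row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(evaluations, file.path(out_dir, "evaluations.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    for (k in names(forecast_tables))
      write_forecast_table(forecast_tables[[k]],
                           file.path(out_dir, paste0("forecast_", k, ".csv")))
    utils::write.csv(assessments, file.path(out_dir, "assessments.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    writeLines(c(
      paste("phemort version:", as.character(utils::packageVersion("phemort"))),
      paste("estimator:", estimator),
      paste("scenarios:", paste(scenarios, collapse = ", ")),
      paste("fractions:", paste(fractions, collapse = ", ")),
      paste("countries:", length(fits))),
      file.path(out_dir, "manifest.txt"))
  }
  list(fits = fits, screens = screens, fit_table = fit_table,
       evaluations = evaluations, forecast_tables = forecast_tables,
       assessments = assessments, summaries = summaries)
}
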