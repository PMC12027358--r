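#' Load a packaged published-table fixture
#'
#' The package ships transcriptions of the published per-country regression
#' summary ("T1") and the six out-of-sample forecast tables ("T2".."T7"):
#' maternal and under-five mortality at 2021/2025/2030 under compounded
#' yearly PHE growth of 10, 20 and 30 percent. Countries whose estimated
#' PHE coefficient was non-negative carry an explicit `Nil` flag — they have
#' no forecast, and Nil is never encoded as zero or silently missing.
#'
#' @param table_id one of `"T1"` .. `"T7"`.
#' @return For `"T1"`, a data frame of per-country intercept and
#'   lagged-log-PHE coefficient estimates (with standard errors and
#'   significance stars) for both outcomes. For `"T2"`.."T7"`, a
#'   `forecast_table` data frame with columns `country`, `y2021`, `y2025`,
#'   `y2030`, `nil` and attributes `outcome` and `growth` (the scenario's
#'   yearly proportional PHE growth).
#' @examples
#' t3 <- load_fixture("T3")
#' attr(t3, "outcome")  # "child"
#' sum(t3$nil)          # 2
#' @export
load_fixture <- function(table_id) {
  registry <- list(
    T1 = list(file = "table1_regression.csv"),
    T2 = list(file = "table2_maternal_g10.csv", outcome = "maternal", g = 0.10),
    T3 = list(file = "table3_child_g10.csv",    outcome = "child",    g = 0.10),
    T4 = list(file = "table4_maternal_g20.csv", outcome = "maternal", g = 0.20),
    T5 = list(file = "table5_child_g20.csv",    outcome = "child",    g = 0.20),
    T6 = list(file = "table6_maternal_g30.csv", outcome = "maternal", g = 0.30),
    T7 = list(file = "table7_child_g30.csv",    outcome = "child",    g = 0.30))
  if (!is.character(table_id) || length(table_id) != 1L ||
      !table_id %in% names(registry))
    stop("unknown table id: must be one of ",
         paste(names(registry), collapse = ", "), call. = FALSE)
  entry <- registry[[table_id]]
  path <- system.file("extdata", entry$file, package = "phemort",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (table_id == "T1") return(df)
  df$nil <- as.logical(df$nil)
  bad <- !df$nil & (is.na(df$y2021) | is.na(df$y2025) | is.na(df$y2030))
  if (any(bad))
    stop("fixture ", table_id, ": non-Nil row with missing values",
         call. = FALSE)
  structure(df, outcome = entry$outcome, growth = entry$g,
            class = c("forecast_table", "data.frame"))
}
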