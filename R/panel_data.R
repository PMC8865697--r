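# Country-year panel container, CSV I/O, validation, and the LMIC income
# filter.  A panel is a plain list with class "u5_panel":
#   $records    data.frame, one row per (country_id, year), canonical columns
#   $countries  data.frame: country_id, region, income_group, gni_pc
#   $year_range integer c(min, max)
# Missing values are NA, never 0 (zero is a legal value for several
# covariates).  Record order is always country_id then year, so iteration is
# deterministic regardless of input order.

#' Canonical panel column names
#'
#' Column dialect for panel CSV files: `country_id` (ISO3-style code),
#' `year`, `u5mr` (under-5 deaths per 1,000 live births), `gdp_pc`
#' (GDP per capita, constant 2010 US$), the socio-economic covariates
#' `electric_power_kwh_pc`, `women_parliament_pct`, `total_fertility`,
#' the health-service covariates `physicians_per_1000`, `dpt_coverage_pct`,
#' plus `under5_pop` (persons aged 0-4), `gni_pc` (GNI per capita, current
#' US$, used for income classification), `region` and `income_group`.
#'
#' @return Character vector of canonical column names.
#' @export
panel_columns <- function() {
  c("country_id", "year", "u5mr", "gdp_pc",
    "electric_power_kwh_pc", "women_parliament_pct", "total_fertility",
    "physicians_per_1000", "dpt_coverage_pct",
    "under5_pop", "gni_pc", "region", "income_group")
}

# Numeric measurement columns (everything except keys and labels).
panel_value_columns <- function() {
  setdiff(panel_columns(), c("country_id", "year", "region", "income_group"))
}

# Variables summarised by default in panel_summary(); the main analysis
# variables, in a fixed display order.
panel_main_variables <- function() {
  c("u5mr", "gdp_pc", "physicians_per_1000", "electric_power_kwh_pc",
    "women_parliament_pct", "total_fertility", "dpt_coverage_pct")
}

u5_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "u5_error")))
}

#' Construct a validated country-year panel
#'
#' @param records data.frame with at least `country_id` and `year`; any
#'   canonical column (see [panel_columns()]) may be present, others are
#'   created as all-`NA`.  Extra columns are dropped.
#' @param year_range optional integer length-2 vector; defaults to the
#'   observed year range.
#' @return An object of class `u5_panel`.
#' @export
panel <- function(records, year_range = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (required in c("country_id", "year")) {
    if (!required %in% names(records))
      u5_error(sprintf("missing required column: %s", required),
               "u5_format_error")
  }
  records$country_id <- as.character(records$country_id)
  records$year <- suppressWarnings(as.integer(records$year))
  bad <- is.na(records$country_id) | records$country_id == "" |
    is.na(records$year)
  if (any(bad)) records <- records[!bad, , drop = FALSE]
  for (col in setdiff(panel_columns(), names(records))) {
    records[[col]] <- if (col %in% c("region", "income_group"))
      NA_character_ else NA_real_
  }
  for (col in panel_value_columns()) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }
  for (col in c("region", "income_group")) {
    records[[col]] <- as.character(records[[col]])
  }
  records <- records[panel_columns()]
  records <- records[order(records$country_id, records$year), , drop = FALSE]
  rownames(records) <- NULL

  key <- paste(records$country_id, records$year)
  if (anyDuplicated(key)) {
    u5_error(sprintf("duplicate (country, year) key: %s",
                     paste(unique(key[duplicated(key)]), collapse = ", ")),
             "u5_validation_error")
  }
  validate_records(records)

  if (is.null(year_range)) {
    year_range <- range(records$year)
  }
  year_range <- as.integer(year_range)
  if (any(records$year < year_range[1] | records$year > year_range[2]))
    u5_error("record year outside configured year range", "u5_range_error")

  first_value <- function(x) if (all(is.na(x))) x[1] else x[!is.na(x)][1]
  countries <- do.call(rbind, lapply(
    split(records, records$country_id),
    function(d) data.frame(country_id = d$country_id[1],
                           region = first_value(d$region),
                           income_group = first_value(d$income_group),
                           gni_pc = first_value(d$gni_pc),
                           stringsAsFactors = FALSE)))
  countries <- countries[order(countries$country_id), , drop = FALSE]
  rownames(countries) <- NULL

  structure(list(records = records, countries = countries,
                 year_range = year_range),
            class = "u5_panel")
}

validate_records <- function(records) {
  check_pos <- function(col) {
    bad <- !is.na(records[[col]]) & records[[col]] <= 0
    if (any(bad))
      u5_error(sprintf("non-positive %s for %s", col,
                       paste(records$country_id[bad], records$year[bad],
                             sep = ":", collapse = ", ")),
               "u5_validation_error")
  }
  check_pos("u5mr")
  check_pos("gdp_pc")
  for (col in c("women_parliament_pct", "dpt_coverage_pct")) {
    bad <- !is.na(records[[col]]) &
      (records[[col]] < 0 | records[[col]] > 100)
    if (any(bad))
      u5_error(sprintf("%s outside [0, 100]", col), "u5_validation_error")
  }
  bad <- !is.na(records$under5_pop) & records$under5_pop < 0
  if (any(bad)) u5_error("negative under5_pop", "u5_validation_error")
  invisible(records)
}

#' @export
print.u5_panel <- function(x, ...) {
  cat(sprintf("<u5_panel> %d countries, %d records, years %d-%d\n",
              nrow(x$countries), nrow(x$records),
              x$year_range[1], x$year_range[2]))
  invisible(x)
}

#' Read a country-year panel from CSV
#'
#' Long layout is canonical: one row per (country, year) with the columns of
#' [panel_columns()] (`country_id` and `year` required, the rest optional).
#' Wide layout is accepted on read only: one row per (country, variable) with
#' columns `country_id`, `variable`, optional `region`/`income_group`/
#' `gni_pc`, and one column per year (`1990`, `1991`, ... — a leading "X"
#' added by spreadsheet tools is tolerated).
#'
#' Empty cells and the literal strings `NA` are missing markers.  Rows whose
#' country or year cannot be parsed are dropped; a duplicated (country, year)
#' key is an error.
#'
#' @param path CSV file path.
#' @param layout `"long"` (default) or `"wide"`.
#' @return A [panel()] object.
#' @export
load_panel <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path))
    u5_error(sprintf("file not found: %s", path), "u5_io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  if (layout == "long") {
    for (col in c("country_id", "year", "u5mr", "gdp_pc")) {
      if (!col %in% names(raw))
        u5_error(sprintf("missing required column: %s", col),
                 "u5_format_error")
    }
    return(panel(raw))
  }
  # wide: melt year columns into long form
  for (col in c("country_id", "variable")) {
    if (!col %in% names(raw))
      u5_error(sprintf("missing required column: %s", col), "u5_format_error")
  }
  year_cols <- grep("^X?[0-9]{4}$", names(raw), value = TRUE)
  if (length(year_cols) == 0)
    u5_error("missing required column: <year columns>", "u5_format_error")
  meta_cols <- intersect(c("region", "income_group", "gni_pc"), names(raw))
  long <- do.call(rbind, lapply(year_cols, function(yc) {
    year <- as.integer(sub("^X", "", yc))
    d <- data.frame(country_id = raw$country_id, year = year,
                    variable = raw$variable,
                    value = suppressWarnings(as.numeric(raw[[yc]])),
                    stringsAsFactors = FALSE)
    for (mc in meta_cols) d[[mc]] <- raw[[mc]]
    d
  }))
  keys <- unique(long[c("country_id", "year")])
  wide <- keys
  for (v in unique(long$variable)) {
    if (!v %in% panel_value_columns()) next
    sub <- long[long$variable == v, c("country_id", "year", "value")]
    names(sub)[3] <- v
    wide <- merge(wide, sub, by = c("country_id", "year"), all.x = TRUE)
  }
  for (mc in meta_cols) {
    sub <- unique(long[!is.na(long[[mc]]), c("country_id", mc)])
    wide <- merge(wide, sub, by = "country_id", all.x = TRUE)
  }
  panel(wide)
}

#' Write a panel to CSV (long layout)
#'
#' Missing values are written as empty cells; numbers are written with full
#' precision so that load -> write -> load round-trips values exactly.
#'
#' @param panel a [panel()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "u5_panel"))
  records <- panel$records
  for (col in panel_value_columns())
    records[[col]] <- format_full(records[[col]])
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

# full-precision decimal formatting (round-trip safe for doubles)
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE)
  }, character(1))
  out
}

#' Keep only low- and middle-income countries
#'
#' Retains countries whose classification GNI per capita is strictly below
#' `gni_threshold` (the World Bank 2020 upper-middle-income ceiling of
#' 12,375 US$).  When a country has no GNI value, its `income_group` label is
#' authoritative: `low`, `lower-middle` and `upper-middle` are retained.
#' A country with neither GNI nor label is a classification error.
#'
#' @param panel a [panel()] object.
#' @param gni_threshold US$ cutoff, default 12375; comparison is strict `<`.
#' @return The filtered panel (possibly with zero countries).
#' @export
filter_lmic <- function(panel, gni_threshold = 12375) {
  stopifnot(inherits(panel, "u5_panel"))
  ctry <- panel$countries
  lmic_labels <- c("low", "lower-middle", "upper-middle")
  has_gni <- !is.na(ctry$gni_pc)
  label <- tolower(trimws(ifelse(is.na(ctry$income_group), "",
                                 ctry$income_group)))
  has_label <- label %in% lmic_labels | label == "high"
  unclassified <- !has_gni & !has_label
  if (any(unclassified))
    u5_error(sprintf("countries lack both gni_pc and income_group: %s",
                     paste(ctry$country_id[unclassified], collapse = ", ")),
             "u5_classification_error")
  keep <- ifelse(has_gni, ctry$gni_pc < gni_threshold, label %in% lmic_labels)
  kept_ids <- ctry$country_id[keep]
  records <- panel$records[panel$records$country_id %in% kept_ids, ,
                           drop = FALSE]
  if (nrow(records) == 0) {
    out <- panel
    out$records <- records
    out$countries <- ctry[0, , drop = FALSE]
    return(out)
  }
  panel(records, year_range = panel$year_range)
}

#' Per-year descriptive statistics with missingness shares
#'
#' For each variable and requested year reports the mean and standard
#' deviation over non-missing values and the share of missing observations,
#' `100 * missing / countries`.  A country with no record at all for a year
#' counts as missing.
#'
#' @param panel a [panel()] object.
#' @param years integer years, all within the panel range.
#' @param variables variables to summarise (default: the main analysis
#'   variables).
#' @return data.frame with columns variable, year, mean, sd, missing_pct.
#' @export
panel_summary <- function(panel, years,
                          variables = panel_main_variables()) {
  stopifnot(inherits(panel, "u5_panel"))
  years <- as.integer(years)
  if (any(years < panel$year_range[1] | years > panel$year_range[2]))
    u5_error("requested year outside panel range", "u5_range_error")
  n_countries <- nrow(panel$countries)
  rows <- expand.grid(variable = variables, year = years,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    v <- rows$variable[i]; yr <- rows$year[i]
    x <- panel$records[[v]][panel$records$year == yr]
    obs <- x[!is.na(x)]
    data.frame(variable = v, year = yr,
               mean = if (length(obs)) mean(obs) else NA_real_,
               sd = if (length(obs) > 1) stats::sd(obs) else
                 if (length(obs) == 1) 0 else NA_real_,
               missing_pct = 100 * (n_countries - length(obs)) / n_countries,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
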