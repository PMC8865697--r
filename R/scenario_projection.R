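# Counterfactual GDP-reduction scenarios.  A scenario removes a fraction r
# of the base-year (2019) GDP per capita; the projected under-5 mortality
# rate is the model prediction at the reduced GDP, so
#     u5mr(r) = u5mr(0) * (1 - r)^beta_j
# exactly (naive exp() retransformation, no smearing).  Deaths apply the
# rate to the under-5 population:  deaths = u5mr * pop / 1000.  "Additional
# lives lost" is scenario deaths minus the r = 0 baseline of the same fit.

#' Scenario definition
#'
#' @param r fraction of base-year GDP per capita removed, `0 <= r < 1`.
#' @param label optional display label (default e.g. `"5%"`).
#' @return list of class `u5_scenario`.
#' @export
scenario <- function(r, label = NULL) {
  if (!is.numeric(r) || r < 0 || r >= 1)
    u5_error("scenario reduction r must satisfy 0 <= r < 1",
             "u5_domain_error")
  if (is.null(label))
    label <- if (r == 0) "baseline" else sprintf("%g%%", 100 * r)
  structure(list(r = r, label = label), class = "u5_scenario")
}

#' Project the under-5 mortality rate under a GDP reduction
#'
#' Evaluates `exp(alpha_j + beta_j * log((1 - r) * base_gdp))`, i.e. the
#' baseline prediction multiplied by `(1 - r)^beta_j`.
#'
#' @param fit a `u5_fit`.
#' @param country_id fitted country.
#' @param base_gdp base-year GDP per capita (US$), > 0.
#' @param r GDP reduction fraction in [0, 1).
#' @return projected U5MR (deaths per 1,000 live births).
#' @export
project_u5mr <- function(fit, country_id, base_gdp, r) {
  stopifnot(inherits(fit, "u5_fit"))
  if (!is.numeric(base_gdp) || base_gdp <= 0)
    u5_error("base_gdp must be positive", "u5_domain_error")
  if (!is.numeric(r) || r < 0 || r >= 1)
    u5_error("r must satisfy 0 <= r < 1", "u5_domain_error")
  i <- match(country_id, fit$countries$country_id)
  if (is.na(i))
    u5_error(sprintf("country not in fit: %s", country_id),
             "u5_lookup_error")
  exp(fit$countries$alpha[i] +
        fit$countries$beta[i] * log((1 - r) * base_gdp))
}

#' Deaths implied by a mortality rate and an exposed population
#'
#' `deaths = u5mr * under5_pop / 1000`, kept continuous; rounding happens
#' only at render time.
#'
#' @param u5mr deaths per 1,000 (>= 0).
#' @param under5_pop persons aged 0-4 (>= 0).
#' @return expected deaths (numeric, vectorised).
#' @export
scenario_deaths <- function(u5mr, under5_pop) {
  if (any(u5mr < 0, na.rm = TRUE) || any(under5_pop < 0, na.rm = TRUE))
    u5_error("u5mr and under5_pop must be non-negative", "u5_domain_error")
  u5mr * under5_pop / 1000
}

#' Run GDP-reduction scenarios over a fitted panel
#'
#' For every fitted country with a base-year GDP and a population-year
#' under-5 population, computes projected U5MR and deaths under each
#' reduction, 95% bounds from the log-scale prediction SE
#' (`exp(log prediction +/- z * s_pred)`, hence log-symmetric), and
#' additional deaths relative to the r = 0 baseline.  Countries missing
#' base-year GDP or population are excluded from totals with a warning and
#' listed in `$excluded`.
#'
#' @param fit a `u5_fit`.
#' @param panel a [panel()] object supplying base-year GDP and
#'   population-year under-5 population.
#' @param reductions numeric reductions; 0 is added automatically as the
#'   baseline scenario.
#' @param base_year GDP base year (default 2019).
#' @param pop_year population year (default 2020).
#' @param level confidence level for the bounds (default 0.95).
#' @return object of class `u5_scenario_result`: `$by_country` (long
#'   data.frame: country_id, region, income_group, r, u5mr, deaths,
#'   deaths_lower, deaths_upper, additional), `$totals` (per r: deaths,
#'   additional), `$excluded`, and the call parameters.
#' @export
run_scenarios <- function(fit, panel, reductions = c(0, 0.05, 0.10, 0.15),
                          base_year = 2019, pop_year = 2020, level = 0.95) {
  stopifnot(inherits(fit, "u5_fit"), inherits(panel, "u5_panel"))
  reductions <- sort(unique(c(0, reductions)))
  for (r in reductions) scenario(r)  # validates the range
  z <- stats::qnorm(1 - (1 - level) / 2)

  records <- panel$records
  base <- records[records$year == base_year, c("country_id", "gdp_pc")]
  pop <- records[records$year == pop_year, c("country_id", "under5_pop")]
  ctab <- fit$countries
  info <- merge(merge(ctab, base, by = "country_id", all.x = TRUE),
                pop, by = "country_id", all.x = TRUE)

  missing_input <- is.na(info$gdp_pc) | is.na(info$under5_pop)
  excluded <- info$country_id[missing_input]
  if (length(excluded))
    warning(sprintf("excluding %d country(ies) without base-year GDP or %d under-5 population: %s",
                    length(excluded), pop_year,
                    paste(excluded, collapse = ", ")))
  info <- info[!missing_input, , drop = FALSE]
  info <- info[order(info$country_id), , drop = FALSE]

  by_country <- do.call(rbind, lapply(reductions, function(r) {
    log_mu <- info$alpha + info$beta * log((1 - r) * info$gdp_pc)
    u5mr <- exp(log_mu)
    deaths <- scenario_deaths(u5mr, info$under5_pop)
    lower <- scenario_deaths(exp(log_mu - z * info$s_pred), info$under5_pop)
    upper <- scenario_deaths(exp(log_mu + z * info$s_pred), info$under5_pop)
    data.frame(country_id = info$country_id, region = info$region,
               income_group = info$income_group, r = r,
               u5mr = u5mr, deaths = deaths,
               deaths_lower = lower, deaths_upper = upper,
               under5_pop = info$under5_pop,
               stringsAsFactors = FALSE)
  }))
  base_deaths <- by_country$deaths[by_country$r == 0]
  names(base_deaths) <- by_country$country_id[by_country$r == 0]
  by_country$additional <-
    by_country$deaths - base_deaths[by_country$country_id]
  by_country$additional_lower <- by_country$deaths_lower -
    by_country$deaths_lower[match(paste(by_country$country_id, 0),
                                  paste(by_country$country_id,
                                        by_country$r))]
  by_country$additional_upper <- by_country$deaths_upper -
    by_country$deaths_upper[match(paste(by_country$country_id, 0),
                                  paste(by_country$country_id,
                                        by_country$r))]
  rownames(by_country) <- NULL

  totals <- do.call(rbind, lapply(reductions, function(r) {
    sub <- by_country[by_country$r == r, , drop = FALSE]
    data.frame(r = r, deaths = sum(sub$deaths),
               additional = sum(sub$additional))
  }))

  structure(list(by_country = by_country, totals = totals,
                 excluded = excluded, reductions = reductions,
                 base_year = base_year, pop_year = pop_year, level = level),
            class = "u5_scenario_result")
}

#' @export
print.u5_scenario_result <- function(x, ...) {
  cat(sprintf("<scenario result> %d countries, base year %d\n",
              length(unique(x$by_country$country_id)), x$base_year))
  print(x$totals, row.names = FALSE)
  invisible(x)
}

#' Write / read a scenario result as CSV
#'
#' The long per-country table plus a header comment carrying the call
#' parameters; full numeric precision so values round-trip.
#'
#' @param result a `u5_scenario_result`.
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_scenarios_csv <- function(result, path) {
  stopifnot(inherits(result, "u5_scenario_result"))
  d <- result$by_country
  num <- vapply(d, is.numeric, logical(1)) & names(d) != "r"
  for (col in names(d)[num]) d[[col]] <- format_full(d[[col]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# u5shock-scenarios/1 base_year=%d pop_year=%d level=%g",
                     result$base_year, result$pop_year, result$level), con)
  utils::write.csv(d, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_scenarios_csv
#' @export
read_scenarios_csv <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^# u5shock-scenarios/1", header))
    u5_error("unrecognised scenarios file", "u5_format_error")
  meta <- regmatches(header, gregexpr("[a-z_]+=[0-9.]+", header))[[1]]
  meta <- stats::setNames(
    as.numeric(sub(".*=", "", meta)), sub("=.*", "", meta))
  d <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  reductions <- sort(unique(d$r))
  totals <- do.call(rbind, lapply(reductions, function(r) {
    sub <- d[d$r == r, , drop = FALSE]
    data.frame(r = r, deaths = sum(sub$deaths),
               additional = sum(sub$additional))
  }))
  structure(list(by_country = d, totals = totals, excluded = character(0),
                 reductions = reductions,
                 base_year = as.integer(meta[["base_year"]]),
                 pop_year = as.integer(meta[["pop_year"]]),
                 level = meta[["level"]]),
            class = "u5_scenario_result")
}
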