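# Aggregation and rendering: regional / income-group / global totals,
# shares of additional deaths, percent increases above baseline, top-N
# country tables, and CSV renderers.  All sums are computed on unrounded
# values; rounding (half-up) happens only at render time.

#' Round half-up
#'
#' Commercial rounding (0.5 always away from zero), as used for printed
#' death counts; base R's `round()` rounds half to even.
#'
#' @param x numeric.
#' @param digits decimal places (default 0).
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Aggregate scenario results by region, income group, or globally
#'
#' Totals are exact sums of unrounded country values; each group's share of
#' additional deaths and the percent increase above baseline are computed
#' before any rounding.
#'
#' @param result a `u5_scenario_result`.
#' @param by `"region"`, `"income_group"` or `"global"`.
#' @return object of class `u5_aggregate_report`: `$table` with columns
#'   group, r, deaths, additional, share_pct (share of the global additional
#'   deaths; `NA` for the baseline scenario), pct_increase.
#' @export
aggregate_scenarios <- function(result,
                                by = c("region", "income_group", "global")) {
  stopifnot(inherits(result, "u5_scenario_result"))
  by <- match.arg(by)
  d <- result$by_country
  if (by == "global") {
    d$group_ <- "global"
  } else {
    if (anyNA(d[[by]]))
      u5_error(sprintf("countries missing %s label: %s", by,
                       paste(unique(d$country_id[is.na(d[[by]])]),
                             collapse = ", ")),
               "u5_aggregation_error")
    d$group_ <- d[[by]]
  }
  tab <- do.call(rbind, lapply(sort(unique(d$r)), function(r) {
    sub <- d[d$r == r, , drop = FALSE]
    global_add <- sum(sub$additional)
    agg <- do.call(rbind, lapply(sort(unique(sub$group_)), function(g) {
      gs <- sub[sub$group_ == g, , drop = FALSE]
      data.frame(group = g, r = r, deaths = sum(gs$deaths),
                 additional = sum(gs$additional),
                 share_pct = if (r == 0) NA_real_ else
                   100 * sum(gs$additional) / global_add,
                 stringsAsFactors = FALSE)
    }))
    agg
  }))
  base_by_group <- tab$deaths[tab$r == 0]
  names(base_by_group) <- tab$group[tab$r == 0]
  tab$pct_increase <- 100 * tab$additional / base_by_group[tab$group]
  rownames(tab) <- NULL
  structure(list(table = tab, by = by), class = "u5_aggregate_report")
}

#' Percent increase of additional deaths above the baseline total
#'
#' `100 * additional_total / baseline_total`, reported to one decimal
#' (half-up).
#'
#' @param additional_total additional deaths.
#' @param baseline_total baseline deaths, > 0.
#' @return percentage, one decimal.
#' @export
percent_increase <- function(additional_total, baseline_total) {
  if (any(baseline_total <= 0))
    u5_error("baseline total must be positive", "u5_domain_error")
  round_half_up(100 * additional_total / baseline_total, 1)
}

#' Top-N countries by additional deaths
#'
#' @param result a `u5_scenario_result`.
#' @param r scenario used for ranking (default the largest reduction).
#' @param n table size (default 10).
#' @return data.frame sorted descending by additional deaths, ties broken
#'   by country_id.
#' @export
top_countries <- function(result, r = max(result$reductions), n = 10) {
  stopifnot(inherits(result, "u5_scenario_result"))
  sub <- result$by_country[result$by_country$r == r, , drop = FALSE]
  sub <- sub[order(-sub$additional, sub$country_id), , drop = FALSE]
  utils::head(sub, n)
}

#' Render result tables to CSV files
#'
#' Writes `scenario_table.csv` (one row per country: baseline deaths and
#' bounds, then per-reduction deaths, additional deaths and bounds —
#' top `top_n` countries by additional deaths under the largest reduction,
#' or all countries if `top_n = Inf`), `aggregate_region.csv`,
#' `aggregate_income_group.csv`, and `mc_summary.csv` when an MC summary is
#' supplied.  Death counts are rounded half-up to integers and percentages
#' to one decimal at render time only.
#'
#' @param result a `u5_scenario_result`.
#' @param mc optional `u5_mc_summary`.
#' @param out_dir output directory (created if needed).
#' @param top_n rows in the country table (default 10).
#' @return character vector of written paths, invisibly.
#' @export
render_tables <- function(result, mc = NULL, out_dir, top_n = 10) {
  stopifnot(inherits(result, "u5_scenario_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  d <- result$by_country
  reds <- setdiff(result$reductions, 0)
  base <- d[d$r == 0, , drop = FALSE]
  wide <- data.frame(country = base$country_id,
                     deaths = round_half_up(base$deaths),
                     lower = round_half_up(base$deaths_lower),
                     upper = round_half_up(base$deaths_upper),
                     stringsAsFactors = FALSE)
  for (r in reds) {
    sub <- d[d$r == r, , drop = FALSE]
    i <- match(wide$country, sub$country_id)
    tag <- sprintf("%g", 100 * r)
    wide[[paste0("deaths_", tag)]] <- round_half_up(sub$deaths[i])
    wide[[paste0("additional_", tag)]] <- round_half_up(sub$additional[i])
    wide[[paste0("lower_", tag)]] <- round_half_up(sub$deaths_lower[i])
    wide[[paste0("upper_", tag)]] <- round_half_up(sub$deaths_upper[i])
  }
  if (nrow(wide) > 0 && length(reds) > 0 && is.finite(top_n)) {
    order_col <- paste0("additional_", sprintf("%g", 100 * max(reds)))
    wide <- wide[order(-wide[[order_col]], wide$country), , drop = FALSE]
    wide <- utils::head(wide, top_n)
  }
  p <- file.path(out_dir, "scenario_table.csv")
  utils::write.csv(wide, p, row.names = FALSE)
  paths <- c(paths, p)

  for (by in c("region", "income_group")) {
    if (nrow(d) == 0 || all(is.na(d[[by]]))) next
    agg <- aggregate_scenarios(result, by)$table
    agg$deaths <- round_half_up(agg$deaths)
    agg$additional <- round_half_up(agg$additional)
    agg$share_pct <- round_half_up(agg$share_pct, 1)
    agg$pct_increase <- round_half_up(agg$pct_increase, 1)
    p <- file.path(out_dir, paste0("aggregate_", by, ".csv"))
    utils::write.csv(agg, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  if (!is.null(mc)) {
    stopifnot(inherits(mc, "u5_mc_summary"))
    s <- mc$summary
    out <- data.frame(scenario = sprintf("%g%% recession", 100 * s$r),
                      point = round_half_up(s$point),
                      mc_mean = round_half_up(s$mean),
                      mc_sd = round_half_up(s$sd),
                      lower = round_half_up(s$lower),
                      upper = round_half_up(s$upper))
    p <- file.path(out_dir, "mc_summary.csv")
    utils::write.csv(out, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
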