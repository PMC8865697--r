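# Missing-data imputation: trailing five-year moving average for GDP per
# capita, and an iterative chained linear-Gaussian ("multivariate normal
# regression") scheme for the socio-economic and health-service covariates.
# Deterministic by default (conditional-mean fills); stochastic draws can be
# switched on for sensitivity work.

#' Impute a GDP series with a trailing moving average
#'
#' Each missing value at year t is replaced by the mean of the `window` most
#' recent preceding non-missing values, where previously imputed values count
#' as available — so runs of missing years are filled left-to-right
#' recursively.  Leading missing values, which have no predecessors, are
#' back-filled with the mean of the earliest `window` available values.
#' Observed values are never altered.
#'
#' @param series numeric vector ordered by contiguous year; `NA` = missing.
#' @param window number of preceding values averaged (default 5).
#' @return Completed numeric vector, same length.
#' @export
impute_gdp_moving_average <- function(series, window = 5) {
  x <- as.numeric(series)
  if (all(is.na(x)))
    u5_error("GDP series entirely missing; cannot impute", "u5_impute_error")
  stopifnot(window >= 1)
  for (i in seq_along(x)) {
    if (!is.na(x[i])) next
    prev <- x[seq_len(i - 1)]
    prev <- prev[!is.na(prev)]
    if (length(prev) == 0) next         # leading block, handled below
    x[i] <- mean(utils::tail(prev, window))
  }
  if (anyNA(x)) {                       # leading missing values
    avail <- x[!is.na(x)]
    x[is.na(x)] <- mean(utils::head(avail, window))
  }
  x
}

#' Impute GDP per capita for every country in a panel
#'
#' Applies [impute_gdp_moving_average()] to each country's year-ordered GDP
#' series.
#'
#' @param panel a [panel()] object.
#' @param window moving-average window in years.
#' @return Panel with `gdp_pc` completed.
#' @export
impute_panel_gdp <- function(panel, window = 5) {
  stopifnot(inherits(panel, "u5_panel"))
  records <- panel$records
  for (id in panel$countries$country_id) {
    idx <- which(records$country_id == id)
    idx <- idx[order(records$year[idx])]
    if (all(is.na(records$gdp_pc[idx]))) next  # left missing; caught later
    records$gdp_pc[idx] <-
      impute_gdp_moving_average(records$gdp_pc[idx], window)
  }
  out <- panel
  out$records <- records
  out
}

# Default covariate set for multivariate-normal imputation.
covariate_variables <- function() {
  c("electric_power_kwh_pc", "women_parliament_pct", "total_fertility",
    "physicians_per_1000", "dpt_coverage_pct")
}

# Valid ranges enforced on imputed cells only (observed cells are validated
# upstream and never altered).
covariate_bounds <- function(variable) {
  switch(variable,
         women_parliament_pct = c(0, 100),
         dpt_coverage_pct = c(0, 100),
         total_fertility = c(0.1, Inf),
         physicians_per_1000 = c(0, Inf),
         electric_power_kwh_pc = c(0, Inf),
         c(-Inf, Inf))
}

#' Iterative multivariate-normal regression imputation of covariates
#'
#' Chained linear-Gaussian scheme: missing cells are initialised at variable
#' means, then each variable with missingness is repeatedly regressed (OLS,
#' fitted on its observed rows) on the other covariates plus log GDP per
#' capita and calendar year, and its missing cells are replaced by the
#' conditional predictions.  Iteration stops when the maximum absolute
#' change across imputed cells, on the standardised (per-variable SD) scale,
#' falls below `tol`, or after `max_iter` sweeps.  The default is fully
#' deterministic; with `stochastic = TRUE` a residual draw
#' N(0, sigma_hat^2) is added to each fill, using `seed`.
#'
#' GDP per capita must be complete before calling (see
#' [impute_panel_gdp()]).  Observed cells are never altered; imputed
#' percentage variables are clamped to their valid range.
#'
#' @param panel a [panel()] object with complete `gdp_pc`.
#' @param variables covariates to impute (default all five).
#' @param max_iter maximum sweeps (default 50).
#' @param tol convergence tolerance on the standardised scale (default 1e-6).
#' @param stochastic add residual noise to fills (default FALSE).
#' @param seed integer seed, used only when `stochastic = TRUE`.
#' @return list with `panel` (completed) and `report` (class
#'   `u5_imputation_report`: per-variable imputed counts, iterations used,
#'   max absolute change at exit, convergence flag, warnings, seed).
#' @export
impute_covariates_mvn <- function(panel, variables = covariate_variables(),
                                  max_iter = 50, tol = 1e-6,
                                  stochastic = FALSE, seed = NULL) {
  stopifnot(inherits(panel, "u5_panel"))
  records <- panel$records
  if (anyNA(records$gdp_pc))
    u5_error("gdp_pc has missing values; impute GDP first", "u5_impute_error")
  variables <- intersect(variables, panel_value_columns())
  warnings <- character(0)

  obs_share <- vapply(variables,
                      function(v) mean(!is.na(records[[v]])), numeric(1))
  if (any(obs_share < 0.30))
    u5_error(sprintf("variables with < 30%% observed cells: %s",
                     paste(variables[obs_share < 0.30], collapse = ", ")),
             "u5_impute_error")

  miss <- lapply(variables, function(v) which(is.na(records[[v]])))
  names(miss) <- variables
  n_missing <- vapply(miss, length, integer(1))
  if (sum(n_missing) == 0) {
    report <- structure(
      list(imputed = n_missing, iterations = 0L, max_change = 0,
           converged = TRUE, warnings = warnings, seed = seed,
           stochastic = stochastic),
      class = "u5_imputation_report")
    return(list(panel = panel, report = report))
  }

  sds <- vapply(variables, function(v) {
    s <- stats::sd(records[[v]], na.rm = TRUE)
    if (is.na(s) || s == 0) 1 else s
  }, numeric(1))

  if (stochastic && !is.null(seed)) set.seed(as.integer(seed))

  # initialise at observed means
  for (v in variables) {
    records[[v]][miss[[v]]] <- mean(records[[v]], na.rm = TRUE)
  }
  records$log_gdp_imp_ <- log(records$gdp_pc)
  active <- variables[n_missing > 0]

  iterations <- 0L
  max_change <- Inf
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    max_change <- 0
    for (v in active) {
      predictors <- c(setdiff(variables, v), "log_gdp_imp_", "year")
      form <- stats::as.formula(
        paste(v, "~", paste(predictors, collapse = " + ")))
      obs_rows <- setdiff(seq_len(nrow(records)), miss[[v]])
      fit <- stats::lm(form, data = records[obs_rows, , drop = FALSE])
      if (anyNA(stats::coef(fit))) {
        dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
        warnings <- c(warnings, sprintf(
          "singular design for %s; dropped predictor(s): %s",
          v, paste(dropped, collapse = ", ")))
        predictors <- setdiff(predictors, dropped)
        form <- stats::as.formula(
          paste(v, "~", paste(predictors, collapse = " + ")))
        fit <- stats::lm(form, data = records[obs_rows, , drop = FALSE])
      }
      pred <- stats::predict(fit, newdata = records[miss[[v]], , drop = FALSE])
      if (stochastic)
        pred <- pred + stats::rnorm(length(pred), 0, stats::sigma(fit))
      b <- covariate_bounds(v)
      pred <- pmin(pmax(pred, b[1]), b[2])
      change <- max(abs(pred - records[[v]][miss[[v]]])) / sds[[v]]
      max_change <- max(max_change, change)
      records[[v]][miss[[v]]] <- pred
    }
    if (max_change < tol) break
  }
  converged <- max_change < tol
  if (!converged)
    warnings <- c(warnings, sprintf(
      "not converged after %d iterations (max change %.3g)",
      iterations, max_change))

  records$log_gdp_imp_ <- NULL
  out <- panel
  out$records <- records
  report <- structure(
    list(imputed = n_missing, iterations = iterations,
         max_change = max_change, converged = converged,
         warnings = warnings, seed = seed, stochastic = stochastic),
    class = "u5_imputation_report")
  list(panel = out, report = report)
}

#' @export
print.u5_imputation_report <- function(x, ...) {
  cat(sprintf("<imputation report> %d cells imputed, %d iteration(s), %s\n",
              sum(x$imputed), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  for (w in x$warnings) cat(" warning:", w, "\n")
  invisible(x)
}
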