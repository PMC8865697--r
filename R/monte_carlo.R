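# Monte Carlo propagation of elasticity uncertainty.  Each iteration draws
# every country's slope beta*_j ~ Normal(beta_j, se_j^2) independently and
# re-evaluates scenario deaths anchored at the point-estimate baseline:
#     deaths_j(r; beta*) = baseline_deaths_j * (1 - r)^beta*_j
# Intercepts (and hence baseline deaths) are held at their point estimates,
# so the r = 0 scenario is unchanged and the sampled quantity is the
# additional-deaths total.  Draws use per-country substreams derived from
# the root seed and the country code, making results invariant to country
# order.

# Deterministic per-country substream seed: a small string hash of the
# country code mixed with the root seed, kept below 2^31.
country_stream_seed <- function(seed, country_id) {
  h <- 0
  for (ch in utf8ToInt(country_id)) h <- (h * 131 + ch) %% 1999999943
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + h) %% 2147483629)
}

#' Monte Carlo uncertainty for scenario death totals
#'
#' @param fit a `u5_fit` providing `(beta, se)` per country.
#' @param panel a [panel()] object (base-year GDP, population).
#' @param reductions non-zero GDP reductions (default 0.05, 0.10, 0.15).
#' @param n_iter iterations (default 500).
#' @param seed root integer seed.
#' @param base_year,pop_year,level as in [run_scenarios()].
#' @param keep_iterations retain the per-iteration totals matrix.
#' @return object of class `u5_mc_summary`: `$summary` (per reduction: mean,
#'   sd, lower, upper of total additional deaths, plus the point estimate),
#'   `$n_iter`, `$seed`, optionally `$iterations`.
#' @export
run_mc <- function(fit, panel, reductions = c(0.05, 0.10, 0.15),
                   n_iter = 500, seed = 1, base_year = 2019,
                   pop_year = 2020, level = 0.95,
                   keep_iterations = FALSE) {
  stopifnot(inherits(fit, "u5_fit"))
  if (n_iter < 2) u5_error("n_iter must be >= 2", "u5_argument_error")
  if (any(fit$countries$se_beta < 0))
    u5_error("negative slope standard error", "u5_domain_error")
  reductions <- sort(unique(reductions[reductions > 0]))

  point <- run_scenarios(fit, panel, reductions,
                         base_year = base_year, pop_year = pop_year,
                         level = level)
  base <- point$by_country[point$by_country$r == 0, , drop = FALSE]
  ids <- base$country_id
  d0 <- base$deaths
  idx <- match(ids, fit$countries$country_id)
  beta <- fit$countries$beta[idx]
  se <- fit$countries$se_beta[idx]

  # per-country slope draws (n_iter x J), order-invariant substreams
  draws <- vapply(seq_along(ids), function(j) {
    set.seed(country_stream_seed(seed, ids[j]))
    stats::rnorm(n_iter, beta[j], se[j])
  }, numeric(n_iter))
  if (n_iter == 1) draws <- matrix(draws, nrow = 1)

  totals <- vapply(reductions, function(r) {
    # deaths_j(iter) = d0_j * (1-r)^beta*_j; sum over countries per iteration
    colSums(t((1 - r)^draws) * d0)
  }, numeric(n_iter))
  colnames(totals) <- sprintf("r=%g", reductions)
  base_total <- sum(d0)
  additional <- totals - base_total

  summary <- do.call(rbind, lapply(seq_along(reductions), function(k) {
    s <- summarize_iterations(additional[, k], level = level)
    data.frame(r = reductions[k], mean = s[["mean"]], sd = s[["sd"]],
               lower = s[["lower"]], upper = s[["upper"]],
               point = point$totals$additional[point$totals$r ==
                                                 reductions[k]])
  }))

  out <- list(summary = summary, n_iter = n_iter, seed = seed,
              level = level, base_total = base_total,
              base_year = base_year, pop_year = pop_year)
  if (keep_iterations) out$iterations <- additional
  structure(out, class = "u5_mc_summary")
}

#' Summarise Monte Carlo iteration totals
#'
#' Sample mean, sample SD (n-1 denominator) and an empirical percentile
#' interval (linear interpolation, quantile type 7).
#'
#' @param totals numeric vector of per-iteration totals (length >= 2).
#' @param level interval coverage (default 0.95).
#' @return named numeric: mean, sd, lower, upper.
#' @export
summarize_iterations <- function(totals, level = 0.95) {
  if (length(totals) < 2)
    u5_error("need at least 2 iteration totals", "u5_argument_error")
  q <- stats::quantile(totals, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  c(mean = mean(totals), sd = stats::sd(totals), lower = q[1], upper = q[2])
}

#' @export
print.u5_mc_summary <- function(x, ...) {
  cat(sprintf("<MC summary> %d iterations, seed %d\n", x$n_iter, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a Monte Carlo summary to JSON
#'
#' @param mc a `u5_mc_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mc_json <- function(mc, path) {
  stopifnot(inherits(mc, "u5_mc_summary"))
  obj <- list(schema = "u5shock-mc/1", n_iter = mc$n_iter, seed = mc$seed,
              level = mc$level, base_total = mc$base_total,
              summary = mc$summary)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
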