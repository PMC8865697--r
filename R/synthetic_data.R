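# Synthetic country-panel generator with known ground truth.  Emulates a
# WDI-style 129-country, 1990-2020 LMIC panel: log-log GDP-U5MR structure
# with country-varying elasticities, covariate processes with mild log-GDP
# dependence, realistic per-variable/per-period missingness, income-group
# labels and classification GNI values, and under-5 populations spanning
# small states to India-scale countries.

#' Generator configuration
#'
#' Defaults describe the emulated world: 129 countries over 1990-2020,
#' country elasticities beta_j ~ Normal(mu_beta = -0.2845, tau_beta = 0.05)
#' (the mean calibrated to published scenario increments of ~1.47% per 5%
#' GDP reduction), intercepts alpha_j ~ Normal(6.6, 0.35), residual SD
#' sigma = 0.1 on the log scale, lognormal GDP growth (mean 2%/yr, SD 4%),
#' under-5 population log-uniform on [1e5, 2e7], and WDI-like per-variable
#' missingness bands (e.g. physicians 17% missing around 2010, unreported
#' after 2018).
#'
#' @param n_countries number of countries.
#' @param years inclusive year range.
#' @param mu_beta,tau_beta mean and SD of country elasticities.
#' @param mu_alpha,tau_alpha mean and SD of country intercepts (log scale).
#' @param sigma residual SD of the log-U5MR equation.
#' @param beta_z named effects of the socio-economic covariates
#'   (electric power kWh pc, women in parliament %, total fertility).
#' @param beta_h named effects of the health-service covariates
#'   (physicians per 1,000, DPT coverage %).
#' @param gdp_growth_mean,gdp_growth_sd lognormal annual GDP growth.
#' @param pop_range under-5 population range (log-uniform).
#' @param income_props proportions of low / lower-middle / upper-middle
#'   countries.
#' @param lmic_share share of countries with classification GNI below the
#'   12,375 US$ ceiling (default 1: an all-LMIC panel).
#' @param missingness data.frame (variable, year_min, year_max, rate) of
#'   masking rates; `NULL` disables masking; defaults WDI-like.
#' @param missing_mechanism `"mcar"` (default) or `"mar"` — under MAR the
#'   masking probability is tilted towards low-GDP country-years.
#' @param seed default seed used by [generate_panel()].
#' @return list of class `u5_generator_config`.
#' @export
generator_config <- function(n_countries = 129, years = c(1990, 2020),
                             mu_beta = -0.2845, tau_beta = 0.05,
                             mu_alpha = 6.6, tau_alpha = 0.35,
                             sigma = 0.1,
                             beta_z = c(electric_power_kwh_pc = -5e-5,
                                        women_parliament_pct = -0.002,
                                        total_fertility = 0.06),
                             beta_h = c(physicians_per_1000 = -0.04,
                                        dpt_coverage_pct = -0.004),
                             gdp_growth_mean = 0.02, gdp_growth_sd = 0.04,
                             pop_range = c(1e5, 2e7),
                             income_props = c(low = 0.22,
                                              `lower-middle` = 0.39,
                                              `upper-middle` = 0.39),
                             lmic_share = 1,
                             missingness = default_missingness(),
                             missing_mechanism = c("mcar", "mar"),
                             seed = 20200901) {
  stopifnot(n_countries >= 1, years[1] <= years[2], sigma >= 0,
            tau_beta >= 0, lmic_share >= 0, lmic_share <= 1,
            all(income_props >= 0))
  missing_mechanism <- match.arg(missing_mechanism)
  structure(list(n_countries = n_countries, years = years,
                 mu_beta = mu_beta, tau_beta = tau_beta,
                 mu_alpha = mu_alpha, tau_alpha = tau_alpha, sigma = sigma,
                 beta_z = beta_z, beta_h = beta_h,
                 gdp_growth_mean = gdp_growth_mean,
                 gdp_growth_sd = gdp_growth_sd,
                 pop_range = pop_range,
                 income_props = income_props / sum(income_props),
                 lmic_share = lmic_share, missingness = missingness,
                 missing_mechanism = missing_mechanism, seed = seed),
            class = "u5_generator_config")
}

#' Default WDI-like missingness bands
#'
#' Per-variable masking rates by year band, loosely matching the shares of
#' missing observations reported for WDI covariates in an all-LMIC sample
#' (e.g. physicians ~17% missing around 2010, ~53% around 2015, unreported
#' 2019 on; electric power unreported after 2014; GDP missingness growing
#' to ~11% by 2019; U5MR and fertility complete).
#'
#' @return data.frame with columns variable, year_min, year_max, rate.
#' @export
default_missingness <- function() {
  bands <- rbind(
    c("gdp_pc",                1990, 2009, 0.020),
    c("gdp_pc",                2010, 2014, 0.023),
    c("gdp_pc",                2015, 2018, 0.047),
    c("gdp_pc",                2019, 2020, 0.109),
    c("physicians_per_1000",   1990, 2009, 0.100),
    c("physicians_per_1000",   2010, 2014, 0.1705),
    c("physicians_per_1000",   2015, 2018, 0.535),
    c("physicians_per_1000",   2019, 2020, 1.000),
    c("electric_power_kwh_pc", 1990, 2009, 0.250),
    c("electric_power_kwh_pc", 2010, 2014, 0.326),
    c("electric_power_kwh_pc", 2015, 2020, 1.000),
    c("women_parliament_pct",  1990, 2009, 0.050),
    c("women_parliament_pct",  2010, 2014, 0.039),
    c("women_parliament_pct",  2015, 2018, 0.023),
    c("women_parliament_pct",  2019, 2020, 0.008),
    c("dpt_coverage_pct",      1990, 2018, 0.008),
    c("dpt_coverage_pct",      2019, 2020, 1.000))
  data.frame(variable = bands[, 1],
             year_min = as.integer(bands[, 2]),
             year_max = as.integer(bands[, 3]),
             rate = as.numeric(bands[, 4]),
             stringsAsFactors = FALSE)
}

synthetic_regions <- function() {
  c("Sub-Saharan Africa", "South Asia", "East Asia & Pacific",
    "Latin America & Caribbean", "Middle East & North Africa",
    "Europe & Central Asia")
}

# three-letter synthetic country codes: SAA, SAB, ...
synthetic_ids <- function(n) {
  stopifnot(n <= 26 * 26)
  paste0("S", rep(LETTERS, each = 26)[seq_len(n)],
         rep(LETTERS, times = 26)[seq_len(n)])
}

#' Generate a synthetic panel with known ground truth
#'
#' Simulates per-country GDP paths (lognormal growth), covariate processes
#' (trends plus noise, bounded for percentage variables, with mild log-GDP
#' dependence so the covariate model is distinguishable from the GDP-only
#' model), residuals e ~ Normal(0, sigma^2), and computes
#' `u5mr = exp(alpha_j + beta_j log gdp + beta_z' Z + beta_h' H + e)`.
#' Configured missingness is then masked onto the observed panel; the
#' complete pre-missingness panel is retained in the ground truth.
#'
#' @param config a [generator_config()].
#' @param seed integer seed (default from config); identical seeds give
#'   identical panels.
#' @return list with `panel` (a [panel()], post-masking) and `truth`
#'   (class `u5_ground_truth`: per-country `alpha`, `beta`, the covariate
#'   effects, `sigma`, and `complete` — the unmasked records).
#' @export
generate_panel <- function(config = generator_config(),
                           seed = config$seed) {
  stopifnot(inherits(config, "u5_generator_config"))
  set.seed(as.integer(seed))
  n <- config$n_countries
  years <- seq(config$years[1], config$years[2])
  ty <- length(years)
  ids <- synthetic_ids(n)

  income <- sample(names(config$income_props), n, replace = TRUE,
                   prob = config$income_props)
  region <- sample(synthetic_regions(), n, replace = TRUE,
                   prob = c(0.37, 0.06, 0.14, 0.19, 0.10, 0.14))
  is_lmic <- stats::runif(n) < config$lmic_share
  gni <- ifelse(is_lmic,
                switch_gni(income), stats::runif(n, 12375, 30000))
  income[!is_lmic] <- "high"

  alpha <- stats::rnorm(n, config$mu_alpha, config$tau_alpha)
  beta <- stats::rnorm(n, config$mu_beta, config$tau_beta)
  if (config$tau_beta == 0) beta <- rep(config$mu_beta, n)
  pop <- exp(stats::runif(n, log(config$pop_range[1]),
                          log(config$pop_range[2])))

  gdp0 <- gni * stats::runif(n, 0.7, 1.1)
  growth <- matrix(exp(stats::rnorm(n * ty, config$gdp_growth_mean,
                                    config$gdp_growth_sd)),
                   nrow = n)
  gdp <- gdp0 * t(apply(growth, 1, cumprod)) / growth[, 1]

  records <- do.call(rbind, lapply(seq_len(n), function(j) {
    lg <- log(gdp[j, ])
    t_idx <- years - years[1]
    elec <- pmax(20, exp(6.7 + 0.4 * (lg - 8) + 0.015 * t_idx +
                           stats::rnorm(ty, 0, 0.5)))
    women <- pmin(100, pmax(0, 5 + 0.5 * t_idx + stats::rnorm(ty, 0, 4)))
    fert <- pmin(9, pmax(0.8, 5.0 - 0.25 * (lg - 8) - 0.045 * t_idx +
                           stats::rnorm(ty, 0, 0.3)))
    phys <- pmax(0.01, exp(-0.9 + 0.3 * (lg - 8) + 0.02 * t_idx +
                             stats::rnorm(ty, 0, 0.4)))
    dpt <- pmin(100, pmax(0, 100 * stats::plogis(
      -0.2 + 0.08 * t_idx + 0.1 * (lg - 8) + stats::rnorm(ty, 0, 0.5))))
    eps <- stats::rnorm(ty, 0, config$sigma)
    log_u5mr <- alpha[j] + beta[j] * lg +
      config$beta_z[["electric_power_kwh_pc"]] * elec +
      config$beta_z[["women_parliament_pct"]] * women +
      config$beta_z[["total_fertility"]] * fert +
      config$beta_h[["physicians_per_1000"]] * phys +
      config$beta_h[["dpt_coverage_pct"]] * dpt + eps
    data.frame(country_id = ids[j], year = years, u5mr = exp(log_u5mr),
               gdp_pc = gdp[j, ], electric_power_kwh_pc = elec,
               women_parliament_pct = women, total_fertility = fert,
               physicians_per_1000 = phys, dpt_coverage_pct = dpt,
               under5_pop = pop[j], gni_pc = gni[j], region = region[j],
               income_group = income[j], stringsAsFactors = FALSE)
  }))

  complete <- records
  if (!is.null(config$missingness)) {
    records <- apply_missingness(records, config$missingness,
                                 config$missing_mechanism)
  }

  names(alpha) <- names(beta) <- ids
  truth <- structure(list(alpha = alpha, beta = beta,
                          beta_z = config$beta_z, beta_h = config$beta_h,
                          sigma = config$sigma, complete = complete,
                          seed = seed),
                     class = "u5_ground_truth")
  list(panel = panel(records, year_range = config$years), truth = truth)
}

switch_gni <- function(income) {
  # World Bank FY2020 classification bands (current US$ GNI per capita)
  lo <- c(low = 300, `lower-middle` = 1036, `upper-middle` = 4046)
  hi <- c(low = 1035, `lower-middle` = 4045, `upper-middle` = 12374)
  stats::runif(length(income), lo[income], hi[income])
}

apply_missingness <- function(records, bands, mechanism) {
  for (i in seq_len(nrow(bands))) {
    v <- bands$variable[i]
    in_band <- records$year >= bands$year_min[i] &
      records$year <= bands$year_max[i]
    rate <- bands$rate[i]
    if (rate <= 0 || !any(in_band)) next
    idx <- which(in_band)
    if (mechanism == "mar" && rate < 1) {
      # tilt masking towards poorer country-years, preserving the mean rate
      lg <- log(records$gdp_pc[idx])
      tilt <- -(lg - mean(lg)) / max(stats::sd(lg), 1e-8)
      p <- stats::plogis(stats::qlogis(min(max(rate, 1e-6), 1 - 1e-6)) +
                           tilt)
      p <- p * rate / mean(p)
      mask <- stats::runif(length(idx)) < pmin(p, 1)
    } else {
      mask <- stats::runif(length(idx)) < rate
    }
    records[[v]][idx[mask]] <- NA_real_
  }
  records
}

#' Single-country fixture reproducing a published projection row
#'
#' Builds a one-country panel and an engine-free fit stub whose projection
#' satisfies `deaths(r) = baseline_deaths * (1 - r)^slope` exactly — used to
#' check scenario arithmetic against published country rows.
#'
#' @param baseline_deaths baseline (r = 0) under-5 deaths, > 0.
#' @param slope GDP elasticity of U5MR (finite).
#' @param base_gdp base-year GDP per capita (any positive value; results do
#'   not depend on it).
#' @param under5_pop exposed population (default 1e8).
#' @param base_year,pop_year panel years (defaults 2019 / 2020).
#' @return list with `panel` and `fit`.
#' @export
single_country_fixture <- function(baseline_deaths, slope, base_gdp = 3000,
                                   under5_pop = 1e8, base_year = 2019,
                                   pop_year = 2020) {
  stopifnot(baseline_deaths > 0, is.finite(slope))
  u5mr0 <- baseline_deaths / under5_pop * 1000
  alpha <- log(u5mr0) - slope * log(base_gdp)
  records <- data.frame(
    country_id = "SYN", year = c(base_year, pop_year),
    u5mr = u5mr0, gdp_pc = base_gdp, under5_pop = under5_pop,
    region = "Synthetic", income_group = "lower-middle",
    stringsAsFactors = FALSE)
  fit <- new_model_fit(data.frame(
    country_id = "SYN", alpha = alpha, beta = slope, se_beta = 0,
    s_pred = 0, n_obs = 2L, region = "Synthetic",
    income_group = "lower-middle", stringsAsFactors = FALSE))
  list(panel = panel(records), fit = fit)
}

#' Infer a GDP elasticity from two published scenario death counts
#'
#' Inverts the identity `deaths(r) = deaths(0) * (1 - r)^beta`:
#' `beta = log(deaths_r / deaths_0) / log(1 - r)`.
#'
#' @param deaths_0 baseline deaths.
#' @param deaths_r deaths under reduction `r`.
#' @param r the reduction fraction.
#' @return the implied elasticity.
#' @export
infer_elasticity <- function(deaths_0, deaths_r, r) {
  stopifnot(deaths_0 > 0, deaths_r > 0, r > 0, r < 1)
  log(deaths_r / deaths_0) / log(1 - r)
}
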