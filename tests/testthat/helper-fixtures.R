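# Shared fixtures, built in code.

# Small long-format records data.frame: `n` countries x `years`,
# deterministic exact log-log lines (no noise) unless sigma > 0.
toy_records <- function(n = 3, years = 1990:2020, alphas = NULL,
                        betas = NULL, gdp0 = NULL, sigma = 0, seed = 1,
                        gni = NULL, income = NULL, region = NULL,
                        pop = NULL) {
  set.seed(seed)
  if (is.null(alphas)) alphas <- seq(6.0, 6.8, length.out = n)
  if (is.null(betas)) betas <- seq(-0.5, -0.1, length.out = n)
  if (is.null(gdp0)) gdp0 <- seq(800, 4000, length.out = n)
  if (is.null(gni)) gni <- gdp0
  if (is.null(income)) income <- rep("lower-middle", n)
  if (is.null(region)) region <- rep(c("Africa", "Asia"), length.out = n)
  if (is.null(pop)) pop <- rep(1e6, n)
  ids <- sprintf("A%02d", seq_len(n))
  do.call(rbind, lapply(seq_len(n), function(j) {
    gdp <- gdp0[j] * 1.02^(years - years[1])
    ny <- length(years)
    u5mr <- exp(alphas[j] + betas[j] * log(gdp) + rnorm(ny, 0, sigma))
    t_idx <- years - years[1]
    data.frame(country_id = ids[j], year = years, u5mr = u5mr,
               gdp_pc = gdp,
               electric_power_kwh_pc = exp(6.7 + 0.4 * (log(gdp) - 8) +
                                             rnorm(ny, 0, 0.3)),
               women_parliament_pct = pmin(100, pmax(
                 0, 10 + 0.3 * t_idx + rnorm(ny, 0, 3))),
               total_fertility = pmax(1, 5 - 0.3 * (log(gdp) - 8) +
                                        rnorm(ny, 0, 0.2)),
               physicians_per_1000 = exp(-0.9 + 0.3 * (log(gdp) - 8) +
                                           rnorm(ny, 0, 0.2)),
               dpt_coverage_pct = pmin(100, pmax(
                 0, 70 + 0.3 * t_idx + rnorm(ny, 0, 5))),
               under5_pop = pop[j], gni_pc = gni[j],
               region = region[j], income_group = income[j],
               stringsAsFactors = FALSE)
  }))
}

toy_panel <- function(...) u5shock::panel(toy_records(...))

# write records to a temp CSV and return the path
write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

ref10 <- function() u5shock::reference_top10()
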