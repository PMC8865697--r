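test_that("aggregation shares and totals are exact", {
  # two regions with additional deaths 49 and 51 -> shares 49% / 51%
  fits <- new_model_fit(data.frame(
    country_id = c("AAA", "BBB"),
    alpha = c(log(49 / 1e8 * 1000), log(51 / 1e8 * 1000)) + 0.3 * log(3000),
    beta = c(-0.3, -0.3), se_beta = 0, s_pred = 0,
    region = c("R1", "R2"), income_group = c("low", "low"),
    stringsAsFactors = FALSE))
  rec <- data.frame(country_id = rep(c("AAA", "BBB"), each = 2),
                    year = rep(c(2019, 2020), 2),
                    u5mr = 1, gdp_pc = 3000, under5_pop = 1e8,
                    region = rep(c("R1", "R2"), each = 2),
                    income_group = "low")
  res <- run_scenarios(fits, panel(rec), reductions = 0.10)
  agg <- aggregate_scenarios(res, "region")$table
  s <- agg[agg$r == 0.10, ]
  # same slope => additional deaths proportional to baseline (49 vs 51)
  expect_equal(s$share_pct, c(49, 51), tolerance = 1e-9)
  expect_equal(sum(s$additional), res$totals$additional[
    res$totals$r == 0.10], tolerance = 1e-12)

  # single-group aggregation -> 100%
  g <- aggregate_scenarios(res, "global")$table
  expect_equal(g$share_pct[g$r == 0.10], 100)
})

test_that("aggregation is permutation invariant and associative", {
  gen <- generate_panel(generator_config(n_countries = 20,
                                         missingness = NULL), seed = 25)
  fit <- suppressWarnings(fit_elasticity(gen$panel, model_spec(1)))
  res <- run_scenarios(fit, gen$panel)
  agg <- aggregate_scenarios(res, "region")$table
  res2 <- res
  res2$by_country <- res$by_country[sample(nrow(res$by_country)), ]
  agg2 <- aggregate_scenarios(res2, "region")$table
  expect_equal(agg, agg2)
  # region totals sum to the global total
  glob <- aggregate_scenarios(res, "global")$table
  for (r in res$reductions) {
    expect_equal(sum(agg$deaths[agg$r == r]),
                 glob$deaths[glob$r == r], tolerance = 1e-9)
  }
  # missing labels are an aggregation error
  res3 <- res
  res3$by_country$region[1:3] <- NA
  expect_error(aggregate_scenarios(res3, "region"),
               class = "u5_aggregation_error")
})

test_that("percent_increase applies one-decimal half-up rounding", {
  expect_equal(percent_increase(0, 123), 0)
  expect_equal(percent_increase(15, 1000), 1.5)
  expect_equal(percent_increase(1.25, 100), 1.3)  # half-up, not banker's
  expect_error(percent_increase(10, 0), class = "u5_domain_error")
})

test_that("round_half_up rounds 0.5 away from zero", {
  expect_equal(round_half_up(43062.7), 43063)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(1.5), 2)   # base round() would give 2 too,
  expect_equal(round_half_up(2.5), 3)   # but round(2.5) == 2
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(1.45, 1), 1.5)
})

test_that("top_countries sorts descending with country_id tie-break", {
  fit <- new_model_fit(data.frame(
    country_id = c("CCC", "AAA", "BBB"),
    alpha = log(c(10, 20, 20) / 1e6 * 1000) + 0.3 * log(1000),
    beta = -0.3, se_beta = 0, stringsAsFactors = FALSE))
  rec <- data.frame(country_id = rep(c("AAA", "BBB", "CCC"), each = 2),
                    year = rep(c(2019, 2020), 3), u5mr = 1,
                    gdp_pc = 1000, under5_pop = 1e6)
  res <- run_scenarios(fit, panel(rec), reductions = 0.10)
  top <- top_countries(res, n = 2)
  expect_equal(top$country_id, c("AAA", "BBB"))  # tie broken by id
})

test_that("render_tables writes rounded tables that parse back", {
  gen <- generate_panel(generator_config(n_countries = 8,
                                         missingness = NULL), seed = 26)
  fit <- suppressMessages(suppressWarnings(
    fit_elasticity(gen$panel, model_spec(2))))
  res <- run_scenarios(fit, gen$panel)
  mc <- run_mc(fit, gen$panel, n_iter = 50, seed = 2)
  out <- tempfile()
  paths <- render_tables(res, mc, out, top_n = 5)
  tab <- read.csv(file.path(out, "scenario_table.csv"))
  expect_equal(nrow(tab), 5)
  expect_true(all(c("deaths", "additional_15", "lower_15", "upper_15")
                  %in% names(tab)))
  # rendered values match unrounded values to the printed precision
  d15 <- res$by_country[res$by_country$r == 0.15, ]
  i <- match(tab$country, d15$country_id)
  expect_true(all(abs(tab$additional_15 - d15$additional[i]) <= 0.5))
  expect_true(all(tab$additional_15 == round_half_up(d15$additional[i])))
  mcs <- read.csv(file.path(out, "mc_summary.csv"))
  expect_equal(nrow(mcs), 3)

  # empty result -> header-only country table, no error
  empty <- res
  empty$by_country <- res$by_country[0, ]
  empty$totals <- res$totals[0, ]
  out2 <- tempfile()
  render_tables(empty, NULL, out2)
  tab2 <- read.csv(file.path(out2, "scenario_table.csv"))
  expect_equal(nrow(tab2), 0)
})

test_that("the CLI drives the pipeline end to end", {
  dir <- tempfile(); dir.create(dir)
  panel_csv <- file.path(dir, "panel.csv")
  imputed_csv <- file.path(dir, "imputed.csv")
  fit_json <- file.path(dir, "fit.json")
  sc_csv <- file.path(dir, "scenarios.csv")
  mc_json <- file.path(dir, "mc.json")

  u5shock_main(c("simulate", "--n-countries", "10", "--seed", "5",
                 "--out", panel_csv,
                 "--truth", file.path(dir, "truth.json")))
  expect_true(file.exists(panel_csv))
  u5shock_main(c("impute", "--panel", panel_csv, "--out", imputed_csv,
                 "--report", file.path(dir, "imp.json")))
  expect_false(anyNA(load_panel(imputed_csv)$records$gdp_pc))
  suppressWarnings(suppressMessages(
    u5shock_main(c("fit", "--panel", imputed_csv, "--model", "2",
                   "--out", fit_json))))
  u5shock_main(c("project", "--fit", fit_json, "--panel", imputed_csv,
                 "--out", sc_csv))
  u5shock_main(c("mc", "--fit", fit_json, "--panel", imputed_csv,
                 "--iters", "25", "--seed", "3", "--out", mc_json))
  u5shock_main(c("report", "--scenarios", sc_csv,
                 "--out-dir", file.path(dir, "tables")))
  expect_true(file.exists(file.path(dir, "tables", "scenario_table.csv")))
  expect_true(file.exists(mc_json))
  fitj <- jsonlite::read_json(fit_json, simplifyVector = TRUE)
  expect_equal(fitj$schema, "u5shock-fit/1")

  expect_error(u5shock_main(c("nonsense")), class = "u5_cli_error")
  expect_error(u5shock_main(c("fit", "--panel")), class = "u5_cli_error")
})
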