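test_that("design matrices honour the model specification", {
  p <- toy_panel(n = 6, region = rep(c("R1", "R2", "R3"), 2),
                 income = rep(c("low", "lower-middle", "upper-middle"), 2))
  # model 1: intercept + log-GDP only
  d1 <- build_design(p, model_spec(1))
  expect_identical(colnames(d1$X), c("(Intercept)", "log_gdp"))
  # model 2 on 3 regions x 3 income groups: 2 + 2 dummy columns,
  # first-sorted level as reference
  d2 <- build_design(p, model_spec(2))
  expect_equal(sum(grepl("^region", colnames(d2$X))), 2)
  expect_equal(sum(grepl("^income_group", colnames(d2$X))), 2)
  expect_equal(d2$ref_levels$region, "R1")
  expect_equal(d2$ref_levels$income_group, "low")

  expect_error(model_spec(1, covariates = "total_fertility"),
               class = "u5_spec_error")
})

test_that("non-positive values and short countries are handled", {
  rec <- toy_records(n = 3)
  rec$gdp_pc[rec$country_id == "A02" & rec$year == 2000] <- NA
  rec2 <- rec
  rec2$gdp_pc[4] <- NA  # can't set 0 through panel(); test via records hack
  p <- panel(rec)
  p$records$gdp_pc[4] <- 0
  expect_error(build_design(p, model_spec(1)), class = "u5_transform_error")

  # a country with < 5 usable rows is excluded with a warning
  rec3 <- toy_records(n = 3)
  drop <- rec3$country_id == "A03" & rec3$year <= 2017
  rec3$u5mr[drop] <- NA
  expect_warning(d <- build_design(panel(rec3), model_spec(1)), "A03")
  expect_false("A03" %in% levels(d$data$country))
})

test_that("noise-free panels are recovered exactly", {
  alphas <- c(6.1, 6.5, 6.9)
  betas <- c(-0.5, -0.3, -0.1)
  p <- toy_panel(n = 3, alphas = alphas, betas = betas, sigma = 0)
  fit <- fit_elasticity(p, model_spec(1))
  expect_equal(fit$countries$beta, betas, tolerance = 1e-6)
  expect_equal(fit$countries$se_beta, rep(0, 3))
  expect_equal(fit$varcomp$sigma2, 0)
  # alpha is the effective intercept: exp(alpha + beta log g) = truth
  g <- 1234.5
  for (j in 1:3) {
    expect_equal(project_u5mr(fit, fit$countries$country_id[j], g, 0),
                 exp(alphas[j] + betas[j] * log(g)), tolerance = 1e-6)
  }
  # degenerate noise => se = 0 and exact beta via country_slope
  cs <- country_slope(fit, "A02")
  expect_equal(cs$beta, -0.3, tolerance = 1e-6)
  expect_equal(cs$se, 0)
})

test_that("a shared-slope noisy panel is recovered within 2 se", {
  p <- toy_panel(n = 12, betas = rep(-0.2845, 12),
                 alphas = seq(5.8, 7, length.out = 12),
                 gdp0 = seq(700, 6000, length.out = 12),
                 sigma = 0.08, seed = 21)
  fit <- fit_elasticity(p, model_spec(1))
  expect_true(all(abs(fit$countries$beta + 0.2845) <=
                    2 * fit$countries$se_beta))
  expect_true(all(fit$countries$se_beta > 0))
  expect_gt(fit$varcomp$sigma2, 0)
  expect_gte(fit$varcomp$tau2_beta, 0)
})

test_that("rescaling GDP shifts intercepts but not slopes", {
  # alphas and betas deliberately decorrelated so the intercept-slope
  # correlation stays off the boundary (the correlated random-effects
  # structure is the one closed under a log-GDP translation)
  rec <- toy_records(n = 8, sigma = 0.05, seed = 5,
                     alphas = c(6.2, 6.8, 6.0, 6.5, 6.9, 6.1, 6.4, 6.6),
                     betas = c(-0.5, -0.2, -0.35, -0.1, -0.45, -0.15,
                               -0.3, -0.25))
  f1 <- fit_elasticity(panel(rec), model_spec(1))
  rec2 <- rec
  rec2$gdp_pc <- rec2$gdp_pc * 100
  f2 <- fit_elasticity(panel(rec2), model_spec(1))
  expect_equal(f2$countries$beta, f1$countries$beta, tolerance = 1e-4)
  # effective intercepts shift by -beta * ln(c)
  expect_equal(f2$countries$alpha,
               f1$countries$alpha - f1$countries$beta * log(100),
               tolerance = 1e-3)
})

test_that("fitting is invariant to row and country permutation", {
  rec <- toy_records(n = 6, sigma = 0.05, seed = 6)
  f1 <- fit_elasticity(panel(rec), model_spec(1))
  set.seed(99)
  f2 <- fit_elasticity(panel(rec[sample(nrow(rec)), ]), model_spec(1))
  expect_equal(f1$countries$beta, f2$countries$beta, tolerance = 1e-6)
  expect_equal(f1$countries$se_beta, f2$countries$se_beta,
               tolerance = 1e-6)
})

test_that("BLUP slopes shrink towards the pooled slope", {
  # Exact betweenness (ols <= blup <= pooled) holds only for a slope-only
  # random-effects model; with a joint intercept-slope BLUP the slope
  # borrows strength from the intercept deviation.  The substance of
  # shrinkage is tested instead: BLUPs are strictly closer to the pooled
  # slope than the per-country OLS slopes, and deviate in the same
  # direction.
  zero_z <- c(electric_power_kwh_pc = 0, women_parliament_pct = 0,
              total_fertility = 0)
  zero_h <- c(physicians_per_1000 = 0, dpt_coverage_pct = 0)
  gen <- generate_panel(
    generator_config(n_countries = 15, sigma = 0.05, tau_beta = 0.15,
                     beta_z = zero_z, beta_h = zero_h,
                     missingness = NULL), seed = 31)
  p <- gen$panel
  fit <- suppressWarnings(fit_elasticity(p, model_spec(1)))
  pooled <- fit$fixef[["log_gdp"]]
  d <- p$records
  ols <- vapply(fit$countries$country_id, function(id) {
    sub <- d[d$country_id == id, ]
    coef(lm(log(u5mr) ~ log(gdp_pc), data = sub))[2]
  }, numeric(1))
  blup <- fit$countries$beta
  expect_lt(mean(abs(blup - pooled)), mean(abs(ols - pooled)))
  expect_gt(cor(blup - pooled, ols - pooled), 0.5)
})

test_that("model 2 with empty covariates reproduces the model 1 design", {
  p <- toy_panel(n = 4, sigma = 0.05)
  s2 <- model_spec(2, covariates = character(0), group_effects = FALSE)
  d1 <- build_design(p, model_spec(1))
  d2 <- build_design(p, s2)
  expect_identical(colnames(d1$X), colnames(d2$X))
  f1 <- fit_elasticity(p, model_spec(1))
  f2 <- fit_elasticity(p, s2)
  expect_equal(f1$countries$beta, f2$countries$beta, tolerance = 1e-8)
})

test_that("unknown country lookups fail cleanly", {
  fit <- single_country_fixture(1000, -0.3)$fit
  expect_error(country_slope(fit, "ZZZ"), class = "u5_lookup_error")
  expect_error(project_u5mr(fit, "ZZZ", 1000, 0.05),
               class = "u5_lookup_error")
})

test_that("fit JSON round-trips the projection-relevant parameters", {
  p <- toy_panel(n = 4, sigma = 0.05, seed = 8)
  fit <- fit_elasticity(p, model_spec(1))
  path <- tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- read_fit_json(path)
  expect_equal(back$countries$beta, fit$countries$beta)
  expect_equal(back$countries$alpha, fit$countries$alpha)
  expect_equal(back$countries$se_beta, fit$countries$se_beta)
  expect_equal(back$varcomp$sigma2, fit$varcomp$sigma2)
  r1 <- run_scenarios(fit, p)
  r2 <- run_scenarios(back, p)
  expect_equal(r2$by_country$deaths, r1$by_country$deaths)
})
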