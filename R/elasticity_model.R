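# Country-specific Preston-curve elasticities: multilevel mixed-effects
# log-log regression of the under-5 mortality rate on GDP per capita, with a
# random intercept and random log-GDP slope per country.
#
#   Model 1:  log u5mr_{j,t} = a_j + b_{1,j} log gdp_{j,t} + e_{j,t}
#   Model 2:  ... + b2' Z_{j,t} + b3' H_{j,t} + region & income dummies
#
# Variance components are estimated by REML (lme4); the per-country slope is
# the fixed mean slope plus the country's BLUP deviation, with a standard
# error combining the fixed-slope sampling variance and the conditional
# (posterior) variance of the BLUP.

#' Model specification for the elasticity regression
#'
#' @param model_id 1 (GDP only) or 2 (adds socio-economic covariates Z,
#'   health-service covariates H, and region / income-group fixed effects).
#' @param covariates character vector of covariate columns; defaults to the
#'   canonical five for model 2 and none for model 1.  Supplying
#'   `character(0)` for model 2 reproduces the model 1 design.
#' @param group_effects include region and income-group dummies (model 2
#'   default TRUE).
#' @param min_obs minimum usable rows for a country to be fitted (default 5).
#' @return list of class `u5_model_spec`.
#' @export
model_spec <- function(model_id = 1,
                       covariates = if (model_id == 2)
                         covariate_variables() else character(0),
                       group_effects = (model_id == 2),
                       min_obs = 5) {
  stopifnot(model_id %in% c(1, 2))
  if (model_id == 1 && (length(covariates) || group_effects))
    u5_error("model 1 admits no covariates or group effects",
             "u5_spec_error")
  structure(list(model_id = model_id, covariates = covariates,
                 group_effects = group_effects, min_obs = min_obs),
            class = "u5_model_spec")
}

#' Build design matrices for the elasticity model
#'
#' Applies natural-log transforms to `u5mr` and `gdp_pc`, dummy-codes
#' `region` and `income_group` (sorted first level as reference), drops rows
#' with any missing required variable (counted), and excludes countries with
#' fewer than `spec$min_obs` usable rows (warned).
#'
#' @param panel a [panel()] object (post-imputation).
#' @param spec a [model_spec()].
#' @return list: `data` (model frame with `log_u5mr`, `log_gdp`, factors),
#'   `formula` (lme4 formula), `X` (fixed-effect matrix), `y`,
#'   `ref_levels`, `dropped_rows`, `dropped_countries`.
#' @export
build_design <- function(panel, spec = model_spec(1)) {
  stopifnot(inherits(panel, "u5_panel"), inherits(spec, "u5_model_spec"))
  d <- panel$records
  required <- c("u5mr", "gdp_pc", spec$covariates)
  if (spec$group_effects) required <- c(required, "region", "income_group")

  bad <- !is.na(d$u5mr) & d$u5mr <= 0
  bad <- bad | (!is.na(d$gdp_pc) & d$gdp_pc <= 0)
  if (any(bad))
    u5_error(sprintf("non-positive u5mr/gdp_pc (log undefined) at %s",
                     paste(d$country_id[bad], d$year[bad], sep = ":",
                           collapse = ", ")),
             "u5_transform_error")

  complete <- stats::complete.cases(d[required])
  dropped_rows <- sum(!complete)
  d <- d[complete, , drop = FALSE]

  n_by_country <- table(d$country_id)
  small <- names(n_by_country)[n_by_country < spec$min_obs]
  if (length(small)) {
    warning(sprintf("excluding %d country(ies) with < %d usable rows: %s",
                    length(small), spec$min_obs,
                    paste(small, collapse = ", ")))
    d <- d[!d$country_id %in% small, , drop = FALSE]
  }
  if (nrow(d) == 0) u5_error("no usable rows", "u5_design_error")

  d$log_u5mr <- log(d$u5mr)
  d$log_gdp <- log(d$gdp_pc)
  d$country <- factor(d$country_id)
  ref_levels <- list()
  fixed_terms <- c("log_gdp", spec$covariates)
  if (spec$group_effects) {
    for (g in c("region", "income_group")) {
      lev <- sort(unique(d[[g]]))
      d[[g]] <- factor(d[[g]], levels = lev)
      ref_levels[[g]] <- lev[1]
      if (length(lev) > 1) fixed_terms <- c(fixed_terms, g)
    }
  }
  fixed_rhs <- paste(fixed_terms, collapse = " + ")
  formula <- stats::as.formula(
    paste("log_u5mr ~", fixed_rhs, "+ (1 + log_gdp | country)"))
  X <- stats::model.matrix(
    stats::as.formula(paste("~", fixed_rhs)), data = d)
  list(data = d, formula = formula, X = X, y = d$log_u5mr,
       ref_levels = ref_levels, dropped_rows = dropped_rows,
       dropped_countries = small)
}

#' Fit the mixed-effects elasticity model
#'
#' Fits the model by REML.  The per-country elasticity is
#' `beta_j = fixed mean slope + BLUP slope deviation`, with
#' `se(beta_j) = sqrt(var(fixed slope) + conditional var(BLUP))`.  If the
#' correlated random-effects fit is singular with |correlation| at the
#' boundary, the model is automatically refitted with independent intercept
#' and slope components.
#'
#' A panel generated with zero residual noise makes REML degenerate
#' (`sigma^2 -> 0`); this case is detected (saturated per-country regression
#' residual variance below 1e-12 of the response variance) and fitted exactly
#' by per-country least squares with `se = 0`.
#'
#' @param panel a [panel()] object (post-imputation).
#' @param spec a [model_spec()].
#' @return object of class `u5_fit`: `$countries` (data.frame with
#'   `country_id`, `alpha` (effective intercept at the country's most recent
#'   usable covariates), `beta`, `se_beta`, `s_pred` (log-scale prediction
#'   SE), `n_obs`, `region`, `income_group`), `$fixef`, `$vcov_fixef`,
#'   `$varcomp` (tau2_alpha, tau2_beta, cov_alpha_beta, sigma2), `$logLik`,
#'   `$ref_levels`, `$model_id`, `$engine` (the lme4 fit, or NULL for the
#'   degenerate path).
#' @export
fit_elasticity <- function(panel, spec = model_spec(1)) {
  des <- build_design(panel, spec)
  d <- des$data
  if (nlevels(d$country) < 2)
    u5_error("need at least 2 countries to fit", "u5_fit_error")

  # Degenerate (noise-free) detection via the saturated per-country-line model
  sat_rhs <- "0 + country + country:log_gdp"
  if (length(spec$covariates))
    sat_rhs <- paste(sat_rhs, "+", paste(spec$covariates, collapse = " + "))
  sat <- stats::lm(stats::as.formula(paste("log_u5mr ~", sat_rhs)), data = d)
  if (mean(stats::residuals(sat)^2) < 1e-12 * max(stats::var(d$log_u5mr),
                                                  1e-8)) {
    return(fit_degenerate(des, sat, spec))
  }

  fit <- lme4::lmer(des$formula, data = d, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore", check.scaleX = "ignore"))
  vc <- lme4::VarCorr(fit)$country
  corr <- attr(vc, "correlation")[1, 2]
  if (is.na(corr) || abs(corr) > 0.999) {
    # boundary correlation: refit with independent components
    f2 <- stats::update.formula(
      des$formula, . ~ . - (1 + log_gdp | country) + (1 + log_gdp || country))
    fit <- lme4::lmer(f2, data = d, REML = TRUE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore", check.scaleX = "ignore"))
  }

  fe <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  re <- lme4::ranef(fit, condVar = TRUE)$country
  pv <- attr(re, "postVar")
  vc_all <- lme4::VarCorr(fit)
  # combine (possibly split, for the "||" refit) country variance components
  tau2_a <- 0; tau2_b <- 0; cov_ab <- 0
  cond_var <- array(0, dim = c(2, 2, nrow(re)))
  if (is.list(pv)) {
    # "||" fit: one 1x1xJ conditional-variance array per independent term
    cond_var[1, 1, ] <- pv[["(Intercept)"]][1, 1, ]
    cond_var[2, 2, ] <- pv[["log_gdp"]][1, 1, ]
  } else {
    cond_var <- pv
  }
  for (nm in names(vc_all)) {
    m <- vc_all[[nm]]
    if ("(Intercept)" %in% rownames(m))
      tau2_a <- tau2_a + m["(Intercept)", "(Intercept)"]
    if ("log_gdp" %in% rownames(m))
      tau2_b <- tau2_b + m["log_gdp", "log_gdp"]
    if (all(c("(Intercept)", "log_gdp") %in% rownames(m)))
      cov_ab <- m["(Intercept)", "log_gdp"]
  }
  sigma2 <- stats::sigma(fit)^2

  ids <- rownames(re)
  slope_fix <- fe[["log_gdp"]]
  var_slope_fix <- V["log_gdp", "log_gdp"]
  beta <- slope_fix + re[["log_gdp"]]
  se_beta <- sqrt(var_slope_fix + cond_var[2, 2, ])

  ctab <- country_table(des, ids, fe, V, re, cond_var, sigma2, beta, se_beta)
  structure(list(countries = ctab, fixef = fe, vcov_fixef = V,
                 varcomp = list(tau2_alpha = tau2_a, tau2_beta = tau2_b,
                                cov_alpha_beta = cov_ab, sigma2 = sigma2),
                 logLik = as.numeric(stats::logLik(fit)),
                 ref_levels = des$ref_levels, model_id = spec$model_id,
                 dropped_rows = des$dropped_rows,
                 dropped_countries = des$dropped_countries,
                 engine = fit),
            class = "u5_fit")
}

# Exact per-country least-squares fit for the noise-free case.
fit_degenerate <- function(des, sat, spec) {
  d <- des$data
  ids <- levels(d$country)
  cf <- stats::coef(sat)
  alpha_j <- cf[paste0("country", ids)]
  beta_j <- cf[paste0("country", ids, ":log_gdp")]
  names(alpha_j) <- names(beta_j) <- ids
  cov_cf <- cf[spec$covariates]
  cov_cf[is.na(cov_cf)] <- 0

  ctab <- do.call(rbind, lapply(ids, function(id) {
    rows <- d[d$country == id, , drop = FALSE]
    last <- rows[which.max(rows$year), , drop = FALSE]
    covterm <- if (length(spec$covariates))
      sum(cov_cf * as.numeric(last[1, spec$covariates])) else 0
    data.frame(country_id = id,
               alpha = unname(alpha_j[id] + covterm),
               beta = unname(beta_j[id]), se_beta = 0, s_pred = 0,
               n_obs = nrow(rows),
               region = if (is.factor(last$region))
                 as.character(last$region) else last$region,
               income_group = if (is.factor(last$income_group))
                 as.character(last$income_group) else last$income_group,
               base_row_year = last$year,
               stringsAsFactors = FALSE)
  }))
  rownames(ctab) <- NULL
  fe <- c("(Intercept)" = mean(alpha_j), log_gdp = mean(beta_j))
  structure(list(countries = ctab, fixef = fe,
                 vcov_fixef = matrix(0, 2, 2,
                                     dimnames = list(names(fe), names(fe))),
                 varcomp = list(tau2_alpha = stats::var(alpha_j),
                                tau2_beta = stats::var(beta_j),
                                cov_alpha_beta = stats::cov(alpha_j, beta_j),
                                sigma2 = 0),
                 logLik = Inf, ref_levels = des$ref_levels,
                 model_id = spec$model_id, dropped_rows = des$dropped_rows,
                 dropped_countries = des$dropped_countries, engine = NULL),
            class = "u5_fit")
}

# Per-country table for the mixed-model path: effective intercepts and
# log-scale prediction SEs evaluated at each country's most recent usable row.
country_table <- function(des, ids, fe, V, re, cond_var, sigma2,
                          beta, se_beta) {
  d <- des$data
  X <- des$X
  do.call(rbind, lapply(seq_along(ids), function(j) {
    id <- ids[j]
    rows <- which(d$country == id)
    last <- rows[which.max(d$year[rows])]
    x <- X[last, names(fe)]  # lmer may have dropped rank-deficient columns
    lg <- d$log_gdp[last]
    mu <- sum(x * fe) + re[j, "(Intercept)"] + re[j, "log_gdp"] * lg
    alpha_eff <- mu - beta[j] * lg
    q <- c(1, lg)
    s_pred <- sqrt(drop(t(x) %*% V %*% x) +
                     drop(t(q) %*% cond_var[, , j] %*% q) + sigma2)
    data.frame(country_id = id, alpha = alpha_eff, beta = beta[j],
               se_beta = se_beta[j], s_pred = s_pred, n_obs = length(rows),
               region = if (is.factor(d$region))
                 as.character(d$region[last]) else d$region[last],
               income_group = if (is.factor(d$income_group))
                 as.character(d$income_group[last]) else
                   d$income_group[last],
               base_row_year = d$year[last],
               stringsAsFactors = FALSE)
  })) -> ctab
  rownames(ctab) <- NULL
  ctab
}

#' Per-country elasticity and standard error
#'
#' @param fit a [fit_elasticity()] result.
#' @param country_id country code.
#' @return list with `beta` and `se`.
#' @export
country_slope <- function(fit, country_id) {
  stopifnot(inherits(fit, "u5_fit"))
  i <- match(country_id, fit$countries$country_id)
  if (is.na(i))
    u5_error(sprintf("country not in fit: %s", country_id),
             "u5_lookup_error")
  list(beta = fit$countries$beta[i], se = fit$countries$se_beta[i])
}

#' @export
print.u5_fit <- function(x, ...) {
  cat(sprintf("<u5_fit> model %d, %d countries\n", x$model_id,
              nrow(x$countries)))
  cat(sprintf("  mean slope %.4f; tau2_beta %.3g; sigma2 %.3g\n",
              x$fixef[["log_gdp"]], x$varcomp$tau2_beta, x$varcomp$sigma2))
  invisible(x)
}

#' Construct a model-fit object directly from per-country parameters
#'
#' Used for fixtures and for deserialising a fit from JSON; the resulting
#' object supports projection and Monte Carlo but carries no fitting engine.
#'
#' @param countries data.frame with columns `country_id`, `alpha`, `beta`,
#'   `se_beta`; optional `s_pred`, `n_obs`, `region`, `income_group`.
#' @param varcomp,fixef,ref_levels,model_id optional metadata.
#' @return `u5_fit` object.
#' @export
new_model_fit <- function(countries, varcomp = NULL, fixef = NULL,
                          ref_levels = list(), model_id = NA_integer_) {
  stopifnot(all(c("country_id", "alpha", "beta", "se_beta") %in%
                  names(countries)))
  if (is.null(countries$s_pred)) countries$s_pred <- 0
  if (is.null(countries$n_obs)) countries$n_obs <- NA_integer_
  if (is.null(countries$region)) countries$region <- NA_character_
  if (is.null(countries$income_group))
    countries$income_group <- NA_character_
  structure(list(countries = countries, fixef = fixef, vcov_fixef = NULL,
                 varcomp = varcomp, logLik = NA_real_,
                 ref_levels = ref_levels, model_id = model_id,
                 dropped_rows = 0L, dropped_countries = character(0),
                 engine = NULL),
            class = "u5_fit")
}

#' Serialise a model fit to JSON
#'
#' Writes the per-country parameters, fixed effects, variance components and
#' reference levels (schema version 1).  The lme4 engine object is not
#' serialised; a fit read back supports projection and Monte Carlo.
#'
#' @param fit a `u5_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "u5_fit"))
  obj <- list(schema = "u5shock-fit/1", model_id = fit$model_id,
              countries = fit$countries,
              fixef = as.list(fit$fixef), varcomp = fit$varcomp,
              logLik = fit$logLik, ref_levels = fit$ref_levels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a model fit from JSON
#'
#' @param path path written by [write_fit_json()].
#' @return `u5_fit` object (engine-free).
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "u5shock-fit/1"))
    u5_error("unrecognised fit schema", "u5_format_error")
  new_model_fit(as.data.frame(obj$countries),
                varcomp = obj$varcomp, fixef = unlist(obj$fixef),
                ref_levels = obj$ref_levels, model_id = obj$model_id)
}
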