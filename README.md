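# u5shock

Excess under-5 mortality from economic downturn scenarios in low- and
middle-income countries (LMICs).

## What this package does

Economic downturns raise child mortality in LMICs through nutrition,
environment and care-seeking channels. `u5shock` estimates that effect as a
country-specific **Preston-curve elasticity**: a multilevel mixed-effects
log-log regression of the under-5 mortality rate (U5MR, deaths under age 5
per 1,000 live births) on GDP per capita,

```
Model 1:  log U5MR_{j,t} = alpha_j + beta_{1,j} log GDP_{j,t} + e_{j,t}
Model 2:  ... + beta_2' Z_{j,t} + beta_3' H_{j,t}  (+ region & income dummies)
```

with a random intercept and random log-GDP slope per country `j` over years
`t` (1990–2020). `Z` holds socio-economic covariates (electric power
consumption per capita, share of parliamentary seats held by women, total
fertility rate) and `H` health-service covariates (physicians per 1,000
people, DPT immunisation coverage). `beta_{1,j}` — the fixed mean slope
plus the country's BLUP deviation — is the elasticity of U5MR with respect
to GDP per capita.

The fitted elasticities drive counterfactual **scenario projections**: a
fraction `r` (0, 5%, 10%, 15%) of 2019 GDP per capita is removed in 2020, so

```
U5MR_j(r) = U5MR_j(0) * (1 - r)^beta_{1,j}
deaths_j(r) = U5MR_j(r) * under5_pop_j / 1000
```

and *additional lives lost* is `deaths_j(r) - deaths_j(0)`. A **Monte
Carlo** experiment (default 500 iterations) redraws each country's slope
from `Normal(beta_{1,j}, se^2)` to propagate estimation uncertainty into the
death totals.

Because the real inputs (World Bank WDI, UN WPP) are not bundled, the
package ships a **synthetic panel generator** with known ground truth that
emulates a 129-country LMIC panel — including WDI-like missingness — so the
whole pipeline is testable offline, plus **imputation** for the gaps it
creates: a trailing five-year moving average for GDP and iterative
multivariate-normal regression for covariates.

## Worked example

```r
library(u5shock)

gen <- generate_panel(generator_config(n_countries = 129), seed = 2020)
p   <- filter_lmic(gen$panel)          # strict GNI < 12,375 US$ filter
p   <- impute_panel_gdp(p)             # five-year moving average
imp <- impute_covariates_mvn(p)        # chained conditional-mean fills
fit <- fit_elasticity(imp$panel, model_spec(2))
res <- run_scenarios(fit, imp$panel)   # r = 0, 0.05, 0.10, 0.15
mc  <- run_mc(fit, imp$panel, n_iter = 500, seed = 2020)
```

which prints (this exact synthetic world, seed 2020):

```
<imputation report> 2994 cells imputed, 6 iteration(s), converged
<u5_fit> model 2, 129 countries
  mean slope -0.2980; tau2_beta 0.00288; sigma2 0.011
<scenario result> 129 countries, base year 2019
    r   deaths additional
 0.00 21993427        0.0
 0.05 22326264   332837.0
 0.10 22682635   689208.2
 0.15 23065659  1072232.4
<MC summary> 500 iterations, seed 2020
    r      mean       sd     lower     upper     point
 0.05  332804.8  8025.80  315992.1  348730.3  332837.0
 0.10  689271.7 16746.43  654170.2  722483.4  689208.2
 0.15 1072548.9 26264.01 1017464.5 1124605.7 1072232.4
```

Reading: under the no-reduction baseline this synthetic world loses ~22.0M
under-5 lives; a 5% GDP contraction adds ~332,800 deaths (a
`percent_increase()` of 1.5% over baseline), a 15% contraction ~1.07M
(4.9%). The MC interval brackets every point estimate. Aggregation and
rendering:

```r
aggregate_scenarios(res, "region")$table   # totals, shares, % increases
top_countries(res, n = 10)                 # highest additional deaths
render_tables(res, mc, "tables/")          # rounded CSV tables
```

## Data dialect

Long CSV, header required, `NA`/empty = missing (never 0): `country_id`,
`year`, `u5mr`, `gdp_pc` (constant 2010 US$), `electric_power_kwh_pc`,
`women_parliament_pct`, `total_fertility`, `physicians_per_1000`,
`dpt_coverage_pct`, `under5_pop`, `gni_pc` (current US$, classification),
`region`, `income_group` (`low`/`lower-middle`/`upper-middle`). A wide
layout (one row per country × variable, one column per year) is accepted by
`load_panel(path, layout = "wide")`.

## Command line

```sh
inst/cli/u5shock simulate --n-countries 129 --seed 42 --out panel.csv --truth truth.json
inst/cli/u5shock impute   --panel panel.csv --out imputed.csv
inst/cli/u5shock fit      --panel imputed.csv --model 2 --out fit.json
inst/cli/u5shock project  --fit fit.json --panel imputed.csv \
                          --reductions 0.05,0.10,0.15 --out scenarios.csv
inst/cli/u5shock mc       --fit fit.json --panel imputed.csv --iters 500 \
                          --seed 20200901 --out mc.json
inst/cli/u5shock report   --scenarios scenarios.csv --out-dir tables/
```

## Limitations

Deaths are weighted by the under-5 *population*, not live births — the
literal rule of the source methodology; the association model has no causal
identification, no residual autocorrelation, no lag structure, and a strict
one-year horizon. See the methods vignette (`vignettes/u5shock-methods.Rmd`)
for assumptions, numerical choices, and what the synthetic world does and
does not establish.
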