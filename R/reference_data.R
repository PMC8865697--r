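# Bundled reference values: published country-level estimates of under-5
# deaths under the 2020 downturn scenarios for the ten highest-burden
# countries.  Used as fixed inputs for internal-consistency checks (the
# scenario arithmetic and elasticity identities), not as a fitting target.

#' Published top-10 reference estimates
#'
#' Per-country under-5 deaths (point and 95% bounds) at baseline and under
#' 5% / 10% / 15% GDP-per-capita reductions, with the printed additional
#' deaths, for the ten countries with the highest additional under-5 lives
#' lost in 2020.
#'
#' @return data.frame with one row per country; columns `deaths_<s>`,
#'   `additional_<s>`, `lower_<s>`, `upper_<s>` for s in 0, 5, 10, 15.
#' @export
reference_top10 <- function() {
  path <- system.file("extdata", "downturn_top10_reference.csv",
                      package = "u5shock", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
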