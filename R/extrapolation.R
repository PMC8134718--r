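# National extrapolation: scale network-level reduction fractions to the
# national monthly incidence baseline.

#' National incidence baseline
#'
#' @param monthly_new_cases New cancer diagnoses per month nationally
#'   (default 31 833).
#' @param annual_new_cases New solid-tumor diagnoses per year
#'   (default 382 000).
#' @param annual_deaths Cancer deaths per year (default 157 400; with the
#'   default incidence this is the 41% national death rate).
#' @param observed_reduction Optional externally reported national reduction
#'   fraction for the study window (0.233 as reported on the national
#'   social-security platform, 24 Nov 2020); carried as a constant, never
#'   recomputed.
#' @return Object of class `national_baseline`; includes the implied
#'   national death rate `rd`.
#' @export
national_baseline <- function(monthly_new_cases = 31833,
                              annual_new_cases = 382000,
                              annual_deaths = 157400,
                              observed_reduction = 0.233) {
  if (abs(monthly_new_cases * 12 - annual_new_cases) / annual_new_cases > 0.01) {
    stop_validation(
      "monthly_new_cases * 12 must match annual_new_cases within 1%")
  }
  structure(list(monthly_new_cases = monthly_new_cases,
                 annual_new_cases = annual_new_cases,
                 annual_deaths = annual_deaths,
                 rd = annual_deaths / annual_new_cases,
                 observed_reduction = observed_reduction),
            class = "national_baseline")
}

#' National missing-patient counts from a network reduction series
#'
#' Scales per-month reduction *fractions* (not raw counts) to the national
#' monthly baseline: `missing_m = monthly_new_cases * max(f_m, 0)`.
#'
#' @param series A [reduction_series()].
#' @param baseline A [national_baseline()].
#' @return Tibble `month, fraction, missing` with attribute `missing_total`.
#' @export
national_missing <- function(series, baseline = national_baseline()) {
  stopifnot(inherits(series, "reduction_series"),
            inherits(baseline, "national_baseline"))
  out <- tibble::tibble(
    month = series$month, fraction = series$fraction,
    missing = baseline$monthly_new_cases * pmax(series$fraction, 0))
  attr(out, "missing_total") <- sum(out$missing)
  out
}

#' Share of national incidence seen by the network
#'
#' Mean monthly reference-year count divided by the national monthly
#' baseline; a reporting figure, not a model input.
#'
#' @param series A [reduction_series()] whose `ref` column holds the network
#'   reference-year counts.
#' @param baseline A [national_baseline()].
#' @return A fraction.
#' @export
network_share <- function(series, baseline = national_baseline()) {
  stopifnot(inherits(series, "reduction_series"))
  if (nrow(series) == 0) stop_validation("empty reduction series")
  mean(series$ref) / baseline$monthly_new_cases
}

#' National excess-death estimate from a network reduction series
#'
#' Convenience pipeline: round the network reduction fractions to the
#' published precision, scale them to the national monthly baseline, build
#' the delay schedule against the resolution month, and evaluate the
#' excess-death model.
#'
#' @param series A [reduction_series()].
#' @param params A [risk_params()].
#' @param baseline A [national_baseline()].
#' @param resolution_month Month by which delayed patients enter care
#'   (default August).
#' @param extra_months Additional months of delay (default 0).
#' @param fraction_digits Decimals the monthly fractions are rounded to
#'   before scaling (default 3, the precision at which the source reductions
#'   are published; use `Inf` for no rounding).
#' @return An [excess_deaths_series()] estimate.
#' @export
national_excess <- function(series, params = risk_params(),
                            baseline = national_baseline(),
                            resolution_month = 8L, extra_months = 0,
                            fraction_digits = 3) {
  f <- series$fraction
  if (is.finite(fraction_digits)) f <- round(f, fraction_digits)
  sched <- build_schedule(pmax(f, 0), resolution_month,
                          extra_months = extra_months,
                          baseline = baseline$monthly_new_cases,
                          months = series$month)
  excess_deaths_series(sched, params)
}
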