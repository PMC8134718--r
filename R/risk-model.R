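# Closed-form excess-mortality model under delayed diagnosis.
#
# A patient whose diagnosis is delayed by n months has their cumulative
# hazard of cancer death multiplied by HR^n. With baseline death probability
# RD (survival S = 1 - RD), the delayed death probability is
#   RDdel = 1 - exp(log(1 - RD) * HR^n)  =  1 - S^(HR^n),
# and a month with N missing patients contributes N * (RDdel - RD) expected
# excess deaths.

#' Risk parameters: baseline death rate and per-month delay hazard ratio
#'
#' @param rd Baseline probability of death from cancer without delay,
#'   strictly in (0, 1). The national default is 0.41 (157 400 deaths /
#'   382 000 new diagnoses).
#' @param hr Hazard ratio on the cumulative hazard per month of delayed
#'   diagnosis/treatment, > 0 (default 1.06).
#' @param label Tumor type the parameters describe, or `"all"`.
#' @return Object of class `risk_params`.
#' @export
risk_params <- function(rd = 0.41, hr = 1.06, label = "all") {
  if (!is.numeric(rd) || length(rd) != 1 || is.na(rd) || rd <= 0 || rd >= 1) {
    stop_validation("rd must be a single number strictly between 0 and 1")
  }
  if (!is.numeric(hr) || length(hr) != 1 || is.na(hr) || hr <= 0) {
    stop_validation("hr must be a single positive number")
  }
  structure(list(rd = rd, hr = hr, label = label), class = "risk_params")
}

#' @export
print.risk_params <- function(x, ...) {
  cat(sprintf("<risk_params> RD = %g, HR = %g per month of delay (%s)\n",
              x$rd, x$hr, x$label))
  invisible(x)
}

#' Death probability after an n-month diagnostic delay
#'
#' Evaluates `1 - exp(log(1 - RD) * HR^n)`. Equals `RD` when `n = 0` or
#' `HR = 1`; strictly increasing in `n` and `HR` when `HR > 1`, with limit 1
#' as `n` grows.
#'
#' @param params A [risk_params()].
#' @param n Months of delay, nonnegative (real values permitted); vectorized.
#' @return Delayed death probabilities in (0, 1).
#' @export
death_rate_with_delay <- function(params, n) {
  stopifnot(inherits(params, "risk_params"))
  if (any(n < 0)) stop_validation("delay n must be nonnegative")
  rate <- -expm1(log1p(-params$rd) * params$hr^n)
  # no delay or unit hazard leave the baseline rate untouched, exactly
  rate[n == 0 | params$hr == 1] <- params$rd
  rate
}

#' Expected excess deaths among one month's missing patients
#'
#' `N * (RDdel(n) - RD)`: the expected number of additional cancer deaths
#' among `N` patients whose diagnosis was delayed by `n` months. Linear in
#' `N`, nonnegative whenever `HR >= 1`.
#'
#' @param n_missing Missing (delayed) patient count, nonnegative; vectorized.
#' @param params A [risk_params()].
#' @param delay Months of delay for those patients; vectorized with
#'   `n_missing`.
#' @return Expected excess deaths (real-valued).
#' @export
excess_deaths_for_month <- function(n_missing, params, delay) {
  if (any(n_missing < 0)) stop_validation("missing counts must be nonnegative")
  n_missing * (death_rate_with_delay(params, delay) - params$rd)
}

#' Build a delay schedule from monthly shortfalls and a resolution month
#'
#' Assigns each shortfall month `m` a delay `n = (resolution_month - m) +
#' extra_months`: patients missing in month `m` are assumed to enter care in
#' the resolution month (August, month 8, in the base scenario), plus any
#' additional backlog months.
#'
#' @param x A [reduction_series()], or a numeric vector of missing counts
#'   (then `months` must be given).
#' @param resolution_month Integer month index at or after the last schedule
#'   month.
#' @param extra_months Additional months of delay added uniformly
#'   (nonnegative, need not be integer).
#' @param baseline Optional scalar monthly baseline: when supplied with a
#'   reduction series, missing counts are rescaled to
#'   `baseline * max(fraction, 0)` (national extrapolation).
#' @param months Integer month indices when `x` is a bare numeric vector.
#' @return A `delay_schedule` tibble with columns `month, missing, delay`.
#' @export
build_schedule <- function(x, resolution_month, extra_months = 0,
                           baseline = NULL, months = NULL) {
  if (extra_months < 0) stop_schedule("extra_months must be nonnegative")
  if (inherits(x, "reduction_series")) {
    months <- x$month
    missing <- if (is.null(baseline)) x$missing else baseline * pmax(x$fraction, 0)
  } else {
    if (is.null(months)) months <- as.integer(names(x))
    if (is.null(months) || anyNA(months)) {
      stop_schedule("months must be supplied for bare missing counts")
    }
    missing <- as.numeric(x)
    if (!is.null(baseline)) missing <- baseline * pmax(missing, 0)
  }
  if (any(missing < 0)) stop_validation("missing counts must be nonnegative")
  if (resolution_month < max(months)) {
    stop_schedule(sprintf(
      "resolution month %d precedes the last schedule month %d",
      resolution_month, max(months)))
  }
  out <- tibble::tibble(month = as.integer(months), missing = missing,
                        delay = (resolution_month - months) + extra_months)
  structure(out, class = c("delay_schedule", class(out)),
            resolution_month = as.integer(resolution_month),
            extra_months = extra_months)
}

#' Excess-death estimate for a whole delay schedule
#'
#' Applies [excess_deaths_for_month()] to every schedule entry and totals the
#' result.
#'
#' @param schedule A [build_schedule()] result.
#' @param params A [risk_params()].
#' @return Object of class `excess_estimate`: list with `per_month` (tibble
#'   `month, missing, delay, rate_delayed, excess`), `total`, `params`,
#'   `resolution_month`, `extra_months`.
#' @export
excess_deaths_series <- function(schedule, params) {
  stopifnot(inherits(schedule, "delay_schedule"),
            inherits(params, "risk_params"))
  rate <- death_rate_with_delay(params, schedule$delay)
  per_month <- tibble::tibble(
    month = schedule$month, missing = schedule$missing,
    delay = schedule$delay, rate_delayed = rate,
    excess = schedule$missing * (rate - params$rd))
  structure(list(per_month = per_month, total = sum(per_month$excess),
                 params = params,
                 resolution_month = attr(schedule, "resolution_month"),
                 extra_months = attr(schedule, "extra_months")),
            class = "excess_estimate")
}

#' @export
print.excess_estimate <- function(x, ...) {
  cat(sprintf(
    "<excess_estimate> RD = %g, HR = %g, resolution month %d (+%g): total %.1f excess deaths\n",
    x$params$rd, x$params$hr, x$resolution_month, x$extra_months, x$total))
  print(x$per_month)
  invisible(x)
}
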