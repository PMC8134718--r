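# Scenario grids over additional delay and additional reduction, and the
# tumor-specific vs one-size-fits-all comparison.

#' Scenario grid of total excess deaths
#'
#' For each cell `(a, p)` the monthly reduction fractions are shifted by `p`
#' percentage points (`f' = f + p`), scaled to the monthly `baseline` to give
#' missing counts `N_m = baseline * max(f'_m, 0)`, and every month's delay is
#' extended by `a` additional months beyond the resolution month. Months with
#' a net increase (`f' <= 0`) contribute zero excess deaths, consistent with
#' the clamping of missing counts.
#'
#' @param x A [reduction_series()], or a numeric vector of reduction
#'   fractions (then `months` must be given).
#' @param params A [risk_params()].
#' @param baseline Monthly new-diagnosis count the fractions are scaled to
#'   (31 833/month nationally).
#' @param resolution_month Month by which all delayed patients enter care in
#'   the `a = 0` row (default August).
#' @param extra_months Additional-delay rows `a` (default 0-4).
#' @param extra_pct Additional-reduction columns `p`, as fractions
#'   (default 0, 0.05, ..., 0.25).
#' @param months Month indices when `x` is a bare fraction vector.
#' @return A `scenario_grid`: numeric matrix of total excess deaths with rows
#'   named by additional months and columns by additional percentage points;
#'   attributes keep the inputs.
#' @export
scenario_grid <- function(x, params, baseline,
                          resolution_month = 8L,
                          extra_months = 0:4,
                          extra_pct = seq(0, 0.25, by = 0.05),
                          months = NULL) {
  stopifnot(inherits(params, "risk_params"))
  if (inherits(x, "reduction_series")) {
    months <- x$month
    fractions <- x$fraction
  } else {
    if (is.null(months)) months <- as.integer(names(x))
    if (is.null(months) || anyNA(months)) {
      stop_scenario("months must be supplied for bare fractions")
    }
    fractions <- as.numeric(x)
  }
  if (any(extra_months < 0)) stop_scenario("extra_months must be nonnegative")
  grid <- matrix(NA_real_, nrow = length(extra_months),
                 ncol = length(extra_pct),
                 dimnames = list(additional_months = as.character(extra_months),
                                 additional_pct = sprintf("%+g%%", -100 * extra_pct)))
  for (i in seq_along(extra_months)) {
    for (j in seq_along(extra_pct)) {
      f2 <- fractions + extra_pct[j]
      if (any(f2 >= 1)) {
        stop_scenario(sprintf(
          "shifted reduction reaches 100%% in month %d (f + p = %.3f)",
          months[which(f2 >= 1)[1]], max(f2)))
      }
      sched <- build_schedule(pmax(f2, 0), resolution_month,
                              extra_months = extra_months[i],
                              baseline = baseline, months = months)
      grid[i, j] <- excess_deaths_series(sched, params)$total
    }
  }
  structure(grid, class = c("scenario_grid", "matrix"),
            params = params, baseline = baseline, months = months,
            fractions = fractions, resolution_month = resolution_month,
            extra_months = extra_months, extra_pct = extra_pct)
}

#' @export
print.scenario_grid <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "<scenario_grid> RD = %g, HR = %g, baseline %g/month, resolution month %d\n",
    p$rd, p$hr, attr(x, "baseline"), attr(x, "resolution_month")))
  print(round(unclass(x), 1))
  invisible(x)
}

#' Scenario grids for a sweep of hazard ratios
#'
#' @inheritParams scenario_grid
#' @param hr_sweep Hazard ratios, one grid each (default 1.02, 1.06, 1.1).
#' @param rd Baseline death rate shared by all panels.
#' @param ... Passed to [scenario_grid()].
#' @return Named list of `scenario_grid` objects, names `"hr_<value>"`.
#' @export
scenario_grid_sweep <- function(x, baseline, hr_sweep = c(1.02, 1.06, 1.1),
                                rd = 0.41, ...) {
  grids <- lapply(hr_sweep, function(hr) {
    scenario_grid(x, risk_params(rd = rd, hr = hr), baseline, ...)
  })
  names(grids) <- paste0("hr_", hr_sweep)
  grids
}

#' Tumor-specific vs one-size-fits-all excess-death comparison
#'
#' Each tumor's total missing patients (`missing_ref - missing_obs`, clamped
#' at zero) are spread over the window months by `monthly_weights` and the
#' excess is computed twice: with the tumor's own death rate
#' (`annual_deaths / annual_incidence`) and hazard ratio, and with the
#' uniform parameters. Per-tumor monthly profiles are not published, so the
#' overall network monthly missing profile is the default weighting.
#'
#' @param specs Data frame with columns `label, annual_incidence,
#'   annual_deaths, hr, missing_ref, missing_obs` (see [tumor_specs()]).
#' @param monthly_weights Per-month weights summing to 1 (tolerance 1e-9).
#' @param months Month indices matching the weights (default March-July).
#' @param resolution_month Resolution month (default August).
#' @param uniform_params The one-size-fits-all [risk_params()]
#'   (default RD 0.41, HR 1.06).
#' @return A `tumor_comparison`: list with `by_tumor` (tibble `label,
#'   missing, rd, hr, excess_specific, excess_uniform`) and `totals`.
#' @export
tumor_specific_excess <- function(specs, monthly_weights, months = 3:7,
                                  resolution_month = 8L,
                                  uniform_params = risk_params(0.41, 1.06)) {
  specs <- tibble::as_tibble(specs)
  needed <- c("label", "annual_incidence", "annual_deaths", "hr",
              "missing_ref", "missing_obs")
  missing_cols <- setdiff(needed, names(specs))
  if (length(missing_cols) > 0) {
    stop_validation(paste0("tumor specs lack column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  if (abs(sum(monthly_weights) - 1) > 1e-9) {
    stop_validation("monthly weights must sum to 1 (tolerance 1e-9)")
  }
  if (length(monthly_weights) != length(months)) {
    stop_validation("monthly_weights and months must have equal length")
  }
  rd_t <- specs$annual_deaths / specs$annual_incidence
  if (any(rd_t <= 0 | rd_t >= 1)) {
    stop_validation("per-tumor death rate must lie strictly in (0, 1)")
  }
  missing_total <- pmax(specs$missing_ref - specs$missing_obs, 0)
  one_tumor <- function(missing, params) {
    sched <- build_schedule(missing * monthly_weights, resolution_month,
                            months = months)
    excess_deaths_series(sched, params)$total
  }
  spec_ex <- vapply(seq_len(nrow(specs)), function(i) {
    one_tumor(missing_total[i],
              risk_params(rd_t[i], specs$hr[i], specs$label[i]))
  }, numeric(1))
  unif_ex <- vapply(seq_len(nrow(specs)), function(i) {
    one_tumor(missing_total[i], uniform_params)
  }, numeric(1))
  by_tumor <- tibble::tibble(
    label = specs$label, missing = missing_total, rd = rd_t, hr = specs$hr,
    excess_specific = spec_ex, excess_uniform = unif_ex)
  structure(list(by_tumor = by_tumor,
                 totals = c(specific = sum(spec_ex), uniform = sum(unif_ex)),
                 uniform_params = uniform_params,
                 monthly_weights = monthly_weights, months = months,
                 resolution_month = resolution_month),
            class = "tumor_comparison")
}

#' @export
print.tumor_comparison <- function(x, ...) {
  cat(sprintf(
    "<tumor_comparison> totals: %.1f (tumor-specific) vs %.1f (uniform RD %g, HR %g)\n",
    x$totals["specific"], x$totals["uniform"],
    x$uniform_params$rd, x$uniform_params$hr))
  print(x$by_tumor)
  invisible(x)
}
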