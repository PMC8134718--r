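# Report generation: the orchestration layer behind the command-line
# entry point (exec/oncodelay). Data go to files; messages go to stderr.

#' Run manifest attached to every report
#'
#' @param inputs Named list of input paths / labels.
#' @param config The configuration list the run used.
#' @param seed Seed, if any randomness was involved.
#' @return List with package version, UTC timestamp, inputs, a stable hash
#'   of the configuration, and the seed.
#' @export
run_manifest <- function(inputs = list(), config = list(), seed = NULL) {
  list(package = "oncodelay",
       version = as.character(utils::packageVersion("oncodelay")),
       created_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
       inputs = inputs,
       config_hash = rlang::hash(config),
       seed = seed)
}

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  invisible(path)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Describe year-over-year reductions in a cohort CSV
#'
#' Writes `reduction.csv` (per-month series) and `describe_summary.json`
#' (cumulative totals, missing patients, manifest) to `out_dir`.
#'
#' @param cohort Path to a cohort CSV or a [cohort_table()].
#' @param ref_year,obs_year Years compared.
#' @param window Month window (default March-July).
#' @param stratum Stratum filter (default new patients, all strata).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, list with `series`, `summary`, `manifest`, and the
#'   paths written.
#' @export
cmd_describe <- function(cohort, ref_year, obs_year, window = 3:7,
                         stratum = cohort_stratum(), out_dir = ".") {
  if (length(window) == 0) stop_validation("empty month window")
  input <- if (is.character(cohort)) cohort else attr(cohort, "source")
  table <- if (is.character(cohort)) read_cohort_csv(cohort) else cohort
  series <- monthly_reduction(table, ref_year, obs_year, window, stratum)
  summary <- cumulative_reduction(series)
  manifest <- run_manifest(
    inputs = list(cohort = input),
    config = list(ref_year = ref_year, obs_year = obs_year,
                  window = window, stratum = stratum))
  ensure_dir(out_dir)
  csv_path <- file.path(out_dir, "reduction.csv")
  json_path <- file.path(out_dir, "describe_summary.json")
  readr::write_csv(tibble::as_tibble(series), csv_path)
  write_json(c(summary, list(ref_year = ref_year, obs_year = obs_year,
                             window = window, manifest = manifest)),
             json_path)
  message(sprintf("describe: %d months, missing_total = %g, fraction = %.4f",
                  nrow(series), summary$missing_total, summary$fraction))
  invisible(list(series = series, summary = summary, manifest = manifest,
                 paths = c(csv_path, json_path)))
}

#' Estimate national excess deaths and scenario grids
#'
#' Writes one grid CSV per hazard ratio (`grid_hr_<hr>.csv`, rows additional
#' months of delay, columns additional reduction percentage points) plus
#' `national_estimate.json` with the per-month base-scenario estimate and all
#' assumptions echoed.
#'
#' @param cohort Path to a cohort CSV or a [cohort_table()]; the reduction
#'   series is computed from it.
#' @param ref_year,obs_year Years compared.
#' @param window Month window (default March-July).
#' @param baseline A [national_baseline()].
#' @param rd Baseline death rate shared by all panels (default 0.41).
#' @param hr Hazard ratio of the base estimate (default 1.06).
#' @param hr_sweep Hazard ratios for the grid panels
#'   (default 1.02, 1.06, 1.1).
#' @param resolution_month Default August.
#' @param extra_months,extra_pct Grid axes.
#' @param fraction_digits Published precision the fractions are rounded to
#'   (default 3); see [national_excess()].
#' @param out_dir Output directory.
#' @return Invisibly, list with `series`, `estimate`, `grids`, `manifest`,
#'   `paths`.
#' @export
cmd_estimate <- function(cohort, ref_year = 2019, obs_year = 2020,
                         window = 3:7, baseline = national_baseline(),
                         rd = 0.41, hr = 1.06,
                         hr_sweep = c(1.02, 1.06, 1.1),
                         resolution_month = 8L,
                         extra_months = 0:4,
                         extra_pct = seq(0, 0.25, by = 0.05),
                         fraction_digits = 3, out_dir = ".") {
  input <- if (is.character(cohort)) cohort else attr(cohort, "source")
  table <- if (is.character(cohort)) read_cohort_csv(cohort) else cohort
  series <- monthly_reduction(table, ref_year, obs_year, window)
  params <- risk_params(rd = rd, hr = hr)
  estimate <- national_excess(series, params, baseline, resolution_month,
                              fraction_digits = fraction_digits)
  f <- series$fraction
  if (is.finite(fraction_digits)) f <- round(f, fraction_digits)
  grids <- scenario_grid_sweep(
    setNames(f, series$month), baseline$monthly_new_cases,
    hr_sweep = hr_sweep, rd = rd, resolution_month = resolution_month,
    extra_months = extra_months, extra_pct = extra_pct)
  manifest <- run_manifest(
    inputs = list(cohort = input),
    config = list(ref_year = ref_year, obs_year = obs_year, window = window,
                  rd = rd, hr = hr, hr_sweep = hr_sweep,
                  resolution_month = resolution_month,
                  monthly_new_cases = baseline$monthly_new_cases,
                  extra_months = extra_months, extra_pct = extra_pct,
                  fraction_digits = fraction_digits))
  ensure_dir(out_dir)
  paths <- character(0)
  for (nm in names(grids)) {
    p <- file.path(out_dir, paste0("grid_", nm, ".csv"))
    g <- grids[[nm]]
    df <- data.frame(additional_months = rownames(g),
                     round(unclass(g)), check.names = FALSE)
    readr::write_csv(df, p)
    paths <- c(paths, p)
  }
  json_path <- file.path(out_dir, "national_estimate.json")
  write_json(list(per_month = estimate$per_month,
                  total = estimate$total,
                  assumptions = list(
                    rd = rd, hr = hr,
                    resolution_month = resolution_month,
                    monthly_new_cases = baseline$monthly_new_cases,
                    fractions = f, months = series$month,
                    fraction_digits = fraction_digits),
                  manifest = manifest),
             json_path)
  message(sprintf("estimate: base total %.1f excess deaths (HR %g)",
                  estimate$total, hr))
  invisible(list(series = series, estimate = estimate, grids = grids,
                 manifest = manifest, paths = c(paths, json_path)))
}

#' Tumor-specific vs uniform excess-death comparison report
#'
#' Writes `tumor_comparison.csv` with per-tumor missing patients, death
#' rates, hazard ratios and the two estimates, plus a totals row.
#'
#' @param specs Tumor specification table (default the packaged
#'   [tumor_specs()]).
#' @param monthly_weights Per-month weights; default the network monthly
#'   missing profile from the packaged data.
#' @param months,resolution_month,uniform_params See
#'   [tumor_specific_excess()].
#' @param out_dir Output directory.
#' @return Invisibly, list with `comparison`, `manifest`, `paths`.
#' @export
cmd_tumor <- function(specs = tumor_specs(), monthly_weights = NULL,
                      months = 3:7, resolution_month = 8L,
                      uniform_params = risk_params(0.41, 1.06),
                      out_dir = ".") {
  if (is.null(monthly_weights)) {
    series <- monthly_reduction(unicancer_monthly("network"), 2019, 2020,
                                window = months)
    monthly_weights <- series$missing / sum(series$missing)
  }
  comparison <- tumor_specific_excess(specs, monthly_weights, months,
                                      resolution_month, uniform_params)
  manifest <- run_manifest(
    inputs = list(specs = "tumor_specs"),
    config = list(months = months, resolution_month = resolution_month,
                  uniform = unclass(uniform_params),
                  monthly_weights = monthly_weights))
  ensure_dir(out_dir)
  csv_path <- file.path(out_dir, "tumor_comparison.csv")
  out <- comparison$by_tumor
  out <- dplyr::bind_rows(
    out,
    tibble::tibble(label = "total", missing = sum(out$missing),
                   rd = NA_real_, hr = NA_real_,
                   excess_specific = comparison$totals["specific"],
                   excess_uniform = comparison$totals["uniform"]))
  readr::write_csv(out, csv_path)
  write_json(list(totals = as.list(comparison$totals), manifest = manifest),
             file.path(out_dir, "tumor_summary.json"))
  message(sprintf("tumor: totals %.1f (specific) vs %.1f (uniform)",
                  comparison$totals["specific"], comparison$totals["uniform"]))
  invisible(list(comparison = comparison, manifest = manifest,
                 paths = csv_path))
}

#' Simulate a synthetic cohort and write it as a cohort CSV
#'
#' @param out_path Output CSV path.
#' @param config A [generator_config()]; `seed` overrides its seed.
#' @param years,months Coverage to generate.
#' @param seed Optional seed override.
#' @return Invisibly, list with the `table`, `manifest` and `paths`.
#' @export
cmd_simulate <- function(out_path, config = generator_config(),
                         years = c(2019, 2020), months = 1:7, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  table <- generate_cohort(config, years = years, months = months)
  ensure_dir(dirname(out_path))
  write_cohort_csv(table, out_path)
  manifest <- run_manifest(
    inputs = list(),
    config = config[c("n_centers", "baseline_mean", "annual_growth",
                      "dip_year", "noise")],
    seed = config$seed)
  manifest_path <- paste0(sub("\\.csv$", "", out_path), "_manifest.json")
  write_json(manifest, manifest_path)
  message(sprintf("simulate: %d records written to %s (seed %d)",
                  nrow(table), out_path, config$seed))
  invisible(list(table = table, manifest = manifest,
                 paths = c(out_path, manifest_path)))
}
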