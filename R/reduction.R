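# Year-over-year reduction and ratio series on monthly counts.

#' Default stratum filter: newly diagnosed patients, all tumors/sexes/stages
#'
#' @param patient_status,tumor_group,sex,stage Single stratum levels.
#' @return Named list usable as the `stratum` argument of
#'   [monthly_reduction()] and [ratio_series()].
#' @export
cohort_stratum <- function(patient_status = "new", tumor_group = "all",
                           sex = "all", stage = "all") {
  list(patient_status = patient_status, tumor_group = tumor_group,
       sex = sex, stage = stage)
}

aggregate_monthly <- function(table, years, window, stratum) {
  dat <- tibble::as_tibble(table)
  for (dim in names(stratum)) {
    dat <- dat[dat[[dim]] == stratum[[dim]], , drop = FALSE]
  }
  dat <- dat[dat$year %in% years & dat$month %in% window, , drop = FALSE]
  dat |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

#' Construct a per-month reduction series from reference and observed counts
#'
#' The signed reduction fraction is `f_m = (ref - obs) / ref`; a negative
#' value means the observed month exceeded the reference. `missing` counts
#' only deficits: `max(ref - obs, 0)`, because the delay model treats only
#' missing patients as delayed.
#'
#' @param month Integer month indices (1-12), ordered.
#' @param ref_counts,obs_counts Counts in the reference and observation year.
#' @param ref_year,obs_year Optional year labels.
#' @return A `reduction_series` tibble with columns
#'   `month, ref, obs, fraction, missing`.
#' @export
reduction_series <- function(month, ref_counts, obs_counts,
                             ref_year = NA_integer_, obs_year = NA_integer_) {
  stopifnot(length(month) == length(ref_counts),
            length(month) == length(obs_counts))
  if (any(ref_counts <= 0)) {
    bad <- month[ref_counts <= 0][1]
    stop_degenerate(sprintf(
      "reduction fraction undefined: reference count is zero for month %d", bad))
  }
  out <- tibble::tibble(
    month = as.integer(month),
    ref = as.numeric(ref_counts),
    obs = as.numeric(obs_counts),
    fraction = (ref_counts - obs_counts) / ref_counts,
    missing = pmax(ref_counts - obs_counts, 0))
  structure(out, class = c("reduction_series", class(out)),
            ref_year = as.integer(ref_year), obs_year = as.integer(obs_year))
}

#' Per-month reduction between two years of a cohort table
#'
#' Aggregates counts over centers for the requested stratum and window and
#' compares the observation year against the reference year month by month.
#'
#' @param table A [cohort_table()].
#' @param ref_year,obs_year Reference and observation calendar years.
#' @param window Integer months to compare (default March-July).
#' @param stratum Stratum filter, see [cohort_stratum()].
#' @return A [reduction_series()].
#' @export
monthly_reduction <- function(table, ref_year, obs_year, window = 3:7,
                              stratum = cohort_stratum()) {
  stopifnot(inherits(table, "cohort_table"))
  agg <- aggregate_monthly(table, c(ref_year, obs_year), window, stratum)
  for (yr in c(ref_year, obs_year)) {
    got <- agg$month[agg$year == yr]
    if (!all(window %in% got)) {
      stop_validation(sprintf(
        "year %d does not cover month(s) %s for the requested stratum",
        yr, paste(setdiff(window, got), collapse = ", ")))
    }
  }
  ref <- agg[agg$year == ref_year, ]
  obs <- agg[agg$year == obs_year, ]
  ref <- ref[match(window, ref$month), ]
  obs <- obs[match(window, obs$month), ]
  reduction_series(window, ref$count, obs$count,
                   ref_year = ref_year, obs_year = obs_year)
}

#' Cumulative reduction over a window
#'
#' @param series A [reduction_series()].
#' @return List with `ref_total`, `obs_total` and the cumulated `fraction`
#'   `(sum(ref) - sum(obs)) / sum(ref)`, plus `missing_total`, the clamped
#'   per-month deficit sum.
#' @export
cumulative_reduction <- function(series) {
  stopifnot(inherits(series, "reduction_series"))
  if (nrow(series) == 0) stop_validation("empty reduction series")
  ref_total <- sum(series$ref)
  obs_total <- sum(series$obs)
  list(ref_total = ref_total, obs_total = obs_total,
       fraction = (ref_total - obs_total) / ref_total,
       missing_total = sum(series$missing))
}

#' Per-month observed/reference count ratios between year pairs
#'
#' For each `(ref_year, obs_year)` pair, the monthly ratio `obs / ref` for
#' the requested stratum, aggregated over centers. Ratios relate to reduction
#' fractions by `fraction = 1 - ratio`.
#'
#' @param table A [cohort_table()].
#' @param year_pairs A length-2 vector `c(ref, obs)` or a list of such pairs.
#' @param window Integer months (default January-July).
#' @param stratum Stratum filter, see [cohort_stratum()].
#' @return Tibble with columns `ref_year, obs_year, month, ref, obs, ratio`.
#' @export
ratio_series <- function(table, year_pairs, window = 1:7,
                         stratum = cohort_stratum()) {
  stopifnot(inherits(table, "cohort_table"))
  if (!is.list(year_pairs)) year_pairs <- list(year_pairs)
  out <- lapply(year_pairs, function(pair) {
    stopifnot(length(pair) == 2)
    agg <- aggregate_monthly(table, pair, window, stratum)
    ref <- agg[agg$year == pair[1], ]
    obs <- agg[agg$year == pair[2], ]
    months <- intersect(window, intersect(ref$month, obs$month))
    if (length(months) == 0) {
      stop_validation(sprintf("years %d/%d do not cover the window",
                              pair[1], pair[2]))
    }
    ref <- ref[match(months, ref$month), ]
    obs <- obs[match(months, obs$month), ]
    if (any(ref$count == 0)) {
      stop_degenerate(sprintf(
        "ratio undefined: zero reference count in month %d of %d",
        months[ref$count == 0][1], pair[1]))
    }
    ref_counts <- ref$count
    obs_counts <- obs$count
    tibble::tibble(ref_year = pair[1], obs_year = pair[2], month = months,
                   ref = ref_counts, obs = obs_counts,
                   ratio = obs_counts / ref_counts)
  })
  dplyr::bind_rows(out)
}
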