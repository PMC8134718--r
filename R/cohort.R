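# Monthly patient-count data model: long/tidy records keyed by
# (center, year, month, patient_status, tumor_group, sex, stage).

COHORT_COLUMNS <- c("center_id", "year", "month", "patient_status",
                    "tumor_group", "sex", "stage", "count")

PATIENT_STATUS_LEVELS <- c("new", "previously_diagnosed")
TUMOR_GROUP_LEVELS <- c("breast", "digestive", "thoracic_lung",
                        "gynecological", "head_and_neck", "urological",
                        "hematological", "skin", "other", "all")
SEX_LEVELS   <- c("male", "female", "all")
STAGE_LEVELS <- c("metastatic", "nonmetastatic", "all")

#' Assemble and validate a cohort table of monthly patient counts
#'
#' A cohort table holds monthly counts of patients by center and stratum,
#' where a stratum is the tuple (patient_status, tumor_group, sex, stage).
#' The literal level `"all"` marks a margin over a stratum dimension; when a
#' table carries both an `"all"` row and the complete set of its sub-strata,
#' the margin must equal their sum.
#'
#' @param records Data frame with columns
#'   `center_id, year, month, patient_status, tumor_group, sex, stage, count`.
#' @param covid_zone Optional named character vector mapping every
#'   `center_id` to `"high"` or `"low"` COVID-19 incidence zone.
#' @param source Character label describing where the counts come from.
#' @param integer_counts Require counts to be whole numbers (default). The
#'   synthetic generator's noiseless mode stores expectation surfaces and
#'   sets this to `FALSE`; file readers always enforce integers.
#' @return An object of class `cohort_table`: the validated records tibble
#'   with `covid_zone`, `source` and `coverage` attributes.
#' @export
cohort_table <- function(records, covid_zone = NULL, source = "unspecified",
                         integer_counts = TRUE) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop_parse(paste0("cohort records lack column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  records <- records[COHORT_COLUMNS]
  records$center_id <- as.character(records$center_id)
  records$year <- as.integer(records$year)
  records$month <- as.integer(records$month)

  if (anyNA(records)) stop_validation("cohort records contain missing values")
  if (any(records$month < 1L | records$month > 12L)) {
    stop_validation("month must lie in 1..12")
  }
  check_level <- function(col, levels) {
    bad <- setdiff(unique(records[[col]]), levels)
    if (length(bad) > 0) {
      stop_validation(paste0("invalid ", col, " level(s): ",
                             paste(bad, collapse = ", ")))
    }
  }
  check_level("patient_status", PATIENT_STATUS_LEVELS)
  check_level("tumor_group", TUMOR_GROUP_LEVELS)
  check_level("sex", SEX_LEVELS)
  check_level("stage", STAGE_LEVELS)

  if (any(records$count < 0)) {
    stop_validation("counts must be nonnegative")
  }
  if (integer_counts && any(records$count != round(records$count))) {
    stop_validation("counts must be whole numbers")
  }

  key <- do.call(paste, c(records[setdiff(COHORT_COLUMNS, "count")], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE][1, ]
    stop_integrity(sprintf(
      "duplicate record for center %s, %d-%02d, stratum (%s, %s, %s, %s)",
      dup$center_id, dup$year, dup$month, dup$patient_status,
      dup$tumor_group, dup$sex, dup$stage))
  }

  if (!is.null(covid_zone)) {
    covid_zone <- unlist(covid_zone)
    centers <- unique(records$center_id)
    unzoned <- setdiff(centers, names(covid_zone))
    if (length(unzoned) > 0) {
      stop_validation(paste0("covid_zone misses center(s): ",
                             paste(unzoned, collapse = ", ")))
    }
    if (!all(covid_zone %in% c("high", "low"))) {
      stop_validation("covid_zone values must be 'high' or 'low'")
    }
  }

  validate_margins(records)

  structure(records,
            class = c("cohort_table", class(tibble::tibble()))) -> out
  attr(out, "covid_zone") <- covid_zone
  attr(out, "source") <- source
  attr(out, "coverage") <- dplyr::distinct(records, .data$year, .data$month)
  out
}

# "all" margins are validated only when the complete set of sub-levels is
# present alongside the margin (the source tables report margins and partial
# strata inconsistently, so absence of sub-strata is not an error).
validate_margins <- function(records) {
  dims <- list(sex = c("male", "female"),
               stage = c("metastatic", "nonmetastatic"),
               tumor_group = setdiff(TUMOR_GROUP_LEVELS, "all"))
  for (dim in names(dims)) {
    others <- setdiff(setdiff(COHORT_COLUMNS, "count"), dim)
    grp <- records |>
      dplyr::group_by(dplyr::across(dplyr::all_of(others))) |>
      dplyr::summarise(
        has_all = any(.data[[dim]] == "all"),
        complete = all(dims[[dim]] %in% .data[[dim]]),
        margin = sum(.data$count[.data[[dim]] == "all"]),
        parts = sum(.data$count[.data[[dim]] %in% dims[[dim]]]),
        .groups = "drop")
    bad <- grp[grp$has_all & grp$complete &
                 abs(grp$margin - grp$parts) > 1e-8, , drop = FALSE]
    if (nrow(bad) > 0) {
      b <- bad[1, ]
      stop_integrity(sprintf(
        "'all' margin over %s (%s vs sum %s) inconsistent for center %s, %d-%02d",
        dim, format(b$margin), format(b$parts), b$center_id, b$year, b$month))
    }
  }
  invisible(records)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d records, %d centers, source: %s\n",
              nrow(x), length(unique(x$center_id)), attr(x, "source")))
  NextMethod()
}

#' Read a cohort table from a tidy CSV file
#'
#' The expected header is
#' `center_id,year,month,patient_status,tumor_group,sex,stage,count`, one row
#' per center/month/stratum, with `all` marking stratum margins.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param covid_zone Optional named character vector of center zones.
#' @param source Label stored with the table; defaults to the file name.
#' @return A [cohort_table()].
#' @export
read_cohort_csv <- function(path, covid_zone = NULL, source = basename(path)) {
  if (!file.exists(path)) stop_parse(paste0("file not found: ", path))
  dat <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      center_id = readr::col_character(),
      year = readr::col_integer(),
      month = readr::col_integer(),
      patient_status = readr::col_character(),
      tumor_group = readr::col_character(),
      sex = readr::col_character(),
      stage = readr::col_character(),
      count = readr::col_double()),
    progress = FALSE, show_col_types = FALSE))
  missing_cols <- setdiff(COHORT_COLUMNS, names(dat))
  if (length(missing_cols) > 0) {
    stop_parse(paste0("header of ", path, " lacks column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  probs <- readr::problems(dat)
  if (nrow(probs) > 0) {
    stop_parse(sprintf("malformed row at line %d of %s: expected %s, got '%s'",
                       probs$row[1] + 1L, path, probs$expected[1], probs$actual[1]))
  }
  if (any(!is.finite(dat$count)) ||
      any(dat$count != round(dat$count))) {
    stop_parse(paste0("counts in ", path, " must parse as integers"))
  }
  cohort_table(dat, covid_zone = covid_zone, source = source)
}

#' Write a cohort table to CSV
#'
#' @param table A [cohort_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}

#' Monthly new-patient counts observed in the Unicancer network
#'
#' Counts of newly diagnosed cancer patients per month (January-July of 2019
#' and 2020) in 17 French comprehensive cancer centers, as published by the
#' network.
#'
#' Two views are shipped. `"network"` holds the published network totals row
#' (January-July sums 47 159 in 2019 and 43 947 in 2020, `center_id`
#' `"NETWORK"`). `"centers"` holds the 17 per-center rows with their high/low
#' COVID-19 incidence-zone labels. Each per-center row is internally
#' consistent with its published January-July totals and 2020/2019 ratio,
#' but the 17 rows sum to about 3-4% less than the published network totals
#' row (45 649 vs 47 159 in 2019); the published table carries this
#' discrepancy and both views are therefore kept as printed, without
#' reconciliation.
#'
#' @param level `"network"` for the totals series, `"centers"` for the
#'   per-center table.
#' @return A [cohort_table()].
#' @export
unicancer_monthly <- function(level = c("network", "centers")) {
  level <- match.arg(level)
  file <- if (level == "network") "unicancer_network_monthly.csv" else
    "unicancer_centers_monthly.csv"
  path <- system.file("extdata", file, package = "oncodelay", mustWork = TRUE)
  zone <- NULL
  if (level == "centers") {
    zone <- unlist(unicancer_constants()$covid_zone)
  }
  read_cohort_csv(path, covid_zone = zone,
                  source = paste0("Unicancer 2019/2020 (", level, ")"))
}

#' Published national and network constants
#'
#' National incidence baselines (382 000 new solid-tumor diagnoses/year,
#' 157 400 cancer deaths/year, 31 833 new diagnoses/month), the default risk
#' parameters (RD = 0.41, HR = 1.06 with sensitivity sweep 1.02/1.1), the
#' network January-July and March-July window totals for 2016-2020, the
#' per-tumor incidence/mortality table, and the center zone map. Each block
#' carries a `source` note.
#'
#' @return Nested list parsed from the packaged YAML constants file.
#' @export
unicancer_constants <- function() {
  path <- system.file("extdata", "national_constants.yaml",
                      package = "oncodelay", mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Tumor-specific incidence, mortality and delay hazard ratios
#'
#' Five-tumor table (colorectal, head and neck, bladder, breast, lung):
#' annual incidence and deaths in France (2018), the per-month-of-delay
#' hazard ratio used for each tumor (1.08 for breast, 1.06 otherwise), and
#' the network March-July new-patient counts for 2019 and 2020.
#'
#' @return Tibble with one row per tumor, columns `label`,
#'   `annual_incidence`, `annual_deaths`, `hr`, `missing_ref`, `missing_obs`.
#' @export
tumor_specs <- function() {
  tu <- unicancer_constants()$tumors
  dplyr::bind_rows(lapply(tu, tibble::as_tibble))
}
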