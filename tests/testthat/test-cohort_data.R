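# Data model, CSV I/O and descriptive statistics on monthly counts.

test_that("the packaged center table loads with 17 centers x 14 months", {
  tab <- unicancer_monthly("centers")
  expect_s3_class(tab, "cohort_table")
  expect_equal(length(unique(tab$center_id)), 17)
  expect_equal(nrow(tab), 17 * 14)
  zone <- attr(tab, "covid_zone")
  expect_setequal(unique(zone), c("high", "low"))
  expect_equal(sum(zone == "high"), 5)
})

test_that("network totals row reproduces the published window sums", {
  tab <- unicancer_monthly("network")
  by_year <- tapply(tab$count, tab$year, sum)
  expect_equal(unname(by_year[["2019"]]), 47159)
  expect_equal(unname(by_year[["2020"]]), 43947)
})

test_that("CSV reader validates structure and content", {
  ok <- write_tiny_cohort("A,2019,3,new,all,all,all,10")
  tab <- read_cohort_csv(ok)
  expect_equal(tab$count, 10)

  empty <- write_tiny_cohort(character(0))
  expect_equal(nrow(read_cohort_csv(empty)), 0)

  neg <- write_tiny_cohort("A,2019,3,new,all,all,all,-3")
  expect_error(read_cohort_csv(neg), class = "oncodelay_validation_error")

  dup <- write_tiny_cohort(c("A,2019,3,new,all,all,all,10",
                             "A,2019,3,new,all,all,all,11"))
  expect_error(read_cohort_csv(dup), class = "oncodelay_integrity_error")

  bad <- write_tiny_cohort("A,2019,3,new,all,all,all,ten")
  expect_error(read_cohort_csv(bad), class = "oncodelay_parse_error")

  missing_col <- tempfile(fileext = ".csv")
  writeLines(c("center_id,year,month,count", "A,2019,3,10"), missing_col)
  expect_error(read_cohort_csv(missing_col), class = "oncodelay_parse_error")

  expect_error(read_cohort_csv(tempfile()), class = "oncodelay_parse_error")
})

test_that("'all' margins are checked only when sub-strata are complete", {
  base <- c("A,2019,3,new,all,male,all,4",
            "A,2019,3,new,all,female,all,6")
  ok <- write_tiny_cohort(c(base, "A,2019,3,new,all,all,all,10"))
  expect_s3_class(read_cohort_csv(ok), "cohort_table")

  wrong <- write_tiny_cohort(c(base, "A,2019,3,new,all,all,all,12"))
  expect_error(read_cohort_csv(wrong), class = "oncodelay_integrity_error")

  # one sex missing: margin cannot be checked, accept as printed
  partial <- write_tiny_cohort(c("A,2019,3,new,all,male,all,4",
                                 "A,2019,3,new,all,all,all,12"))
  expect_s3_class(read_cohort_csv(partial), "cohort_table")
})

test_that("monthly_reduction reproduces the March-July network reductions", {
  tab <- unicancer_monthly("network")
  s <- monthly_reduction(tab, 2019, 2020, window = 3:7)
  expect_equal(s$ref, c(6736, 6673, 6672, 6319, 7306))
  expect_equal(s$obs, c(6645, 5296, 5218, 6208, 6477))
  expect_equal(round(s$fraction, 3), paper_fractions)
  expect_equal(sum(s$missing), 3862)
})

test_that("reduction fractions are signed but missing counts are clamped", {
  s <- reduction_series(1:2, c(100, 100), c(90, 110))
  expect_equal(s$fraction, c(0.10, -0.10))
  expect_equal(sum(s$missing), 10)

  same <- reduction_series(3:7, c(5, 5, 5, 5, 5), c(5, 5, 5, 5, 5))
  expect_equal(same$fraction, rep(0, 5))
  expect_equal(sum(same$missing), 0)

  expect_error(reduction_series(1, 0, 5), class = "oncodelay_degenerate_error")
  expect_error(reduction_series(1, 0, 5), "month 1")
})

test_that("monthly_reduction requires full window coverage", {
  tab <- unicancer_monthly("network")
  expect_error(monthly_reduction(tab, 2019, 2020, window = 3:9),
               class = "oncodelay_validation_error")
})

test_that("cumulative reductions match the published window totals", {
  tab <- unicancer_monthly("network")
  mar_jul <- cumulative_reduction(monthly_reduction(tab, 2019, 2020, 3:7))
  expect_equal(mar_jul$ref_total, 33706)
  expect_equal(mar_jul$obs_total, 29844)
  expect_equal(round(mar_jul$fraction, 4), 0.1146)

  jan_jul <- cumulative_reduction(monthly_reduction(tab, 2019, 2020, 1:7))
  expect_equal(jan_jul$ref_total, 47159)
  expect_equal(jan_jul$obs_total, 43947)
  expect_equal(round(jan_jul$fraction, 4), 0.0681)

  single <- cumulative_reduction(reduction_series(7, 50, 50))
  expect_equal(single$fraction, 0)
})

test_that("chi-square matches the closed-form oracle and known cases", {
  expect_equal(chi_square_2x2(10, 10, 10, 10)$statistic, 0)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$p_value, 1)

  expect_equal(round(chi_square_2x2(20, 80, 40, 60)$statistic, 3), 9.524)

  # 2020 vs 2019, newly vs previously diagnosed patients
  res <- chi_square_2x2(43947, 46802, 47159, 44938)
  expect_lt(res$p_value, 1e-4)

  set.seed(7)
  for (i in 1:50) {
    cells <- rpois(4, lambda = sample(c(5, 50, 500), 4, replace = TRUE)) + 1
    got <- chi_square_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$statistic,
                 chi2_formula(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }

  expect_error(chi_square_2x2(0, 0, 5, 5),
               class = "oncodelay_degenerate_error")
  expect_error(chi_square_2x2(-1, 2, 3, 4),
               class = "oncodelay_validation_error")
})

test_that("rank-sum exact branch agrees with enumeration", {
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, rank_sum_enumerate(c(1, 2, 3), c(4, 5, 6)))
})

test_that("identical groups give a flagged p of 1", {
  expect_warning(res <- rank_sum_test(c(1, 1), c(1, 1)), "identical")
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
})

test_that("high vs low COVID-zone center ratios are not significantly different", {
  tab <- unicancer_monthly("centers")
  zone <- attr(tab, "covid_zone")
  per_center <- stats::aggregate(count ~ center_id + year,
                                 data = as.data.frame(tab), FUN = sum)
  wide <- reshape(per_center, idvar = "center_id", timevar = "year",
                  direction = "wide")
  ratio <- wide$count.2020 / wide$count.2019
  hi <- ratio[zone[wide$center_id] == "high"]
  lo <- ratio[zone[wide$center_id] == "low"]
  expect_length(hi, 5)
  expect_length(lo, 12)
  res <- rank_sum_test(hi, lo)
  expect_equal(res$method, "normal")
  expect_equal(round(res$p_value, 1), 0.2)
})

test_that("exact and normal branches agree within 0.05 on untied 6+6 samples", {
  set.seed(11)
  for (i in 1:25) {
    x <- sample(seq(1, 200), 6)
    y <- sample(setdiff(seq(1, 200), x), 6)
    p_exact <- rank_sum_test(x, y, method = "exact")$p_value
    p_norm <- rank_sum_test(x, y, method = "normal")$p_value
    expect_lt(abs(p_exact - p_norm), 0.05)
  }
})

test_that("ratio series reproduce the published monthly ratios", {
  tab <- unicancer_monthly("network")
  rs <- ratio_series(tab, c(2019, 2020), window = 1:7)
  expect_equal(rs$ref[rs$month == 1], 7069)
  expect_equal(rs$obs[rs$month == 1], 7378)
  expect_equal(round(rs$ratio[rs$month == 1], 4), 1.0437)

  same <- ratio_series(tab, c(2019, 2019), window = 1:7)
  expect_equal(same$ratio, rep(1, 7))
})

test_that("published network growth 2017->2018 is +3.1%", {
  nt <- unicancer_constants()$network_totals$treated_jan_jul
  expect_equal(round(nt$y2018 / nt$y2017, 4), 1.0312)
  expect_equal(round(nt$y2017 / nt$y2016, 3), 1.027)
})

test_that("reduction fraction and ratio are complementary", {
  tab <- unicancer_monthly("centers")
  s <- monthly_reduction(tab, 2019, 2020, 3:7)
  rs <- ratio_series(tab, c(2019, 2020), window = 3:7)
  expect_equal(s$fraction, 1 - rs$ratio, tolerance = 1e-12)
})
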