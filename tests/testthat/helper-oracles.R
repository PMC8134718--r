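# Independent oracles used to freeze expected values.

# Textbook Pearson chi-square for a 2x2 table: N (ad - bc)^2 / product of margins.
chi2_formula <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Exact two-sided Mann-Whitney p by full enumeration of label assignments.
rank_sum_enumerate <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mu <- m * (length(y)) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Delayed death probability through the survival-power form, kept separate
# from the exp/log implementation path.
rddel_power <- function(rd, hr, n) 1 - (1 - rd)^(hr^n)

# Minimal cohort CSV writer for I/O tests.
write_tiny_cohort <- function(lines, path = tempfile(fileext = ".csv")) {
  header <- "center_id,year,month,patient_status,tumor_group,sex,stage,count"
  writeLines(c(header, lines), path)
  path
}

paper_fractions <- c(0.014, 0.206, 0.218, 0.018, 0.113)
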