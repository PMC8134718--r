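# National incidence baselines and network window totals used by the
# excess-mortality analysis. Each block notes where the figure was reported.

national:
  monthly_new_cases: 31833
  annual_new_cases: 382000
  annual_deaths: 157400
  observed_reduction_2020: 0.233
  source: >
    French National Cancer Institute figures for 2018 (382 000 new
    solid-tumor diagnoses, 157 400 cancer deaths, i.e. a 41% death rate;
    31 833 new diagnoses per month). The 23.3% national reduction in newly
    diagnosed cancers for January-July 2020 vs 2019 is an external constant
    from the national social-security platform as consulted on 24 Nov 2020;
    it is carried as configuration, never recomputed.

risk:
  rd: 0.41
  hr: 1.06
  hr_sweep: [1.02, 1.06, 1.1]
  source: >
    Uniform per-month-of-delay hazard ratio 1.06 (meta-analysis estimate for
    frequent cancer types), with 1.02 and 1.1 as sensitivity extremes;
    death rate 0.41 = 157 400 / 382 000.

resolution_month: 8

grid:
  extra_months: [0, 1, 2, 3, 4]
  extra_pct: [0.0, 0.05, 0.10, 0.15, 0.20, 0.25]

# January-July and March-July totals for the 17-center network. The
# previously-diagnosed change was reported as +4.5% although the printed
# counts (46 802 vs 44 938) give +4.15%; the counts are stored as printed
# and the discrepancy is not resolved here. Likewise two breast March-July
# count pairs circulate (text: 10 525/8 428; five-tumor table:
# 10 115/8 194); both are stored.
network_totals:
  treated_jan_jul: {y2016: 81666, y2017: 83877, y2018: 86493, y2019: 90432, y2020: 89161}
  new_jan_jul: {y2019: 47159, y2020: 43947}
  previously_diagnosed_jan_jul: {y2019: 44938, y2020: 46802}
  new_mar_jul: {y2019: 33706, y2020: 29844}
  breast_mar_jul_text: {y2019: 10525, y2020: 8428}

covid_zone:
  C01: low
  C02: low
  C03: low
  C04: high
  C05: low
  C06: low
  C07: high
  C08: low
  C09: high
  C10: low
  C11: high
  C12: high
  C13: low
  C14: low
  C15: low
  C16: low
  C17: low

# Five-tumor comparison inputs: annual incidence and deaths in France
# (2018), per-month-of-delay hazard ratio (1.08 for breast, 1.06 for the
# others), and network March-July new-patient counts in 2019 (missing_ref)
# and 2020 (missing_obs).
tumors:
  - label: colorectal
    annual_incidence: 20120
    annual_deaths: 7908
    hr: 1.06
    missing_ref: 1626
    missing_obs: 1439
  - label: head_and_neck
    annual_incidence: 4298
    annual_deaths: 1055
    hr: 1.06
    missing_ref: 1977
    missing_obs: 1826
  - label: bladder
    annual_incidence: 2448
    annual_deaths: 1223
    hr: 1.06
    missing_ref: 553
    missing_obs: 517
  - label: breast
    annual_incidence: 58547
    annual_deaths: 12146
    hr: 1.08
    missing_ref: 10115
    missing_obs: 8194
  - label: lung
    annual_incidence: 15132
    annual_deaths: 10356
    hr: 1.06
    missing_ref: 2701
    missing_obs: 2590
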