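test_that("daily MME sums active fills through the conversion factors", {
  mor <- make_rx(drug_code = "MOR_PO", start_date = "2016-03-01",
                 days_supplied = 10, units_per_day = 2, unit_strength_mg = 30)
  expect_equal(daily_mme(mor, "2016-03-05"), 60)
  oxy <- make_rx(drug_code = "OXY_PO", start_date = "2016-03-01",
                 days_supplied = 10, units_per_day = 4, unit_strength_mg = 10)
  expect_equal(daily_mme(oxy, "2016-03-05"), 60)
  both <- rbind(mor, oxy)
  expect_equal(daily_mme(both, "2016-03-05"), 120)
  # outside the covered interval the fill is inactive
  expect_equal(daily_mme(mor, "2016-03-11"), 0)
  expect_equal(daily_mme(mor, "2016-03-10"), 60)  # closed range end day
  bad <- make_rx(drug_code = "TRAMADOL")
  expect_error(daily_mme(bad, "2016-03-05"), "TRAMADOL")
})

test_that("high-dose proportion uses an inclusive threshold on the max day", {
  # one patient at exactly 100 MME/day, one below
  fills <- rbind(
    make_rx(rx_id = "R1", patient_id = "A", drug_code = "MOR_PO",
            start_date = "2016-03-02", days_supplied = 5,
            units_per_day = 2, unit_strength_mg = 50),
    make_rx(rx_id = "R2", patient_id = "B", drug_code = "MOR_PO",
            start_date = "2016-03-02", days_supplied = 5,
            units_per_day = 2, unit_strength_mg = 49.5)
  )
  expect_equal(high_dose_proportion(fills, 2016, 3), 50)
  expect_equal(high_dose_proportion(fills[2, ], 2016, 3), 0)
  expect_equal(high_dose_proportion(fills[1, ], 2016, 3), 100)
})

test_that("concurrent fills can jointly cross the high-dose threshold", {
  fills <- rbind(
    make_rx(rx_id = "R1", patient_id = "A", drug_code = "MOR_PO",
            start_date = "2016-03-01", days_supplied = 10,
            units_per_day = 2, unit_strength_mg = 30),
    make_rx(rx_id = "R2", patient_id = "A", drug_code = "OXY_PO",
            start_date = "2016-03-08", days_supplied = 10,
            units_per_day = 4, unit_strength_mg = 10)
  )
  # days 8-10: 60 + 60 = 120 >= 100; singly the patient peaks at 60
  expect_equal(high_dose_proportion(fills, 2016, 3), 100)
  expect_equal(high_dose_proportion(fills[1, ], 2016, 3), 0)
})

test_that("a fill spilling in from the previous month raises the dose but not membership", {
  fills <- rbind(
    make_rx(rx_id = "R1", patient_id = "A", drug_code = "MOR_PO",
            start_date = "2016-02-25", days_supplied = 10,
            units_per_day = 2, unit_strength_mg = 30),
    make_rx(rx_id = "R2", patient_id = "A", drug_code = "MOR_PO",
            start_date = "2016-03-01", days_supplied = 10,
            units_per_day = 2, unit_strength_mg = 30)
  )
  # March 1-5: 60 + 60 = 120
  expect_equal(high_dose_proportion(fills, 2016, 3), 100)
  # the February fill alone does not put the patient in March's denominator
  expect_true(is.na(high_dose_proportion(fills[1, ], 2016, 3)))
})

test_that("high-dose proportion is monotone as the threshold decreases", {
  set.seed(5)
  sim <- simulate_claims(synth_config(n_months = 24, interruptions = 13,
                                      true_betas = lapply(
                                        default_true_betas(), function(b) b[1:4]
                                      ),
                                      patients_per_month = 120, seed = 5))
  fills <- sim$prescriptions[sim$prescriptions$drug_code != NALOXONE_CODE, ]
  thresholds <- c(200, 150, 100, 60, 30, 10)
  vals <- vapply(thresholds, function(th) {
    high_dose_proportion(fills, 2016, 4,
                         config = indicator_config(high_dose_mme_threshold = th))
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("multiple-provider counting ignores institutional affiliation", {
  fills <- rbind(
    make_rx(rx_id = "R1", patient_id = "A", provider_id = "D1",
            institution_id = "H1", start_date = "2016-03-02"),
    make_rx(rx_id = "R2", patient_id = "A", provider_id = "D2",
            institution_id = "H1", start_date = "2016-03-20"),
    make_rx(rx_id = "R3", patient_id = "B", provider_id = "D1",
            institution_id = "H1", start_date = "2016-03-05"),
    make_rx(rx_id = "R4", patient_id = "B", provider_id = "D1",
            institution_id = "H2", start_date = "2016-03-21")
  )
  # A: two providers at one institution -> counted; B: one provider at two
  # institutions -> not counted
  expect_equal(multi_provider_proportion(fills, 2016, 3), 50)
  expect_equal(multi_provider_proportion(fills[fills$patient_id == "B", ],
                                         2016, 3), 0)
})

test_that("overlap ratio matches the printed-definition examples", {
  f <- make_rx(rx_id = c("R1", "R2"), patient_id = "A",
               start_date = c("2016-03-01", "2016-03-06"),
               days_supplied = c(10, 10))
  expect_equal(overlap_ratio(f), 5 / 15)
  disjoint <- make_rx(rx_id = c("R1", "R2"), patient_id = "A",
                      start_date = c("2016-03-01", "2016-03-20"),
                      days_supplied = c(5, 5))
  expect_equal(overlap_ratio(disjoint), 0)
  dup <- make_rx(rx_id = c("R1", "R2"), patient_id = "A",
                 start_date = "2016-03-01", days_supplied = 10)
  expect_equal(overlap_ratio(dup), 1)
})

test_that("overlap ratio equals the brute-force per-day coverage oracle", {
  set.seed(33)
  for (rep in 1:60) {
    k <- sample(1:10, 1)
    fills <- make_rx(
      rx_id = paste0("R", 1:k), patient_id = "A",
      start_date = format(as.Date("2016-03-01") + sample(0:59, k, TRUE)),
      days_supplied = sample(1:30, k, TRUE)
    )
    clip <- sample(c(TRUE, FALSE), 1)
    cs <- if (clip) "2016-03-10" else NULL
    ce <- if (clip) "2016-04-20" else NULL
    expect_equal(overlap_ratio(fills, cs, ce), oracle_overlap(fills, cs, ce),
                 info = paste("rep", rep))
  }
})

test_that("monthly overlap rate averages per-patient ratios, with an any-overlap mode", {
  fills <- rbind(
    make_rx(rx_id = c("R1", "R2"), patient_id = "A",
            start_date = "2016-03-01", days_supplied = 10),
    make_rx(rx_id = "R3", patient_id = "B", start_date = "2016-03-01",
            days_supplied = 10)
  )
  expect_equal(overlap_rate_monthly(fills, 2016, 3), 50)
  expect_equal(overlap_rate_monthly(fills, 2016, 3, mode = "any_overlap"), 50)
  expect_equal(overlap_rate_monthly(fills[3, ], 2016, 3), 0)
  # overlap days are clipped to the month
  spill <- make_rx(rx_id = c("R1", "R2"), patient_id = "A",
                   start_date = c("2016-03-25", "2016-03-25"),
                   days_supplied = c(14, 14))
  expect_equal(overlap_rate_monthly(spill, 2016, 3), 100)
})

test_that("naloxone rate counts same-month naloxone among opioid users only", {
  fills <- make_rx(rx_id = c("R1", "R2"), patient_id = c("A", "B"),
                   start_date = "2016-03-02")
  nal <- make_rx(rx_id = c("N1", "N2"), patient_id = c("A", "C"),
                 drug_code = NALOXONE_CODE, start_date = "2016-03-15",
                 days_supplied = 1, unit_strength_mg = 0.4)
  expect_equal(naloxone_rate(fills, nal, 2016, 3), 50)
  # naloxone in a different month is not counted
  nal_apr <- make_rx(rx_id = "N1", patient_id = "A", drug_code = NALOXONE_CODE,
                     start_date = "2016-04-02", days_supplied = 1,
                     unit_strength_mg = 0.4)
  expect_equal(naloxone_rate(fills, nal_apr, 2016, 3), 0)
})

test_that("proportion arithmetic reproduces two-decimal reporting", {
  expect_equal(proportion_pct(1, 800), 0.13)  # 0.125 rounds half-up
  expect_equal(proportion_pct(0, 10), 0)
  expect_true(is.na(proportion_pct(0, 0)))
  expect_equal(proportion_pct(1, 3, digits = NULL), 100 / 3)
})

test_that("the monthly series is gapless, bounded and permutation-invariant", {
  set.seed(9)
  sim <- simulate_claims(synth_config(patients_per_month = 60, seed = 9))
  cohort <- sim_to_cohort(sim)
  series <- build_series(cohort)
  expect_s3_class(series, "indicator_series")
  expect_equal(series$month_index, 1:60)
  expect_equal(series$year[c(1, 60)], c(2016, 2020))
  for (col in c("high_dose", "multi_provider", "naloxone")) {
    v <- series[[paste0(col, "_pct")]]
    expect_true(all(v >= 0 & v <= 100))
    expect_true(all(series[[paste0(col, "_n")]] <= series$n_users))
  }
  expect_true(all(series$overlap_mean_pct >= 0 & series$overlap_mean_pct <= 100))

  shuffled <- cohort
  set.seed(1)
  shuffled$prescriptions <- shuffled$prescriptions[
    sample(nrow(shuffled$prescriptions)), ]
  expect_equal(build_series(shuffled), series)
})

test_that("a month with no opioid users is flagged missing and the run continues", {
  fills <- make_rx(start_date = "2016-03-02")
  expect_warning(series <- build_series(list(prescriptions = fills,
                                             naloxone = fills[0, ])),
                 "no opioid users")
  expect_equal(nrow(series), 60)
  expect_true(is.na(series$high_dose_pct[1]))
  expect_equal(series$n_users[3], 1)
  empty <- expect_warning(build_series(list(prescriptions = fills[0, ],
                                            naloxone = fills[0, ])))
  expect_true(all(is.na(empty$high_dose_pct)))
})
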