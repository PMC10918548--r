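# Small in-code fixtures and independent oracles shared across tests.

make_patients <- function(patient_id = "P1", sex = "female",
                          birth_year = 1971L, insurance = "NHI",
                          diagnoses = "M54") {
  data.frame(
    patient_id = patient_id, sex = sex, birth_year = birth_year,
    insurance = insurance, diagnoses = diagnoses, stringsAsFactors = FALSE
  )
}

make_rx <- function(rx_id = "R1", patient_id = "P1", provider_id = "D1",
                    institution_id = "H1", drug_code = "OXY_PO",
                    start_date = "2016-03-01", days_supplied = 7,
                    units_per_day = 2, unit_strength_mg = 10,
                    setting = "outpatient") {
  data.frame(
    rx_id = rx_id, patient_id = patient_id, provider_id = provider_id,
    institution_id = institution_id, drug_code = drug_code,
    start_date = start_date, days_supplied = days_supplied,
    units_per_day = units_per_day, unit_strength_mg = unit_strength_mg,
    setting = setting, stringsAsFactors = FALSE
  )
}

# brute-force overlap oracle: literal per-day coverage counting
oracle_overlap <- function(fills, clip_start = NULL, clip_end = NULL) {
  counts <- integer(0)
  days_seen <- integer(0)
  for (i in seq_len(nrow(fills))) {
    s <- as.integer(as.Date(fills$start_date[i]))
    e <- s + fills$days_supplied[i] - 1L
    if (!is.null(clip_start)) s <- max(s, as.integer(as.Date(clip_start)))
    if (!is.null(clip_end)) e <- min(e, as.integer(as.Date(clip_end)))
    if (s > e) next
    for (d in s:e) {
      j <- match(d, days_seen)
      if (is.na(j)) {
        days_seen <- c(days_seen, d)
        counts <- c(counts, 1L)
      } else {
        counts[j] <- counts[j] + 1L
      }
    }
  }
  if (length(counts) == 0) return(NA_real_)
  sum(counts >= 2) / length(counts)
}

# independent least-squares oracle: explicit normal equations
oracle_normal_equations <- function(design, y) {
  X <- cbind(1, as.matrix(as.data.frame(design)))
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# stationary AR(1) noise without stats::arima.sim, for independence from
# the generator's own recursion
oracle_ar1_noise <- function(n, rho, sd) {
  z <- rnorm(n)
  e <- numeric(n)
  e[1] <- sd * z[1]
  for (t in seq_len(n)[-1]) e[t] <- rho * e[t - 1] + sd * sqrt(1 - rho^2) * z[t]
  e
}

sim_to_cohort <- function(sim) {
  list(
    prescriptions = sim$prescriptions[sim$prescriptions$drug_code != NALOXONE_CODE, ],
    naloxone = sim$prescriptions[sim$prescriptions$drug_code == NALOXONE_CODE, ]
  )
}
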