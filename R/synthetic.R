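#' Default generating coefficients for the synthetic cohort
#'
#' One six-coefficient vector (intercept, baseline trend, level and trend
#' change at the first interruption, level and trend change at the second)
#' per indicator, on the percentage scale.  The magnitudes mirror the
#' published segmented-regression estimates for the four indicators, so
#' default synthetic series move on a realistic scale (monthly prevalences
#' of roughly 0.3 to 3 percent).
#'
#' @return Named list of numeric vectors of length 6.
#' @export
default_true_betas <- function() {
  list(
    high_dose      = c(0.7947,  0.0040,  0.1743,  0.0271, 0.0484,  0.0309),
    multi_provider = c(0.8141, -0.0076,  0.6252, -0.0067, 0.3969,  0.0323),
    overlap        = c(1.4828, -0.0113,  0.3349,  0.0101, 0.3709, -0.0442),
    naloxone       = c(0.3685,  0.0156, -0.2968, -0.0117, 0.0652, -0.0324)
  )
}

default_demographic_mix <- function() {
  list(
    sex = c(male = 0.391, female = 0.609),
    age_group = c("20-39" = 0.125, "40-59" = 0.331,
                  "60-74" = 0.346, "75+" = 0.198),
    insurance = c(NHI = 0.909, MedAid = 0.081, PVI = 0.010),
    morbidity = c(Arthropathies = 0.261, Dorsopathies = 0.466,
                  "Soft tissue disorders" = 0.261, Others = 0.012)
  )
}

#' Expected monthly indicator values under the segmented model
#'
#' Evaluates the deterministic segmented mean
#' \eqn{\mu_t = X_t \beta} on the study design for a single indicator.
#'
#' @param betas Coefficient vector: length `2 + 2 * length(interruptions)`.
#' @param n_months Series length.
#' @param interruptions 1-based interruption month indices (one or two).
#' @return Numeric vector of length `n_months` (percentage scale).
#' @export
#' @examples
#' segmented_mean(c(5, 0, 0, 0), 24, 13)
segmented_mean <- function(betas, n_months, interruptions) {
  m2 <- if (length(interruptions) >= 2) interruptions[2] else NULL
  design <- build_design(n_months, interruptions[1], m2)
  X <- design_matrix(design)
  if (length(betas) != ncol(X)) {
    stop("betas must have length ", ncol(X), " for ",
         length(interruptions), " interruption(s)")
  }
  drop(X %*% betas)
}

#' Configuration of the synthetic claims generator
#'
#' Describes the study conditions the generator emulates: a 60-month
#' window with interruptions at months 29 and 50, monthly cohorts of
#' roughly 890 opioid-using outpatients (the pre-interruption monthly
#' cohort size implied by the study's period totals), demographic mix
#' matching the published cohort, and monthly indicator prevalences that
#' follow the segmented linear model.
#'
#' At construction the implied monthly expected proportions are checked to
#' lie within `[0, 100]` for every indicator and month.
#'
#' @param n_months Number of months (>= 24 when two interruptions are
#'   requested, so that each evaluated segment has 12 observations).
#' @param interruptions One or two 1-based interruption month indices.
#' @param patients_per_month Cohort patients generated per month.
#' @param true_betas Named list of generating coefficient vectors, one per
#'   indicator (see [default_true_betas()]).
#' @param noise_sd Residual standard deviation(s) in percentage points for
#'   the series-level simulator; a single value or one per indicator.
#' @param ar1_rho First-order autocorrelation of the series-level
#'   residuals, in `[-0.99, 0.99]`.
#' @param demographic_mix Target fractions for sex, age group, insurance
#'   and morbidity class.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_months = 60,
                         interruptions = c(29, 50),
                         patients_per_month = 890,
                         true_betas = default_true_betas(),
                         noise_sd = c(high_dose = 0.25, multi_provider = 0.30,
                                      overlap = 0.30, naloxone = 0.20),
                         ar1_rho = 0.2,
                         demographic_mix = default_demographic_mix(),
                         seed = NULL) {
  if (length(interruptions) < 1 || length(interruptions) > 2) {
    stop("interruptions must contain one or two month indices")
  }
  if (length(interruptions) == 2 && n_months < 24) {
    stop("two interruptions require n_months >= 24 ",
         "(12 months before and after the evaluated intervention)")
  }
  if (abs(ar1_rho) > 0.99) stop("ar1_rho must lie in [-0.99, 0.99]")
  if (patients_per_month < 0) stop("patients_per_month must be non-negative")
  indicators <- names(indicator_columns())
  if (!all(indicators %in% names(true_betas))) {
    stop("true_betas must name all of: ", paste(indicators, collapse = ", "))
  }
  if (length(noise_sd) == 1) {
    noise_sd <- stats::setNames(rep(noise_sd, 4), indicators)
  }
  mu <- lapply(true_betas[indicators], segmented_mean,
               n_months = n_months, interruptions = interruptions)
  for (ind in indicators) {
    if (any(mu[[ind]] < 0 | mu[[ind]] > 100)) {
      stop("expected monthly proportion for '", ind,
           "' leaves [0, 100]; adjust true_betas")
    }
  }
  structure(
    list(
      n_months = n_months,
      interruptions = interruptions,
      patients_per_month = patients_per_month,
      true_betas = true_betas[indicators],
      noise_sd = noise_sd[indicators],
      ar1_rho = ar1_rho,
      demographic_mix = demographic_mix,
      seed = seed,
      mu = mu,
      grid = month_grid("2016-01", n_months)
    ),
    class = "synth_config"
  )
}

#' Simulate a monthly indicator series
#'
#' Series-level tier of the generator: the deterministic segmented mean
#' plus stationary Gaussian AR(1) noise
#' (\eqn{e_1 \sim N(0, \sigma^2)},
#' \eqn{e_t = \rho e_{t-1} + \sigma\sqrt{1-\rho^2} z_t}), so the marginal
#' residual standard deviation equals `noise_sd` at every month.  The same
#' seed always reproduces the same series.
#'
#' @param config A [synth_config()].
#' @param indicator One of `"high_dose"`, `"multi_provider"`, `"overlap"`,
#'   `"naloxone"`.
#' @return Data frame with `month_index`, `year`, `month`, `value` and the
#'   attribute `mu` (the noiseless mean).
#' @export
#' @examples
#' s <- simulate_series(synth_config(seed = 7), "high_dose")
#' head(s)
simulate_series <- function(config, indicator = "high_dose") {
  stopifnot(inherits(config, "synth_config"))
  indicator <- match.arg(indicator, names(indicator_columns()))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_months
  mu <- config$mu[[indicator]]
  sd <- config$noise_sd[[indicator]]
  rho <- config$ar1_rho
  z <- stats::rnorm(n)
  e <- numeric(n)
  e[1] <- sd * z[1]
  if (n > 1) {
    w <- sd * sqrt(1 - rho^2)
    for (t in 2:n) e[t] <- rho * e[t - 1] + w * z[t]
  }
  out <- data.frame(
    month_index = config$grid$month_index,
    year = config$grid$year,
    month = config$grid$month,
    value = mu + e
  )
  attr(out, "mu") <- mu
  out
}

# dosing menus: (drug_code, unit_strength_mg, units_per_day) rows.
# "low" fills stay at <= 40 MME/day so that even two concurrent low fills
# (80 MME) cannot cross the 100-MME high-dose threshold; "high" fills are
# engineered to >= 120 MME/day on their own.
low_dose_menu <- function() {
  data.frame(
    drug_code = c("MOR_PO", "OXY_PO", "COD_PO", "TAP_PO", "HCO_PO",
                  "DHC_PO", "HMO_PO"),
    unit_strength_mg = c(10, 5, 30, 50, 10, 30, 2),
    units_per_day = c(2, 2, 4, 2, 3, 4, 2)
  )
}

high_dose_menu <- function() {
  data.frame(
    drug_code = c("MOR_PO", "OXY_PO", "FEN_TD", "HMO_PO"),
    unit_strength_mg = c(30, 40, 50, 8),
    units_per_day = c(4, 2, 1, 4)
  )
}

sample_mix <- function(mix, n) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

sample_dx <- function(classes) {
  pools <- list(
    "Arthropathies" = 0:25,
    "Dorsopathies" = 40:54,
    "Soft tissue disorders" = 60:79,
    "Others" = c(26:39, 80:99)
  )
  num <- integer(length(classes))
  for (cls in names(pools)) {
    idx <- which(classes == cls)
    if (length(idx) > 0) {
      num[idx] <- sample(pools[[cls]], length(idx), replace = TRUE)
    }
  }
  sprintf("M%02d", num)
}

#' Simulate record-level claims
#'
#' Record-level tier of the generator.  Per month it creates
#' `patients_per_month` opioid-using cohort patients (valid demographics
#' and one chapter-M diagnosis drawn from `demographic_mix`), each with a
#' baseline low-dose opioid fill, and then plants the four misuse
#' behaviours with independent Bernoulli draws at the month's expected
#' indicator prevalence from the segmented model:
#'
#' * high dose: the baseline fill is replaced by one dosed at
#'   120+ MME/day (all other patients stay at or below 40 MME/day per
#'   fill, so at most 80 MME/day even with two concurrent fills);
#' * overlap: an exact duplicate of the baseline fill is added (every
#'   covered day double-covered);
#' * multiple providers: a second, day-disjoint fill from a different
#'   prescriber is added;
#' * naloxone: one naloxone record (reserved drug code) in the month.
#'
#' Noise therefore arises from binomial sampling, not from the Gaussian
#' AR(1) of the series tier.  All records pass [read_claims()] validation
#' and [select_cohort()] unchanged.  Patient identifiers are month-scoped,
#' so each monthly cohort is independent.
#'
#' @param config A [synth_config()].
#' @return List with data frames `patients` and `prescriptions`, and
#'   `truth`: the generator parameters plus the planted per-month
#'   numerators (`month_index`, `n_users`, `high_dose_n`,
#'   `multi_provider_n`, `overlap_n`, `naloxone_n`).
#' @export
#' @examples
#' sim <- simulate_claims(synth_config(patients_per_month = 50, seed = 1))
#' head(sim$truth$planted)
simulate_claims <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ppm <- config$patients_per_month
  n_months <- config$n_months
  grid <- config$grid
  mix <- config$demographic_mix
  N <- ppm * n_months

  empty_patients <- data.frame(
    patient_id = character(), sex = character(),
    birth_year = integer(), insurance = character(),
    diagnoses = character(), stringsAsFactors = FALSE
  )
  empty_rx <- data.frame(
    rx_id = character(), patient_id = character(), provider_id = character(),
    institution_id = character(), drug_code = character(),
    start_date = character(), days_supplied = numeric(),
    units_per_day = numeric(), unit_strength_mg = numeric(),
    setting = character(), stringsAsFactors = FALSE
  )
  planted_empty <- data.frame(
    month_index = grid$month_index, n_users = 0L, high_dose_n = 0L,
    multi_provider_n = 0L, overlap_n = 0L, naloxone_n = 0L
  )
  truth <- list(
    n_months = n_months,
    interruptions = config$interruptions,
    patients_per_month = ppm,
    true_betas = config$true_betas,
    seed = config$seed,
    planted = planted_empty
  )
  if (N == 0) {
    return(list(patients = empty_patients, prescriptions = empty_rx,
                truth = truth))
  }

  month <- rep(grid$month_index, each = ppm)
  year <- grid$year[month]
  cal_month <- grid$month[month]
  pid <- sprintf("P%02d_%05d", month, rep(seq_len(ppm), times = n_months))

  sex <- sample_mix(mix$sex, N)
  age_group <- sample_mix(mix$age_group, N)
  age_lo <- c("20-39" = 20, "40-59" = 40, "60-74" = 60, "75+" = 75)[age_group]
  age_hi <- c("20-39" = 39, "40-59" = 59, "60-74" = 74, "75+" = 94)[age_group]
  age <- age_lo + floor(stats::runif(N) * (age_hi - age_lo + 1))
  birth_year <- year - age
  insurance <- sample_mix(mix$insurance, N)
  morb <- sample_mix(mix$morbidity, N)
  diagnoses <- sample_dx(morb)

  patients <- data.frame(
    patient_id = pid, sex = sex, birth_year = as.integer(birth_year),
    insurance = insurance, diagnoses = diagnoses, stringsAsFactors = FALSE
  )

  # planted behaviours: independent Bernoulli at the month's expected
  # prevalence under the segmented model
  prob_of <- function(ind) pmin(1, pmax(0, config$mu[[ind]][month] / 100))
  hd <- stats::rbinom(N, 1, prob_of("high_dose")) == 1
  mp <- stats::rbinom(N, 1, prob_of("multi_provider")) == 1
  ov <- stats::rbinom(N, 1, prob_of("overlap")) == 1
  nx <- stats::rbinom(N, 1, prob_of("naloxone")) == 1

  low <- low_dose_menu()
  high <- high_dose_menu()
  base_menu_i <- sample(nrow(low), N, replace = TRUE)
  base <- low[base_menu_i, , drop = FALSE]
  hi_i <- sample(nrow(high), sum(hd), replace = TRUE)
  base[hd, ] <- high[hi_i, , drop = FALSE]

  provider_num <- sample(3000L, N, replace = TRUE)
  provider <- sprintf("D%04d", provider_num)
  provider2 <- sprintf("D%04d", provider_num %% 3000L + 1L)
  institution <- sprintf("H%03d", sample(400L, N, replace = TRUE))

  m_start <- month_start(year, cal_month)
  # baseline fill on days 1..12 of the month; the disjoint second-provider
  # fill on days 15..26 (every month has >= 28 days)
  base_start <- m_start + sample(0:2, N, replace = TRUE)
  base_days <- sample(5:10, N, replace = TRUE)

  mk_rx <- function(pid, provider, institution, drug, start, days, upd, mg) {
    data.frame(
      rx_id = NA_character_, patient_id = pid, provider_id = provider,
      institution_id = institution, drug_code = drug,
      start_date = format(start, "%Y-%m-%d"), days_supplied = days,
      units_per_day = upd, unit_strength_mg = mg,
      setting = "outpatient", stringsAsFactors = FALSE
    )
  }

  rx <- list(
    mk_rx(pid, provider, institution, base$drug_code, base_start, base_days,
          base$units_per_day, base$unit_strength_mg)
  )
  if (any(ov)) {
    rx$dup <- mk_rx(pid[ov], provider[ov], institution[ov],
                    base$drug_code[ov], base_start[ov], base_days[ov],
                    base$units_per_day[ov], base$unit_strength_mg[ov])
  }
  if (any(mp)) {
    n_mp <- sum(mp)
    mp_menu <- low[sample(nrow(low), n_mp, replace = TRUE), , drop = FALSE]
    mp_start <- m_start[mp] + 14L + sample(0:3, n_mp, replace = TRUE)
    mp_days <- sample(5:9, n_mp, replace = TRUE)
    rx$mp <- mk_rx(pid[mp], provider2[mp], institution[mp],
                   mp_menu$drug_code, mp_start, mp_days,
                   mp_menu$units_per_day, mp_menu$unit_strength_mg)
  }
  if (any(nx)) {
    n_nx <- sum(nx)
    nx_start <- m_start[nx] + sample(0:27, n_nx, replace = TRUE)
    rx$nx <- mk_rx(pid[nx], provider[nx], institution[nx],
                   NALOXONE_CODE, nx_start, 1L, 1, 0.4)
  }
  prescriptions <- do.call(rbind, rx)
  prescriptions$rx_id <- sprintf("R%07d", seq_len(nrow(prescriptions)))
  rownames(prescriptions) <- NULL

  agg <- function(flag) as.integer(rowsum(as.integer(flag), month)[, 1])
  truth$planted <- data.frame(
    month_index = grid$month_index,
    n_users = as.integer(rowsum(rep(1L, N), month)[, 1]),
    high_dose_n = agg(hd),
    multi_provider_n = agg(mp),
    overlap_n = agg(ov),
    naloxone_n = agg(nx)
  )
  list(patients = patients, prescriptions = prescriptions, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Writes `patients.csv`, `prescriptions.csv` and `truth.json` (the
#' generating parameters and planted monthly numerators) to a directory.
#'
#' @param sim Result of [simulate_claims()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_claims(sim, file.path(dir, "patients.csv"),
               file.path(dir, "prescriptions.csv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
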