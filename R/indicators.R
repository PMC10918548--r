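#' Indicator configuration
#'
#' Parameters of the four monthly misuse indicators.
#'
#' @param high_dose_mme_threshold Daily morphine-milligram-equivalent dose
#'   at or above which a patient counts as on high-dose treatment
#'   (default 100 MME/day, threshold inclusive).
#' @param multi_provider_min Minimum number of distinct prescribers in a
#'   month for the multiple-provider indicator (default 2).
#' @param high_dose_mode How a patient's month is summarized before the
#'   threshold comparison: `"max"` (default, the strictest day of the
#'   month) or `"mean"` (average over the patient's covered days).
#' @param grid Month grid ([month_grid()]); defaults to the 60-month
#'   January 2016 -- December 2020 study window.
#' @return An object of class `indicator_config`.
#' @export
indicator_config <- function(high_dose_mme_threshold = 100,
                             multi_provider_min = 2,
                             high_dose_mode = c("max", "mean"),
                             grid = month_grid()) {
  if (high_dose_mme_threshold <= 0) stop("high_dose_mme_threshold must be positive")
  if (multi_provider_min < 2) stop("multi_provider_min must be at least 2")
  structure(
    list(
      high_dose_mme_threshold = high_dose_mme_threshold,
      multi_provider_min = multi_provider_min,
      high_dose_mode = match.arg(high_dose_mode),
      grid = grid
    ),
    class = "indicator_config"
  )
}

#' Percentage from a numerator/denominator pair
#'
#' `100 * numerator / denominator`, optionally rounded half-up to the
#' reporting precision (2 decimal places, the convention used in the
#' result tables).  Returns `NA` when the denominator is zero.
#'
#' @param numerator,denominator Non-negative counts.
#' @param digits Decimal places for half-up rounding; `NULL` leaves the
#'   value unrounded.
#' @return Percentage value(s).
#' @export
#' @examples
#' proportion_pct(187, 24924)
proportion_pct <- function(numerator, denominator, digits = 2) {
  pct <- 100 * numerator / denominator
  pct[!is.finite(pct)] <- NA_real_
  if (!is.null(digits)) {
    scale <- 10^digits
    pct <- sign(pct) * floor(abs(pct) * scale + 0.5) / scale
  }
  pct
}

fill_daily_mme <- function(fills, catalog) {
  i <- match(fills$drug_code, catalog$drug_code)
  if (anyNA(i)) {
    stop("unknown drug_code '", fills$drug_code[which(is.na(i))[1]],
         "' (not an opioid in the catalog)")
  }
  fills$units_per_day * fills$unit_strength_mg * catalog$mme_factor[i]
}

#' Daily morphine milligram equivalents for one patient
#'
#' Total MME/day over the fills of a single patient that are active on a
#' given day: the sum over active fills of
#' `units_per_day * unit_strength_mg * mme_factor`.  A fill is active on
#' the closed day range `[start_date, start_date + days_supplied - 1]`.
#'
#' @param fills Prescription rows of one patient (opioids only).
#' @param day The day to evaluate (date or "YYYY-MM-DD").
#' @param catalog Opioid catalog.
#' @return Total MME/day (0 when no fill is active).
#' @export
#' @examples
#' fills <- data.frame(
#'   drug_code = "MOR_PO", start_date = "2016-03-01", days_supplied = 10,
#'   units_per_day = 2, unit_strength_mg = 30
#' )
#' daily_mme(fills, "2016-03-05")  # 60 MME/day
daily_mme <- function(fills, day, catalog = default_opioid_catalog()) {
  day <- as.Date(day)
  start <- as.Date(fills$start_date)
  end <- start + fills$days_supplied - 1
  active <- start <= day & day <= end
  sum(fill_daily_mme(fills[active, , drop = FALSE], catalog))
}

# Pre-parses the claims columns the monthly workhorse needs (dates as
# integer day numbers, MME per fill) so build_series converts them once,
# not once per month.
prep_indicator_inputs <- function(fills, naloxone, catalog) {
  start <- as.integer(as.Date(fills$start_date))
  list(
    pid = fills$patient_id,
    provider = fills$provider_id,
    start = start,
    end = start + as.integer(fills$days_supplied) - 1L,
    mme = fill_daily_mme(fills, catalog),
    nx_pid = if (is.null(naloxone)) character(0) else naloxone$patient_id,
    nx_day = if (is.null(naloxone)) integer(0) else
      as.integer(as.Date(naloxone$start_date))
  )
}

# Per-month workhorse: expands the active fills of the month's opioid
# users into (patient, day) contributions and derives all four indicator
# numerators at once.  `ms`/`me` are the month's first and last day as
# integer day numbers.
month_slice_stats_prepared <- function(prep, ms, me, config) {
  starts_in <- prep$start >= ms & prep$start <= me
  users <- unique(prep$pid[starts_in])
  n_users <- length(users)
  out <- list(
    n_users = n_users, high_dose_n = NA_integer_,
    multi_provider_n = NA_integer_, overlap_mean_ratio = NA_real_,
    overlap_any_n = NA_integer_, naloxone_n = NA_integer_
  )
  if (n_users == 0) return(out)

  pidx <- match(prep$pid, users)
  active <- !is.na(pidx) & prep$start <= me & prep$end >= ms
  d0 <- pmax(prep$start[active], ms)
  d1 <- pmin(prep$end[active], me)
  len <- d1 - d0 + 1L
  # (patient, day) keys: day offset within the month occupies 5 bits
  upid <- rep(pidx[active], len)
  uday <- rep(d0 - ms, len) + sequence(len) - 1L
  key <- upid * 32L + uday
  tot <- rowsum(rep(prep$mme[active], len), key)      # MME per patient-day
  n_fills_day <- rowsum(rep(1L, length(key)), key)    # concurrent fills
  key_pidx <- as.integer(rownames(tot)) %/% 32L

  thr <- config$high_dose_mme_threshold
  if (config$high_dose_mode == "max") {
    out$high_dose_n <- length(unique(key_pidx[tot[, 1] >= thr]))
  } else {
    mean_dose <- rowsum(tot[, 1], key_pidx) /
      tabulate(key_pidx, nbins = n_users)[sort(unique(key_pidx))]
    out$high_dose_n <- sum(mean_dose >= thr)
  }

  covered <- tabulate(key_pidx, nbins = n_users)
  doubled <- tabulate(key_pidx[n_fills_day[, 1] >= 2L], nbins = n_users)
  ratio <- doubled / covered
  out$overlap_mean_ratio <- mean(ratio)
  out$overlap_any_n <- sum(ratio > 0)

  sidx <- which(starts_in)
  prov_key <- pidx[sidx] * 1e6 + as.integer(factor(prep$provider[sidx]))
  first <- !duplicated(prov_key)
  out$multi_provider_n <-
    sum(tabulate(pidx[sidx][first], nbins = n_users) >=
          config$multi_provider_min)

  nx_pidx <- match(prep$nx_pid, users)
  nx_in <- !is.na(nx_pidx) & prep$nx_day >= ms & prep$nx_day <= me
  out$naloxone_n <- length(unique(nx_pidx[nx_in]))
  out
}

month_slice_stats <- function(fills, naloxone, ms, me, config, catalog) {
  prep <- prep_indicator_inputs(fills, naloxone, catalog)
  month_slice_stats_prepared(prep, as.integer(ms), as.integer(me), config)
}

#' Proportion of patients on high-dose opioid treatment in a month
#'
#' Denominator: patients with at least one opioid fill starting in the
#' month.  Numerator: those whose summed daily MME, summarized over the
#' days of the month (maximum by default), reaches the threshold.  Fills
#' spilling in from earlier months contribute to the daily dose but not to
#' month membership.
#'
#' @param fills Cohort opioid fills.
#' @param year,month Calendar month to evaluate.
#' @param config [indicator_config()].
#' @param catalog Opioid catalog.
#' @return Percentage (unrounded), `NA` when the month has no opioid
#'   users.
#' @export
high_dose_proportion <- function(fills, year, month,
                                 config = indicator_config(),
                                 catalog = default_opioid_catalog()) {
  s <- month_slice_stats(fills, NULL, month_start(year, month),
                         month_end(year, month), config, catalog)
  proportion_pct(s$high_dose_n, s$n_users, digits = NULL)
}

#' Proportion of patients with opioid fills from multiple providers
#'
#' Numerator: patients whose opioid fills starting in the month carry at
#' least `multi_provider_min` distinct `provider_id` values, irrespective
#' of the providers' institutional affiliation.
#'
#' @inheritParams high_dose_proportion
#' @return Percentage (unrounded), `NA` when the month has no users.
#' @export
multi_provider_proportion <- function(fills, year, month,
                                      config = indicator_config(),
                                      catalog = default_opioid_catalog()) {
  s <- month_slice_stats(fills, NULL, month_start(year, month),
                         month_end(year, month), config, catalog)
  proportion_pct(s$multi_provider_n, s$n_users, digits = NULL)
}

#' Prescription overlap ratio for one patient
#'
#' Over one patient's opioid fill day ranges (optionally clipped to a
#' window): the number of days covered by two or more fills divided by the
#' number of days covered by at least one fill.
#'
#' @param fills Opioid fills of a single patient.
#' @param clip_start,clip_end Optional window (e.g. month bounds) to clip
#'   the fill intervals to.
#' @return Ratio in `[0, 1]` (`NA` if no covered day remains after
#'   clipping).
#' @export
#' @examples
#' fills <- data.frame(
#'   start_date = c("2016-03-01", "2016-03-06"), days_supplied = c(10, 10)
#' )
#' overlap_ratio(fills)  # 5 shared days / 15 covered days
overlap_ratio <- function(fills, clip_start = NULL, clip_end = NULL) {
  start <- as.Date(fills$start_date)
  end <- start + fills$days_supplied - 1
  if (!is.null(clip_start)) start <- pmax(start, as.Date(clip_start))
  if (!is.null(clip_end)) end <- pmin(end, as.Date(clip_end))
  keep <- start <= end
  if (!any(keep)) return(NA_real_)
  d0 <- as.integer(start[keep])
  d1 <- as.integer(end[keep])
  len <- d1 - d0 + 1L
  day <- rep(d0, len) + sequence(len) - 1L
  cnt <- tabulate(day - min(day) + 1L)
  sum(cnt >= 2L) / sum(cnt >= 1L)
}

#' Monthly overlap rate of opioid prescriptions per patient
#'
#' Primary mode (`"mean_ratio"`): the mean of per-patient
#' [overlap_ratio()] values (clipped to the month) across the month's
#' opioid users, times 100.  Secondary mode (`"any_overlap"`): the
#' percentage of the month's users with any overlapping day, which matches
#' the numerator/denominator presentation used in period summaries.
#'
#' @inheritParams high_dose_proportion
#' @param mode `"mean_ratio"` (default) or `"any_overlap"`.
#' @return Percentage (unrounded), `NA` when the month has no users.
#' @export
overlap_rate_monthly <- function(fills, year, month,
                                 mode = c("mean_ratio", "any_overlap"),
                                 config = indicator_config(),
                                 catalog = default_opioid_catalog()) {
  mode <- match.arg(mode)
  s <- month_slice_stats(fills, NULL, month_start(year, month),
                         month_end(year, month), config, catalog)
  if (s$n_users == 0) return(NA_real_)
  if (mode == "mean_ratio") {
    100 * s$overlap_mean_ratio
  } else {
    proportion_pct(s$overlap_any_n, s$n_users, digits = NULL)
  }
}

#' Monthly naloxone use rate among opioid users
#'
#' Numerator: the month's opioid users with at least one naloxone record
#' in the same month; denominator as in [high_dose_proportion()].
#'
#' @inheritParams high_dose_proportion
#' @param naloxone Naloxone records (reserved drug code) of cohort
#'   patients.
#' @return Percentage (unrounded), `NA` when the month has no users.
#' @export
naloxone_rate <- function(fills, naloxone, year, month,
                          config = indicator_config(),
                          catalog = default_opioid_catalog()) {
  s <- month_slice_stats(fills, naloxone, month_start(year, month),
                         month_end(year, month), config, catalog)
  proportion_pct(s$naloxone_n, s$n_users, digits = NULL)
}

#' Build the monthly indicator series
#'
#' Computes all four indicators for every month of the configured grid
#' from a selected cohort, yielding the gapless monthly series the
#' segmented regression consumes.  Values are kept at full precision;
#' rounding happens only in reporting.  A month with no opioid users
#' yields flagged missing values and a warning, and the run continues.
#'
#' @param cohort List as returned by [select_cohort()] (components
#'   `prescriptions` and `naloxone`), or a data frame of opioid fills.
#' @param config [indicator_config()].
#' @param catalog Opioid catalog.
#' @return Data frame of class `indicator_series`: one row per month with
#'   `month_index`, `year`, `month`, `n_users`, numerator and percentage
#'   columns for the four indicators (`high_dose_*`, `multi_provider_*`,
#'   `overlap_mean_pct` plus `overlap_any_*`, `naloxone_*`).
#' @export
build_series <- function(cohort, config = indicator_config(),
                         catalog = default_opioid_catalog()) {
  if (is.data.frame(cohort)) {
    cohort <- list(prescriptions = cohort,
                   naloxone = cohort[0, , drop = FALSE])
  }
  fills <- cohort$prescriptions
  naloxone <- cohort$naloxone
  grid <- config$grid
  prep <- prep_indicator_inputs(fills, naloxone, catalog)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- month_slice_stats_prepared(
      prep,
      as.integer(month_start(grid$year[i], grid$month[i])),
      as.integer(month_end(grid$year[i], grid$month[i])),
      config
    )
    data.frame(
      month_index = grid$month_index[i],
      year = grid$year[i],
      month = grid$month[i],
      n_users = s$n_users,
      high_dose_n = s$high_dose_n,
      high_dose_pct = proportion_pct(s$high_dose_n, s$n_users, digits = NULL),
      multi_provider_n = s$multi_provider_n,
      multi_provider_pct = proportion_pct(s$multi_provider_n, s$n_users,
                                          digits = NULL),
      overlap_mean_pct = ifelse(s$n_users > 0,
                                100 * s$overlap_mean_ratio, NA_real_),
      overlap_any_n = s$overlap_any_n,
      overlap_any_pct = proportion_pct(s$overlap_any_n, s$n_users,
                                       digits = NULL),
      naloxone_n = s$naloxone_n,
      naloxone_pct = proportion_pct(s$naloxone_n, s$n_users, digits = NULL)
    )
  })
  series <- do.call(rbind, rows)
  if (any(series$n_users == 0)) {
    warning(sum(series$n_users == 0),
            " month(s) with no opioid users; values flagged missing")
  }
  class(series) <- c("indicator_series", "data.frame")
  series
}

#' Names of the four indicator series columns
#'
#' Maps indicator identifiers to the percentage columns of an
#' [build_series()] result.
#'
#' @return Named character vector.
#' @export
indicator_columns <- function() {
  c(
    high_dose = "high_dose_pct",
    multi_provider = "multi_provider_pct",
    overlap = "overlap_mean_pct",
    naloxone = "naloxone_pct"
  )
}
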