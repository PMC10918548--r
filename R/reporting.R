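#' Study period definition
#'
#' Splits the monthly grid into labeled periods at the interruption
#' months.  The default reproduces the study layout: pre-intervention
#' (months 1--28, January 2016 -- April 2018), post-intervention
#' pre-outbreak (29--49, May 2018 -- January 2020) and post-outbreak
#' (50--60, February -- December 2020).  The interruption month itself
#' opens its period.
#'
#' @param interruptions 1-based interruption month indices.
#' @param n_months Series length.
#' @param labels Period labels (length `length(interruptions) + 1`).
#' @return Data frame with `label`, `start_index`, `end_index`, `months`.
#' @export
#' @examples
#' period_definition()
period_definition <- function(interruptions = c(29, 50), n_months = 60,
                              labels = NULL) {
  k <- length(interruptions)
  if (is.null(labels)) {
    labels <- if (k == 2) {
      c("Pre-NIMS", "Post-NIMS pre-COVID-19", "Post-COVID-19")
    } else if (k == 1) {
      c("Pre-intervention", "Post-intervention")
    } else {
      paste("Period", seq_len(k + 1))
    }
  }
  if (length(labels) != k + 1) stop("need one label per period")
  start <- c(1L, as.integer(interruptions))
  end <- c(as.integer(interruptions) - 1L, n_months)
  if (any(end < start)) stop("interruptions must be increasing and within the grid")
  data.frame(
    label = labels,
    start_index = start,
    end_index = end,
    months = end - start + 1L
  )
}

period_of_month <- function(month_index, periods) {
  lab <- rep(NA_character_, length(month_index))
  for (i in seq_len(nrow(periods))) {
    sel <- month_index >= periods$start_index[i] &
      month_index <= periods$end_index[i]
    lab[sel] <- periods$label[i]
  }
  factor(lab, levels = periods$label)
}

count_block <- function(values, block) {
  tab <- table(values)
  data.frame(
    block = block,
    level = names(tab),
    n = as.integer(tab),
    pct = proportion_pct(as.integer(tab), sum(tab), digits = 1),
    stringsAsFactors = FALSE
  )
}

#' Cohort and outcome summary table
#'
#' Builds the study-style population summary: counts and percentages by
#' sex, age group, insurance (NHI versus MedAid-or-PVI, the two public
#' programs pooled as in the study), and musculoskeletal morbidity class
#' -- per period of first opioid fill and in total -- together with the
#' per-period outcome summaries, both as mean (SD) of the monthly
#' percentages and as pooled month-summed numerator/denominator
#' proportions (the two presentations used in published period tables).
#'
#' @param cohort A [select_cohort()] result.
#' @param series An [build_series()] result.
#' @param periods A [period_definition()] data frame.
#' @param grid Month grid matching the series.
#' @return List of two data frames: `characteristics` (`period`, `block`,
#'   `level`, `n`, `pct`) and `outcomes` (`indicator`, `period`,
#'   `mean_monthly`, `sd_monthly`, `pooled_n`, `pooled_total`,
#'   `pooled_pct`).
#' @export
make_table1 <- function(cohort, series, periods = period_definition(),
                        grid = month_grid()) {
  fills <- cohort$prescriptions
  patients <- cohort$patients
  first_midx <- vapply(
    split(month_index_of(fills$start_date, grid), fills$patient_id),
    min, numeric(1)
  )
  midx <- first_midx[patients$patient_id]
  period <- period_of_month(midx, periods)
  ref_year <- grid$year[midx]

  one_period <- function(sel, label) {
    p <- patients[sel, , drop = FALSE]
    ins <- ifelse(p$insurance == "NHI", "NHI", "MedAid or PVI")
    ins <- factor(ins, levels = c("NHI", "MedAid or PVI"))
    blocks <- rbind(
      count_block(factor(p$sex, levels = c("male", "female")), "Sex"),
      count_block(assign_age_group(p$birth_year, ref_year[sel]), "Age group"),
      count_block(ins, "Insurance type"),
      count_block(morbidity_class(p$diagnoses), "Morbidity")
    )
    cbind(period = label, blocks)
  }

  chars <- rbind(
    one_period(rep(TRUE, nrow(patients)), "Total"),
    do.call(rbind, lapply(levels(period), function(lb) {
      one_period(!is.na(period) & period == lb, lb)
    }))
  )
  rownames(chars) <- NULL

  num_cols <- c(high_dose = "high_dose_n", multi_provider = "multi_provider_n",
                overlap = "overlap_any_n", naloxone = "naloxone_n")
  pct_cols <- indicator_columns()
  series_period <- period_of_month(series$month_index, periods)
  outcomes <- do.call(rbind, lapply(names(pct_cols), function(ind) {
    do.call(rbind, lapply(levels(series_period), function(lb) {
      s <- series[series_period == lb, , drop = FALSE]
      vals <- s[[pct_cols[ind]]]
      data.frame(
        indicator = ind,
        period = lb,
        mean_monthly = mean(vals, na.rm = TRUE),
        sd_monthly = stats::sd(vals, na.rm = TRUE),
        pooled_n = sum(s[[num_cols[ind]]], na.rm = TRUE),
        pooled_total = sum(s$n_users),
        pooled_pct = proportion_pct(sum(s[[num_cols[ind]]], na.rm = TRUE),
                                    sum(s$n_users)),
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(outcomes) <- NULL
  list(characteristics = chars, outcomes = outcomes)
}

TERM_LABELS <- c(
  intercept = "Intercept (b0)",
  time = "Baseline trend (b1)",
  nims = "Level change after NIMS (b2)",
  time_after_nims = "Trend change after NIMS (b3)",
  covid = "Level change after COVID-19 (b4)",
  time_after_covid = "Trend change after COVID-19 (b5)"
)

#' Coefficient table for the fitted outcomes
#'
#' Stacks the segmented-regression coefficients of one fit per outcome
#' into the published layout: one labeled row per coefficient with its
#' p-value, plus the per-outcome Durbin-Watson statistic of the OLS
#' residuals and the estimator actually used.  Estimates are reported to
#' 4 decimal places in `estimate_4dp`; unrounded values stay in
#' `estimate`.
#'
#' @param fits Named list of `its_fit` objects (one per outcome).
#' @return Data frame with `outcome`, `term`, `label`, `estimate`,
#'   `estimate_4dp`, `p_value`, `p_formatted`, `dw`, `estimator`.
#' @export
make_table2 <- function(fits) {
  stopifnot(length(fits) > 0, !is.null(names(fits)))
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    co <- f$coefficients
    data.frame(
      outcome = nm,
      term = co$term,
      label = unname(TERM_LABELS[co$term]),
      estimate = co$estimate,
      estimate_4dp = sprintf("%.4f", co$estimate),
      p_value = co$p_value,
      p_formatted = format_p(co$p_value),
      dw = f$dw,
      estimator = f$estimator,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Four-panel interrupted time-series figure
#'
#' Observed monthly indicator values (solid line and points), fitted
#' segment means, and dot-dash counterfactual extensions of each
#' pre-interruption model, with vertical markers at the interruption
#' months; one panel per indicator.  Months with missing values are left
#' as gaps.
#'
#' @param series An [build_series()] result.
#' @param fits Named list of `its_fit` objects keyed by indicator
#'   (see [indicator_columns()]).
#' @param path Optional output file (`.png` or `.pdf`); when given, the
#'   figure is also written there.
#' @return The ggplot object, invisibly when `path` is given.
#' @export
plot_series <- function(series, fits, path = NULL) {
  cols <- indicator_columns()
  fits <- fits[intersect(names(cols), names(fits))]
  panels <- do.call(rbind, lapply(names(fits), function(ind) {
    f <- fits[[ind]]
    pl <- predict_lines(f)
    obs <- series[[cols[ind]]][f$t_index]
    df <- data.frame(indicator = ind, time = pl$time, observed = NA_real_,
                     fitted = pl$fitted,
                     counterfactual_baseline = pl$counterfactual_baseline)
    df$observed[match(f$t_index, pl$time)] <- obs
    df$counterfactual_pre_second <-
      if ("counterfactual_pre_second" %in% names(pl)) {
        pl$counterfactual_pre_second
      } else {
        NA_real_
      }
    df
  }))
  m1 <- fits[[1]]$m1
  m2 <- fits[[1]]$m2
  p <- ggplot2::ggplot(panels, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_vline(xintercept = m1 - 0.5, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "#2166ac",
                       na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "#2166ac",
                        size = 0.7, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "black") +
    ggplot2::geom_line(ggplot2::aes(y = .data$counterfactual_baseline),
                       linetype = "dotdash", colour = "#e08214") +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(x = "Month", y = "Percentage of opioid users") +
    ggplot2::theme_bw()
  if (!is.null(m2)) {
    p <- p +
      ggplot2::geom_vline(xintercept = m2 - 0.5, linetype = "dashed",
                          colour = "grey40") +
      ggplot2::geom_line(ggplot2::aes(y = .data$counterfactual_pre_second),
                         linetype = "dotdash", colour = "#1b7837",
                         na.rm = TRUE)
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 9, height = 6, dpi = 150)
    return(invisible(p))
  }
  p
}

fit_to_list <- function(f) {
  list(
    estimator = f$estimator,
    coefficients = f$coefficients,
    rho = f$rho,
    sigma = f$sigma,
    dw = f$dw,
    dw_p = f$dw_p,
    loglik = f$loglik,
    n = f$n,
    m1 = f$m1,
    m2 = f$m2
  )
}

#' Run the full synthetic-claims pipeline
#'
#' Orchestrates simulate -> cohort selection -> monthly indicators ->
#' one segmented fit per indicator -> tables and figure, writing all
#' artifacts plus a reproducibility manifest to `outdir`.  Outputs are
#' staged and moved into place only on success, so a failing stage leaves
#' no partial outputs.
#'
#' @param config A YAML file path or a list with (at least)
#'   `interruptions`; optional `n_months`, `patients_per_month`, `seed`,
#'   `alpha`, `estimator`, `ar1_rho`, `noise_sd`, `true_betas`.
#' @param outdir Output directory.
#' @return Invisibly, a list with the cohort, series, fits, tables and the
#'   output paths.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$interruptions) || length(config$interruptions) < 1) {
    stop("config validation: 'interruptions' (month indices) is required")
  }
  cfg_defaults <- list(n_months = 60, patients_per_month = 890, seed = 1,
                       alpha = 0.05, estimator = "auto")
  config <- utils::modifyList(cfg_defaults, config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sc_args <- config[intersect(
    names(config),
    c("n_months", "interruptions", "patients_per_month", "true_betas",
      "noise_sd", "ar1_rho", "seed")
  )]
  scfg <- stage("config", do.call(synth_config, sc_args))

  sim <- stage("simulate", simulate_claims(scfg))
  criteria <- cohort_criteria(
    study_start = month_start(scfg$grid$year[1], scfg$grid$month[1]),
    study_end = month_end(scfg$grid$year[scfg$n_months],
                          scfg$grid$month[scfg$n_months])
  )
  cohort <- stage("cohort", select_cohort(sim$patients, sim$prescriptions,
                                          criteria, quiet = TRUE))
  icfg <- indicator_config(grid = scfg$grid)
  series <- stage("indicators", build_series(cohort, icfg))

  m2 <- if (length(config$interruptions) >= 2) config$interruptions[2] else NULL
  design <- build_design(config$n_months, config$interruptions[1], m2)
  fits <- stage("fit", lapply(indicator_columns(), function(col) {
    fit_its(design, series[[col]], alpha = config$alpha,
            estimator = config$estimator)
  }))
  names(fits) <- names(indicator_columns())

  periods <- period_definition(config$interruptions, config$n_months)
  table1 <- stage("report", make_table1(cohort, series, periods, scfg$grid))
  table2 <- stage("report", make_table2(fits))

  staging <- tempfile("opioidits_run_")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  stage("write", {
    utils::write.csv(series, file.path(staging, "series.csv"),
                     row.names = FALSE)
    utils::write.csv(table1$characteristics,
                     file.path(staging, "table1_characteristics.csv"),
                     row.names = FALSE)
    utils::write.csv(table1$outcomes,
                     file.path(staging, "table1_outcomes.csv"),
                     row.names = FALSE)
    utils::write.csv(table2, file.path(staging, "table2.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lapply(fits, fit_to_list),
                         file.path(staging, "fits.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    plot_series(series, fits, file.path(staging, "figure2.png"))
    plot_series(series, fits, file.path(staging, "figure2.pdf"))
    manifest <- list(
      package = "opioidits",
      package_version = as.character(utils::packageVersion("opioidits")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      config = config[c("n_months", "interruptions", "patients_per_month",
                        "seed", "alpha", "estimator")],
      attrition = as.list(cohort$attrition)
    )
    jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (f in list.files(staging)) {
    file.copy(file.path(staging, f), file.path(outdir, f), overwrite = TRUE)
  }
  invisible(list(
    cohort = cohort, series = series, fits = fits,
    table1 = table1, table2 = table2, outdir = outdir
  ))
}
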