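PATIENT_COLUMNS <- c("patient_id", "sex", "birth_year", "insurance", "diagnoses")
RX_COLUMNS <- c(
  "rx_id", "patient_id", "provider_id", "institution_id", "drug_code",
  "start_date", "days_supplied", "units_per_day", "unit_strength_mg", "setting"
)
ICD10_PATTERN <- "^[A-Z][0-9]{2}[0-9A-Z]{0,2}$"

#' Cohort selection criteria
#'
#' Bundles the inclusion and exclusion rules used by [select_cohort()].
#' Defaults reproduce the study design: adult (20+) outpatients with a
#' musculoskeletal or connective-tissue diagnosis (ICD-10 chapter M),
#' excluding anyone with a cancer diagnosis (C00--C97) at any time in the
#' window, restricted to outpatient fills of catalog opioids in
#' January 2016 -- December 2020.
#'
#' Diagnosis matching is by code prefix on dot-free ICD-10 codes, so the
#' exclusion prefix "C50" covers "C50", "C501", "C509" and so on.  Age is
#' computed in completed years at the calendar year of the patient's first
#' in-window opioid fill (claims carry birth year only).
#'
#' @param min_age Minimum age in years (default 20).
#' @param include_dx_prefixes Character vector of ICD-10 prefixes at least
#'   one of which a patient must carry (default `"M"`, the whole
#'   musculoskeletal chapter).
#' @param exclude_dx_prefixes Prefixes that disqualify a patient (default
#'   the malignant-neoplasm block C00--C97).
#' @param study_start,study_end Study window (dates or "YYYY-MM-DD").
#' @return An object of class `cohort_criteria`.
#' @export
cohort_criteria <- function(min_age = 20,
                            include_dx_prefixes = "M",
                            exclude_dx_prefixes = sprintf("C%02d", 0:97),
                            study_start = "2016-01-01",
                            study_end = "2020-12-31") {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (is.na(study_start) || is.na(study_end) || study_end < study_start) {
    stop("invalid study window")
  }
  overlap <- outer(include_dx_prefixes, exclude_dx_prefixes,
                   function(a, b) startsWith(a, b) | startsWith(b, a))
  if (any(overlap)) stop("include and exclude diagnosis prefixes overlap")
  structure(
    list(
      min_age = min_age,
      include_dx_prefixes = include_dx_prefixes,
      exclude_dx_prefixes = exclude_dx_prefixes,
      study_start = study_start,
      study_end = study_end
    ),
    class = "cohort_criteria"
  )
}

split_dx <- function(diagnoses) strsplit(diagnoses, ";", fixed = TRUE)

matches_any_prefix <- function(codes, prefixes) {
  any(vapply(codes, function(cd) any(startsWith(cd, prefixes)), logical(1)))
}

validate_patients <- function(patients) {
  missing_cols <- setdiff(PATIENT_COLUMNS, names(patients))
  if (length(missing_cols) > 0) {
    stop("patients table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(patients$patient_id)) {
    dup <- patients$patient_id[duplicated(patients$patient_id)][1]
    stop("duplicate patient_id: ", dup)
  }
  bad_sex <- !patients$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop("invalid sex at patients row ", which(bad_sex)[1])
  }
  bad_ins <- !patients$insurance %in% c("NHI", "MedAid", "PVI")
  if (any(bad_ins)) {
    stop("invalid insurance at patients row ", which(bad_ins)[1])
  }
  if (!is.numeric(patients$birth_year) || any(is.na(patients$birth_year))) {
    stop("birth_year must be an integer year for every patient")
  }
  dx <- split_dx(patients$diagnoses)
  ok <- vapply(dx, function(codes) {
    length(codes) > 0 && all(grepl(ICD10_PATTERN, codes))
  }, logical(1))
  if (!all(ok)) {
    stop("malformed ICD-10 diagnosis code at patients row ", which(!ok)[1])
  }
  patients
}

validate_prescriptions <- function(prescriptions, patients, catalog) {
  missing_cols <- setdiff(RX_COLUMNS, names(prescriptions))
  if (length(missing_cols) > 0) {
    stop("prescriptions table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(prescriptions) == 0) return(prescriptions)
  start <- as.Date(prescriptions$start_date, format = "%Y-%m-%d")
  if (anyNA(start)) {
    stop("unparseable start_date at prescriptions row ", which(is.na(start))[1])
  }
  bad <- !is.finite(prescriptions$days_supplied) | prescriptions$days_supplied < 1 |
    prescriptions$days_supplied != floor(prescriptions$days_supplied)
  if (any(bad)) {
    stop("days_supplied must be a positive integer; prescriptions row ",
         which(bad)[1])
  }
  bad <- !is.finite(prescriptions$units_per_day) | prescriptions$units_per_day <= 0
  if (any(bad)) {
    stop("units_per_day must be positive; prescriptions row ", which(bad)[1])
  }
  bad <- !is.finite(prescriptions$unit_strength_mg) | prescriptions$unit_strength_mg <= 0
  if (any(bad)) {
    stop("unit_strength_mg must be positive; prescriptions row ", which(bad)[1])
  }
  bad <- !prescriptions$setting %in% c("outpatient", "inpatient")
  if (any(bad)) {
    stop("setting must be 'outpatient' or 'inpatient'; prescriptions row ",
         which(bad)[1])
  }
  known <- c(catalog$drug_code, NALOXONE_CODE)
  bad <- !prescriptions$drug_code %in% known
  if (any(bad)) {
    stop("unknown drug_code '", prescriptions$drug_code[which(bad)[1]],
         "' at prescriptions row ", which(bad)[1])
  }
  orphan <- !prescriptions$patient_id %in% patients$patient_id
  if (any(orphan)) {
    stop("prescription references unknown patient_id '",
         prescriptions$patient_id[which(orphan)[1]], "' at row ",
         which(orphan)[1])
  }
  prescriptions
}

#' Read claims tables
#'
#' Reads the two delimited claims tables and validates every row.  The
#' patient table has columns `patient_id`, `sex`, `birth_year`,
#' `insurance`, `diagnoses` (semicolon-separated dot-free ICD-10 codes);
#' the prescription table has `rx_id`, `patient_id`, `provider_id`,
#' `institution_id`, `drug_code`, `start_date` (ISO 8601),
#' `days_supplied`, `units_per_day`, `unit_strength_mg`, `setting`.
#' A fill covers the closed day range
#' `[start_date, start_date + days_supplied - 1]`.
#'
#' @param patients_path,prescriptions_path CSV file paths.
#' @param catalog Opioid catalog (default [default_opioid_catalog()]);
#'   every `drug_code` must be in the catalog or be the reserved
#'   [NALOXONE_CODE].
#' @return A list with validated data frames `patients` and
#'   `prescriptions`.
#' @export
read_claims <- function(patients_path, prescriptions_path,
                        catalog = default_opioid_catalog()) {
  for (p in c(patients_path, prescriptions_path)) {
    if (!file.exists(p)) stop("claims file not found: ", p)
  }
  validate_catalog(catalog)
  patients <- utils::read.csv(patients_path, stringsAsFactors = FALSE,
                              colClasses = "character")
  patients$birth_year <- suppressWarnings(as.integer(patients$birth_year))
  prescriptions <- utils::read.csv(prescriptions_path, stringsAsFactors = FALSE,
                                   colClasses = "character")
  for (col in c("days_supplied", "units_per_day", "unit_strength_mg")) {
    if (col %in% names(prescriptions)) {
      prescriptions[[col]] <- suppressWarnings(as.numeric(prescriptions[[col]]))
    }
  }
  patients <- validate_patients(patients)
  prescriptions <- validate_prescriptions(prescriptions, patients, catalog)
  list(patients = patients, prescriptions = prescriptions)
}

#' Write claims tables
#'
#' Inverse of [read_claims()]: writes the two tables as plain CSV so that a
#' read/write cycle reproduces valid input files byte-identically.
#'
#' @param claims List with `patients` and `prescriptions` data frames.
#' @param patients_path,prescriptions_path Output CSV paths.
#' @return The two paths, invisibly.
#' @export
write_claims <- function(claims, patients_path, prescriptions_path) {
  utils::write.csv(claims$patients[PATIENT_COLUMNS], patients_path,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(claims$prescriptions[RX_COLUMNS], prescriptions_path,
                   row.names = FALSE, quote = FALSE)
  invisible(c(patients_path, prescriptions_path))
}

#' Select the study cohort
#'
#' Applies the inclusion/exclusion cascade: a patient is retained when they
#' (a) carry at least one diagnosis matching an include prefix, (b) carry
#' no diagnosis matching an exclude prefix, (c) are at least `min_age`
#' years old in the year of their first in-window outpatient opioid fill,
#' and (d) have at least one such fill.  Retained prescriptions are the
#' outpatient catalog-opioid fills of retained patients inside the study
#' window; naloxone records of retained patients are carried alongside for
#' the naloxone indicator.
#'
#' An attrition summary (counts remaining after each rule) is emitted as a
#' message unless `quiet = TRUE`.
#'
#' @param patients,prescriptions Validated claims tables.
#' @param criteria A [cohort_criteria()] object.
#' @param catalog Opioid catalog.
#' @param quiet Suppress the attrition message.
#' @return A list with `patients`, `prescriptions` (opioid fills),
#'   `naloxone` (naloxone records of cohort patients) and `attrition`
#'   (named integer vector).
#' @export
select_cohort <- function(patients, prescriptions,
                          criteria = cohort_criteria(),
                          catalog = default_opioid_catalog(),
                          quiet = FALSE) {
  stopifnot(inherits(criteria, "cohort_criteria"))
  dx <- split_dx(patients$diagnoses)
  has_include <- vapply(dx, matches_any_prefix, logical(1),
                        prefixes = criteria$include_dx_prefixes)
  has_exclude <- vapply(dx, matches_any_prefix, logical(1),
                        prefixes = criteria$exclude_dx_prefixes)

  start <- as.Date(prescriptions$start_date)
  in_window <- start >= criteria$study_start & start <= criteria$study_end
  is_opioid <- prescriptions$drug_code %in% catalog$drug_code
  opioid_fills <- prescriptions[in_window & is_opioid &
                                  prescriptions$setting == "outpatient", ,
                                drop = FALSE]

  # age at the year of the first in-window outpatient opioid fill
  first_year <- vapply(
    split(as.integer(format(as.Date(opioid_fills$start_date), "%Y")),
          opioid_fills$patient_id),
    min, integer(1)
  )
  ref_year <- first_year[patients$patient_id]
  age <- ref_year - patients$birth_year
  has_fill <- !is.na(ref_year)
  old_enough <- has_fill & age >= criteria$min_age

  keep <- has_include & !has_exclude & old_enough
  attrition <- c(
    input = nrow(patients),
    with_included_diagnosis = sum(has_include),
    without_excluded_diagnosis = sum(has_include & !has_exclude),
    with_outpatient_opioid_fill = sum(has_include & !has_exclude & has_fill),
    age_eligible = sum(keep)
  )
  if (!quiet) {
    message(paste(sprintf("%s: %d", names(attrition), attrition),
                  collapse = " -> "))
  }

  cohort_patients <- patients[keep, , drop = FALSE]
  cohort_fills <- opioid_fills[opioid_fills$patient_id %in%
                                 cohort_patients$patient_id, , drop = FALSE]
  naloxone <- prescriptions[in_window &
                              prescriptions$drug_code == NALOXONE_CODE &
                              prescriptions$patient_id %in%
                                cohort_patients$patient_id, , drop = FALSE]
  rownames(cohort_patients) <- NULL
  rownames(cohort_fills) <- NULL
  rownames(naloxone) <- NULL
  list(
    patients = cohort_patients,
    prescriptions = cohort_fills,
    naloxone = naloxone,
    attrition = attrition
  )
}

#' Assign the study age group
#'
#' Buckets completed age (`reference_year - birth_year`) into the four
#' strata 20-39, 40-59, 60-74 and 75+.
#'
#' @param birth_year Integer vector of birth years.
#' @param reference_year Year at which age is evaluated.
#' @return Factor with levels `"20-39"`, `"40-59"`, `"60-74"`, `"75+"`.
#' @export
#' @examples
#' assign_age_group(c(1987, 1951, 1940), 2016)
assign_age_group <- function(birth_year, reference_year) {
  age <- reference_year - birth_year
  if (any(age < 20, na.rm = TRUE)) {
    stop("age below 20: cohort selection should have removed this patient")
  }
  cut(age, breaks = c(20, 40, 60, 75, Inf), right = FALSE,
      labels = c("20-39", "40-59", "60-74", "75+"))
}

#' Classify musculoskeletal morbidity
#'
#' Maps a patient's first chapter-M diagnosis to the four reporting
#' classes: arthropathies (M00--M25), dorsopathies (M40--M54), soft tissue
#' disorders (M60--M79), and other musculoskeletal disorders (the residual
#' M codes).
#'
#' @param diagnoses Semicolon-separated diagnosis strings.
#' @return Factor with the four class labels (`NA` when no M code).
#' @export
morbidity_class <- function(diagnoses) {
  first_m <- vapply(split_dx(diagnoses), function(codes) {
    m <- codes[startsWith(codes, "M")]
    if (length(m) == 0) NA_character_ else m[1]
  }, character(1))
  num <- suppressWarnings(as.integer(substr(first_m, 2, 3)))
  cls <- ifelse(is.na(num), NA_character_,
         ifelse(num <= 25, "Arthropathies",
         ifelse(num >= 40 & num <= 54, "Dorsopathies",
         ifelse(num >= 60 & num <= 79, "Soft tissue disorders", "Others"))))
  factor(cls, levels = c("Arthropathies", "Dorsopathies",
                         "Soft tissue disorders", "Others"))
}
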