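#' Reserved drug code identifying naloxone records
#'
#' Naloxone administrations travel through the same prescription table as
#' opioid fills, flagged by this reserved `drug_code`.  Naloxone rows are
#' never treated as opioid fills: they do not enter morphine-milligram-
#' equivalent (MME) sums, denominators, or overlap computations.
#'
#' @export
NALOXONE_CODE <- "NALOXONE"

#' Default opioid catalog
#'
#' Returns the catalog of the nine study opioids: oral codeine,
#' dihydrocodeine, hydrocodone, hydromorphone, morphine, oxycodone and
#' tapentadol, plus transdermal buprenorphine and fentanyl.  Sublingual,
#' buccal and nasal formulations are out of scope (they are reserved for
#' breakthrough cancer pain under Korean reimbursement rules, and cancer
#' patients are excluded from the cohort).
#'
#' `mme_factor` converts milligrams of molecule to morphine milligram
#' equivalents; morphine oral is 1 by definition.  The shipped factors
#' follow the CDC 2018 conversion file for oral agents.  For the two
#' transdermal patches, `unit_strength_mg` is interpreted as the delivery
#' rate in micrograms per hour and the factor converts that rate to
#' MME/day (fentanyl 2.4, buprenorphine 12.6), the usual claims-analysis
#' convention.  The catalog is configuration, not code: supply your own
#' table via [read_opioid_catalog()] to change any factor.
#'
#' @return A data frame with columns `drug_code`, `molecule`, `route`,
#'   `mme_factor`.
#' @export
#' @examples
#' default_opioid_catalog()
default_opioid_catalog <- function() {
  data.frame(
    drug_code = c(
      "BUP_TD", "COD_PO", "DHC_PO", "FEN_TD", "HCO_PO",
      "HMO_PO", "MOR_PO", "OXY_PO", "TAP_PO"
    ),
    molecule = c(
      "buprenorphine", "codeine", "dihydrocodeine", "fentanyl",
      "hydrocodone", "hydromorphone", "morphine", "oxycodone", "tapentadol"
    ),
    route = c(
      "transdermal", "oral", "oral", "transdermal", "oral",
      "oral", "oral", "oral", "oral"
    ),
    mme_factor = c(12.6, 0.15, 0.25, 2.4, 1, 4, 1, 1.5, 0.4),
    stringsAsFactors = FALSE
  )
}

#' Read an opioid catalog from CSV
#'
#' @param path Path to a CSV file with columns `drug_code`, `molecule`,
#'   `route`, `mme_factor`.
#' @return A validated catalog data frame.
#' @export
read_opioid_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  cat_df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_catalog(cat_df)
}

#' Validate an opioid catalog
#'
#' Checks column presence, positive conversion factors, admissible routes,
#' unique drug codes, and that oral morphine (if present) has factor
#' exactly 1.
#'
#' @param catalog A catalog data frame.
#' @return The catalog, invisibly unchanged, for chaining.
#' @export
validate_catalog <- function(catalog) {
  required <- c("drug_code", "molecule", "route", "mme_factor")
  missing_cols <- setdiff(required, names(catalog))
  if (length(missing_cols) > 0) {
    stop("catalog is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(catalog$drug_code)) {
    stop("catalog drug_code values must be unique")
  }
  if (NALOXONE_CODE %in% catalog$drug_code) {
    stop("drug_code ", NALOXONE_CODE, " is reserved and cannot appear in the catalog")
  }
  if (!all(catalog$route %in% c("oral", "transdermal"))) {
    stop("catalog route must be 'oral' or 'transdermal'")
  }
  if (!all(is.finite(catalog$mme_factor)) || any(catalog$mme_factor <= 0)) {
    stop("all mme_factor values must be positive")
  }
  morphine_oral <- catalog$molecule == "morphine" & catalog$route == "oral"
  if (any(morphine_oral) && any(catalog$mme_factor[morphine_oral] != 1)) {
    stop("oral morphine must have mme_factor exactly 1")
  }
  catalog
}

#' Write an opioid catalog to CSV
#'
#' @param catalog A catalog data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_opioid_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  utils::write.csv(catalog, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
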