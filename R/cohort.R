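ATYPICAL_PATTERNS <- c("bilateral_atrophy", "lopsided", "mild_lopsided",
                       "unilateral", "asymmetric")

REFERRAL_REASONS <- c("incidental", "ultrasound_for_family_history",
                      "ultrasound_for_symptoms")

SMOKING_LEVELS <- c("yes", "no", "former")

#' Load the packaged atypical-ADPKD reference cohort
#'
#' Returns the 12-patient atypical (Mayo Class 2) ADPKD cohort bundled with the
#' package: clinical variables (age, sex, serum creatinine, eGFR and its annual
#' slope, hypertension, referral reason, smoking, diabetes, extrarenal
#' involvement, family history) joined to the MRI volumetrics (imaging pattern,
#' height-adjusted total kidney volume htTKV, total cyst volume TCV, cystic
#' percentage and residual tissue volume RTV, all in mL/m). A `mayo_class`
#' column (2A/2B) is derived from the imaging pattern.
#'
#' Volumes are stored as printed in the source tables (integers, mL/m); the
#' published percentage column is kept verbatim even where it disagrees
#' slightly with `100 * tcv / httkv` recomputed from the rounded volumes.
#' Patient 5's clinical row (creatinine 1.40 mg/dL, eGFR 57, slope +8.59) is a
#' reconstruction of a typographically ambiguous source cell, chosen as the
#' unique reading consistent with the cohort's published mean eGFR (74.2),
#' mean creatinine (0.97), the count of two subjects with eGFR < 60, and the
#' slope median/IQR.
#'
#' @param validate logical; run integrity checks on the packaged data
#'   (default `TRUE`). A corrupted fixture raises an error naming the
#'   offending patient.
#' @return A `data.frame` with 12 rows and 18 columns, one row per patient.
#' @examples
#' cohort <- load_cohort()
#' table(cohort$mayo_class)
#' @export
load_cohort <- function(validate = TRUE) {
  path <- system.file("extdata", "atypical_cohort.csv", package = "atypkd",
                      mustWork = TRUE)
  cohort <- read_cohort_csv(path, quiet = TRUE)
  if (validate) validate_cohort(cohort)
  cohort
}

#' Read a cohort table from CSV
#'
#' Parses and type-checks a cohort CSV in the packaged schema (see
#' [load_cohort()] for the column set). Unknown extra columns are kept with a
#' warning; missing required columns or invalid values are errors.
#'
#' @param path path to a CSV file with a header row.
#' @param quiet logical; suppress the extra-column warning.
#' @return A typed `data.frame` with a derived `mayo_class` column.
#' @export
read_cohort_csv <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "age", "sex", "serum_creatinine", "egfr",
                "egfr_slope", "hypertension", "referral_reason", "smoking",
                "diabetes", "extrarenal_involvement", "family_history_positive",
                "pattern", "httkv", "tcv", "tcv_percent", "rtv")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("cohort CSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(raw), required)
  if (length(extra) && !quiet)
    warning("ignoring unknown cohort column(s): ", paste(extra, collapse = ", "))

  cohort <- raw[required]
  cohort$patient_id <- as.integer(cohort$patient_id)
  for (col in c("age", "serum_creatinine", "egfr", "egfr_slope",
                "httkv", "tcv", "tcv_percent", "rtv"))
    cohort[[col]] <- as.numeric(cohort[[col]])
  for (col in c("hypertension", "diabetes", "extrarenal_involvement",
                "family_history_positive"))
    cohort[[col]] <- as.logical(cohort[[col]])

  check_value <- function(ok, what) {
    if (any(!ok))
      stop("invalid ", what, " for patient ",
           paste(cohort$patient_id[!ok], collapse = ", "))
  }
  check_value(cohort$sex %in% c("M", "F"), "sex")
  check_value(cohort$pattern %in% ATYPICAL_PATTERNS, "imaging pattern")
  check_value(cohort$referral_reason %in% REFERRAL_REASONS, "referral reason")
  check_value(cohort$smoking %in% SMOKING_LEVELS, "smoking status")
  check_value(is.finite(cohort$serum_creatinine) & cohort$serum_creatinine > 0,
              "serum creatinine")
  check_value(is.finite(cohort$egfr) & cohort$egfr > 0, "eGFR")
  check_value(is.finite(cohort$httkv) & cohort$httkv > 0, "htTKV")
  check_value(is.finite(cohort$tcv) & cohort$tcv >= 0, "TCV")

  cohort$mayo_class <- vapply(cohort$pattern, mayo2_subclass, character(1))
  cohort
}

#' Export the packaged cohort as CSV
#'
#' Writes the packaged 12-patient cohort (without the derived `mayo_class`
#' column) to `path` in the same schema it is shipped in, so that
#' [read_cohort_csv()] round-trips it.
#'
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
export_cohort_csv <- function(path) {
  src <- system.file("extdata", "atypical_cohort.csv", package = "atypkd",
                     mustWork = TRUE)
  file.copy(src, path, overwrite = TRUE)
  invisible(path)
}

validate_cohort <- function(cohort) {
  if (nrow(cohort) != 12L)
    stop("packaged cohort must have exactly 12 records, found ", nrow(cohort))
  if (anyDuplicated(cohort$patient_id))
    stop("duplicated patient_id in cohort: ",
         cohort$patient_id[duplicated(cohort$patient_id)][1])
  bad <- which(cohort$rtv != cohort$httkv - cohort$tcv)
  if (length(bad))
    stop("RTV != htTKV - TCV for patient ",
         paste(cohort$patient_id[bad], collapse = ", "))
  n_low <- sum(cohort$egfr < 60)
  if (n_low != 2L)
    stop("expected exactly 2 records with eGFR < 60, found ", n_low)
  invisible(cohort)
}

#' Mayo Class 2 subclassification from the imaging pattern
#'
#' Atypical (Class 2) ADPKD is split by the Mayo imaging classification into
#' Class 2A (focal disease: unilateral, segmental/lopsided, asymmetric or mild
#' atypical presentation) and Class 2B (atrophic disease).
#'
#' @param pattern one of `"bilateral_atrophy"`, `"lopsided"`,
#'   `"mild_lopsided"`, `"unilateral"`, `"asymmetric"`.
#' @return `"2A"` or `"2B"`.
#' @examples
#' mayo2_subclass("bilateral_atrophy")  # "2B"
#' mayo2_subclass("lopsided")           # "2A"
#' @export
mayo2_subclass <- function(pattern) {
  if (length(pattern) != 1L || !is.character(pattern) ||
      !(pattern %in% ATYPICAL_PATTERNS))
    stop("unknown atypical imaging pattern: ",
         paste(format(pattern), collapse = ", "))
  if (pattern == "bilateral_atrophy") "2B" else "2A"
}
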