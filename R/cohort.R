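#' @keywords internal
"_PACKAGE"

# --- cohort schema -----------------------------------------------------------

# Column order is the documented, canonical CSV layout.
cohort_enums <- list(
  center            = c("SAHZU", "BTH", "CCF", "other"),
  sex               = c("M", "F"),
  seizure_frequency = c("high", "low"),
  location          = c("frontal", "temporal", "posterior_quadrant",
                        "insular_opercular"),
  side              = c("left", "right"),
  fcd_subtype       = c("IIa", "IIb"),
  ied_class         = c("normal", "regional", "nonregional"),
  ictal_class       = c("normal", "regional", "nonregional")
)

cohort_logicals <- c("sre", "mri_report_positive", "bosd", "invasive_eeg",
                     "engel_I")

cohort_numerics <- c("age_at_mri", "age_at_onset", "duration_months",
                     "lesion_volume_mm3", "icv_mm3", "thal_left_mm3",
                     "thal_right_mm3")

#' Canonical cohort column names
#'
#' The required columns of a cohort table, in documented CSV order.
#' `lesion_volume_mm3`, `thal_left_mm3` and `thal_right_mm3` may be empty
#' (patient retained in clinical comparisons, excluded from volume
#' analyses); every other column must be filled.
#'
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c("patient_id", "center", "sex", "age_at_mri", "age_at_onset",
    "duration_months", "sre", "seizure_frequency", "mri_report_positive",
    "location", "side", "bosd", "fcd_subtype", "ied_class", "ictal_class",
    "invasive_eeg", "engel_I", "lesion_volume_mm3", "icv_mm3",
    "thal_left_mm3", "thal_right_mm3")
}

#' Validate a cohort table
#'
#' Checks the schema invariants: required columns present, enum columns
#' restricted to their legal values, volumes positive where present,
#' `age_at_onset <= age_at_mri`, unique non-missing `patient_id`, and at
#' least one row. Unknown extra columns are allowed and preserved.
#'
#' @param cohort A data frame with the columns of [cohort_columns()].
#' @return The cohort as a tibble, invisibly, if valid; otherwise an error
#'   of class `fcdsre_schema_error` (missing column) or
#'   `fcdsre_validation_error` (row-level violation, message names the
#'   offending `patient_id`s).
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0) {
    abort_fcd(paste0("cohort is missing required column(s): ",
                     paste(missing_cols, collapse = ", ")), "schema_error")
  }
  if (nrow(cohort) == 0) abort_fcd("cohort must be nonempty", "validation_error")

  id <- cohort$patient_id
  if (anyNA(id) || any(id == "")) {
    abort_fcd("patient_id must be nonmissing for every row", "validation_error")
  }
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    abort_fcd(paste0("patient_id not unique: ", paste(dup, collapse = ", ")),
              "validation_error")
  }

  bad <- function(rows, what) {
    if (any(rows, na.rm = TRUE)) {
      abort_fcd(paste0(what, " for patient(s): ",
                       paste(id[which(rows)], collapse = ", ")),
                "validation_error")
    }
  }

  for (col in names(cohort_enums)) {
    v <- as.character(cohort[[col]])
    bad(is.na(v) | !(v %in% cohort_enums[[col]]),
        paste0("illegal ", col, " value"))
  }
  for (col in cohort_logicals) {
    bad(is.na(as.logical(cohort[[col]])), paste0(col, " must be TRUE/FALSE"))
  }

  bad(is.na(cohort$age_at_mri) | cohort$age_at_mri <= 0,
      "age_at_mri must be > 0")
  bad(is.na(cohort$age_at_onset) | cohort$age_at_onset < 0,
      "age_at_onset must be >= 0")
  bad(cohort$age_at_onset > cohort$age_at_mri,
      "age_at_onset exceeds age_at_mri")
  bad(is.na(cohort$duration_months) | cohort$duration_months <= 0,
      "duration_months must be > 0")
  bad(is.na(cohort$icv_mm3) | cohort$icv_mm3 <= 0, "icv_mm3 must be > 0")
  # optional volumes: positive where present
  for (col in c("lesion_volume_mm3", "thal_left_mm3", "thal_right_mm3")) {
    bad(!is.na(cohort[[col]]) & cohort[[col]] <= 0,
        paste0(col, " must be > 0 when present"))
  }
  invisible(cohort)
}

cohort_col_types <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    center = readr::col_character(),
    sex = readr::col_character(),
    age_at_mri = readr::col_double(),
    age_at_onset = readr::col_double(),
    duration_months = readr::col_double(),
    sre = readr::col_logical(),
    seizure_frequency = readr::col_character(),
    mri_report_positive = readr::col_logical(),
    location = readr::col_character(),
    side = readr::col_character(),
    bosd = readr::col_logical(),
    fcd_subtype = readr::col_character(),
    ied_class = readr::col_character(),
    ictal_class = readr::col_character(),
    invasive_eeg = readr::col_logical(),
    engel_I = readr::col_logical(),
    lesion_volume_mm3 = readr::col_double(),
    icv_mm3 = readr::col_double(),
    thal_left_mm3 = readr::col_double(),
    thal_right_mm3 = readr::col_double(),
    .default = readr::col_character()
  )
}

#' Read a cohort table from CSV
#'
#' Reads a UTF-8, comma-separated cohort file with a header row, validates
#' it against the schema (see [validate_cohort()]) and returns a tibble.
#' Empty cells in the optional volume columns become `NA` (patient
#' excluded from volume analyses). Unknown columns are kept as character.
#' Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort_fcd(paste0("no such file: ", path), "io_error")
  cohort <- readr::read_csv(path, col_types = cohort_col_types(),
                            na = c("", "NA"), progress = FALSE)
  validate_cohort(cohort)
  cohort
}

#' Write a cohort table to CSV
#'
#' Serializes a validated cohort in the documented column order (extra
#' columns appended after the canonical ones). Missing optional values are
#' written as empty cells. Output bytes are deterministic given identical
#' input, so `read_cohort(write_cohort(x))` round-trips.
#'
#' @param cohort A cohort data frame (validated before writing).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  extra <- setdiff(names(cohort), cohort_columns())
  cohort <- cohort[, c(cohort_columns(), extra)]
  readr::write_csv(cohort, path, na = "", progress = FALSE)
  invisible(path)
}
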