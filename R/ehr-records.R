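#' Admission-record tables
#'
#' An admission table holds one row per inpatient hospitalization with the
#' columns:
#'
#' * `patient_id` (character): opaque patient identifier, unique within an
#'   edition of the registry.
#' * `edition_id` (character): label of the registry release (edition) the
#'   record was taken from.
#' * `admission_day` (integer): day offset from a fixed, arbitrary epoch.
#'   The real registries are deidentified, so only intervals between
#'   admissions carry meaning; integer offsets avoid calendar arithmetic.
#' * `diagnosis_codes` (list of character): ordered ICD-9-CM codes charted at
#'   that admission; the first element is the principal diagnosis.
#' * `died_in_hospital` (logical): in-hospital death outcome of the stay.
#' * `age_years` (numeric): patient age at admission.
#'
#' On disk the table is delimited text with a header and the diagnosis list
#' packed into a single column using a sub-delimiter (default `"|"`).
#'
#' @name admissions
NULL

ADMISSION_COLS <- c(
  "patient_id", "edition_id", "admission_day",
  "diagnosis_codes", "died_in_hospital", "age_years"
)

#' Coerce a data frame to an admission table
#'
#' Accepts `diagnosis_codes` either as a list of character vectors or as a
#' packed string column, validates the invariants, and returns a tibble in
#' canonical column order. Row order is never changed.
#'
#' @param x A data frame with the columns described in [admissions].
#' @param dx_sep Sub-delimiter used when `diagnosis_codes` is a packed string.
#' @return A tibble, one row per admission.
#' @export
as_admissions <- function(x, dx_sep = "|") {
  missing <- setdiff(ADMISSION_COLS, names(x))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("admission table is missing column(s): ",
             paste(missing, collapse = ", ")),
      class = "trajmine_format_error"
    )
  }
  out <- tibble::as_tibble(x)[ADMISSION_COLS]
  if (!is.list(out$diagnosis_codes)) {
    out$diagnosis_codes <- strsplit(as.character(out$diagnosis_codes),
                                    dx_sep, fixed = TRUE)
  }
  out$patient_id <- as.character(out$patient_id)
  out$edition_id <- as.character(out$edition_id)
  out$admission_day <- as.integer(out$admission_day)
  if (is.numeric(out$died_in_hospital)) {
    out$died_in_hospital <- out$died_in_hospital != 0
  }
  out$age_years <- as.double(out$age_years)
  validate_admissions(out)
  out
}

#' Validate an admission table
#'
#' Checks the container invariants: every admission carries at least one
#' diagnosis code, days are finite integers, ages are nonnegative and the
#' death flag is logical. Aborts with the offending row index otherwise.
#'
#' @param records An admission tibble.
#' @return `records`, invisibly.
#' @export
validate_admissions <- function(records) {
  bad <- which(lengths(records$diagnosis_codes) == 0)
  if (length(bad) > 0) {
    rlang::abort(
      paste0("empty diagnosis_codes in row(s): ",
             paste(utils::head(bad, 5), collapse = ", ")),
      class = "trajmine_record_error"
    )
  }
  bad <- which(!is.finite(records$admission_day))
  if (length(bad) > 0) {
    rlang::abort(
      paste0("non-finite admission_day in row(s): ",
             paste(utils::head(bad, 5), collapse = ", ")),
      class = "trajmine_record_error"
    )
  }
  bad <- which(!is.finite(records$age_years) | records$age_years < 0)
  if (length(bad) > 0) {
    rlang::abort(
      paste0("invalid age_years in row(s): ",
             paste(utils::head(bad, 5), collapse = ", ")),
      class = "trajmine_record_error"
    )
  }
  if (!is.logical(records$died_in_hospital) ||
      anyNA(records$died_in_hospital)) {
    rlang::abort("died_in_hospital must be logical with no missing values",
                 class = "trajmine_record_error")
  }
  invisible(records)
}

#' Read an admission table from delimited text
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter (default comma).
#' @param dx_sep Sub-delimiter packing the ordered diagnosis codes into the
#'   `diagnosis_codes` column; the first code is the principal diagnosis.
#' @return An admission tibble (see [admissions]), rows in file order.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_admissions(example_admissions(), path)
#' read_admissions(path)
read_admissions <- function(path, delim = ",", dx_sep = "|") {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path), class = "trajmine_io_error")
  }
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(ADMISSION_COLS, names(raw))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("missing mandatory column(s): ", paste(missing, collapse = ", ")),
      class = "trajmine_format_error"
    )
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(
      patient_id = character(), edition_id = character(),
      admission_day = integer(), diagnosis_codes = list(),
      died_in_hospital = logical(), age_years = double()
    ))
  }
  day <- suppressWarnings(as.integer(raw$admission_day))
  age <- suppressWarnings(as.double(raw$age_years))
  bad <- which(is.na(day) | is.na(age))
  if (length(bad) > 0) {
    rlang::abort(
      paste0("unparseable admission_day/age_years in data row(s): ",
             paste(utils::head(bad, 5), collapse = ", ")),
      class = "trajmine_format_error"
    )
  }
  as_admissions(
    tibble::tibble(
      patient_id = raw$patient_id,
      edition_id = raw$edition_id,
      admission_day = day,
      diagnosis_codes = raw$diagnosis_codes,
      died_in_hospital = raw$died_in_hospital %in% c("1", "TRUE", "true"),
      age_years = age
    ),
    dx_sep = dx_sep
  )
}

#' Write an admission table to delimited text
#'
#' Inverse of [read_admissions()]: writing then reading reproduces the table
#' field for field, including diagnosis order.
#'
#' @param records An admission tibble.
#' @param path Output path.
#' @inheritParams read_admissions
#' @return `path`, invisibly.
#' @export
write_admissions <- function(records, path, delim = ",", dx_sep = "|") {
  records <- as_admissions(records, dx_sep = dx_sep)
  flat <- dplyr::mutate(
    records,
    diagnosis_codes = vapply(.data$diagnosis_codes, paste,
                             character(1), collapse = dx_sep),
    died_in_hospital = as.integer(.data$died_in_hospital)
  )
  readr::write_delim(flat, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' A small worked-example admission table
#'
#' Six admissions for three patients, used in documentation examples.
#'
#' @return An admission tibble.
#' @export
example_admissions <- function() {
  as_admissions(tibble::tibble(
    patient_id = c("p1", "p1", "p1", "p2", "p2", "p3"),
    edition_id = "2010",
    admission_day = c(0L, 120L, 400L, 10L, 200L, 50L),
    diagnosis_codes = c("296", "295|401", "728.88", "410", "428", "486"),
    died_in_hospital = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    age_years = c(40, 40.3, 41.1, 70, 70.5, 80)
  ))
}
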