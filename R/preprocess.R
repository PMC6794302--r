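#' Extract the principal diagnosis of each admission
#'
#' The first charted diagnosis code of an admission is taken as the principal
#' diagnosis — the main reason for the hospitalization.
#'
#' @param records An admission tibble, or a list of diagnosis-code vectors.
#' @return Character vector of principal codes, one per admission.
#' @export
principal_diagnosis <- function(records) {
  codes <- if (is.data.frame(records)) records$diagnosis_codes else records
  if (any(lengths(codes) == 0)) {
    rlang::abort("admission with empty diagnosis_codes",
                 class = "trajmine_record_error")
  }
  vapply(codes, `[[`, character(1), 1L)
}

#' Truncate ICD-9-CM codes to the three-digit level
#'
#' Diagnosis codes are rounded to the chapter-level three-digit code to avoid
#' splitting a condition across sub-classifications (e.g. rhabdomyolysis,
#' 728.88, is analysed under muscle/ligament/fascia disorders, 728).
#' Numeric codes keep their first three digits, V codes keep "V" plus two
#' digits, E codes keep "E" plus three digits; the decimal part is dropped.
#'
#' @param code Character vector of ICD-9-CM codes.
#' @return Character vector of three-digit codes.
#' @export
#' @examples
#' round_icd9(c("728.88", "295", "V58.11", "E850.0"))
round_icd9 <- function(code) {
  code <- as.character(code)
  ok_num <- stringr::str_detect(code, "^[0-9]{3}(\\.[0-9]{1,2})?$")
  ok_v <- stringr::str_detect(code, "^V[0-9]{2}(\\.[0-9]{1,2})?$")
  ok_e <- stringr::str_detect(code, "^E[0-9]{3}(\\.[0-9])?$")
  bad <- !(ok_num | ok_v | ok_e)
  if (any(bad)) {
    rlang::abort(
      paste0("not a valid ICD-9-CM code: ",
             paste(unique(utils::head(code[bad], 5)), collapse = ", ")),
      class = "trajmine_coding_error"
    )
  }
  out <- code
  out[ok_num] <- substr(code[ok_num], 1, 3)
  out[ok_v] <- substr(code[ok_v], 1, 3)
  out[ok_e] <- substr(code[ok_e], 1, 4)
  out
}

#' Round every diagnosis code in an admission table
#'
#' @param records An admission tibble.
#' @return The table with all `diagnosis_codes` truncated via [round_icd9()].
#' @export
round_diagnoses <- function(records) {
  records$diagnosis_codes <- lapply(records$diagnosis_codes, round_icd9)
  records
}

#' Merge registry editions without double-counting patients
#'
#' Registry editions carry longitudinal records per patient but patient
#' identifiers cannot be linked across editions. To avoid counting the same
#' individual twice, the merge keeps every record of the latest edition and,
#' from each earlier edition, only the records of patients who died in
#' hospital in that edition (a deceased patient cannot reappear later).
#'
#' @param records An admission tibble spanning one or more editions.
#' @param latest_edition Label of the most recent edition; defaults to the
#'   lexicographic maximum of `edition_id`.
#' @param backfill_requires_death If `FALSE`, earlier editions are merged
#'   wholesale (no deceased-only rule). Default `TRUE`.
#' @return The merged admission tibble; `edition_id` records provenance.
#'   A warning is raised if a patient id occurs in more than one edition of
#'   the merged output (the ids are then treated as the same patient).
#' @export
merge_editions <- function(records, latest_edition = NULL,
                           backfill_requires_death = TRUE) {
  records <- as_admissions(records)
  editions <- unique(records$edition_id)
  if (is.null(latest_edition)) latest_edition <- max(editions)
  if (!latest_edition %in% editions) {
    rlang::abort(
      paste0("latest_edition '", latest_edition, "' not present in data"),
      class = "trajmine_config_error"
    )
  }
  if (!backfill_requires_death) {
    out <- records
  } else {
    keep_early <- records |>
      dplyr::filter(.data$edition_id != latest_edition) |>
      dplyr::group_by(.data$edition_id, .data$patient_id) |>
      dplyr::filter(any(.data$died_in_hospital)) |>
      dplyr::ungroup()
    out <- dplyr::bind_rows(
      dplyr::filter(records, .data$edition_id == latest_edition),
      keep_early
    )
  }
  dup <- out |>
    dplyr::distinct(.data$patient_id, .data$edition_id) |>
    dplyr::count(.data$patient_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::warn(paste0(
      nrow(dup), " patient id(s) appear in more than one merged edition; ",
      "records collapsed by patient_id"
    ))
  }
  out
}

# Chapter ranges treated as non-disease; pinned to the four named categories.
# Perinatal-condition codes (760-779) are retained deliberately.
nondisease_category <- function(code3) {
  num <- suppressWarnings(as.integer(substr(code3, 1, 3)))
  dplyr::case_when(
    startsWith(code3, "E") ~ "external_causes",
    startsWith(code3, "V") ~ "administrative",
    !is.na(num) & num >= 630 & num <= 679 ~ "pregnancy",
    !is.na(num) & num >= 800 & num <= 999 ~ "injury",
    .default = NA_character_
  )
}

#' Drop admissions whose principal diagnosis is not a disease
#'
#' Removes admissions whose (three-digit) principal diagnosis falls in the
#' non-disease chapters: pregnancy/childbirth/puerperium (630–679),
#' injury/poisoning (800–999), external causes (E codes), and supplementary
#' or administrative classifications (V codes). All other admissions are
#' retained. The operation is idempotent.
#'
#' @param records An admission tibble with principal diagnoses already
#'   rounded to the three-digit level (see [round_diagnoses()]).
#' @return The filtered tibble. The counts dropped per category are attached
#'   as the `"filter_report"` attribute (a tibble with columns `category`,
#'   `n_dropped`).
#' @export
filter_nondisease <- function(records) {
  principal <- principal_diagnosis(records)
  cat <- nondisease_category(principal)
  report <- tibble::tibble(category = cat[!is.na(cat)]) |>
    dplyr::count(.data$category, name = "n_dropped")
  out <- records[is.na(cat), , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' Build per-patient first-diagnosis timelines
#'
#' Collapses an admission table to one row per patient and three-digit
#' principal diagnosis, keeping only the earliest admission for each disease
#' (rediagnoses and rehospitalizations for the same disease are ignored).
#' Death is terminal: `death_day` is the day of the earliest death-flagged
#' admission, and any records dated after it are dropped with a warning.
#'
#' @param records An admission tibble, already merged across editions,
#'   three-digit rounded and non-disease filtered.
#' @return A timeline tibble with columns `patient_id`, `code`, `first_day`
#'   (earliest admission day with that principal diagnosis), `age` (age at
#'   that admission) and `death_day` (integer, `NA` if the patient has no
#'   in-hospital death record).
#' @export
build_timelines <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(
      patient_id = character(), code = character(), first_day = integer(),
      age = double(), death_day = integer()
    ))
  }
  df <- tibble::tibble(
    patient_id = records$patient_id,
    code = principal_diagnosis(records),
    day = records$admission_day,
    age = records$age_years,
    died = records$died_in_hospital
  )
  died_rows <- dplyr::filter(df, .data$died)
  deaths <- if (nrow(died_rows) == 0) {
    tibble::tibble(patient_id = character(), death_day = integer())
  } else {
    dplyr::summarise(died_rows, death_day = min(.data$day),
                     .by = "patient_id")
  }
  df <- dplyr::left_join(df, deaths, by = "patient_id")
  post <- !is.na(df$death_day) & df$day > df$death_day
  if (any(post)) {
    rlang::warn(paste0(
      sum(post), " admission(s) dated after a patient's death day dropped"
    ))
    df <- df[!post, , drop = FALSE]
  }
  df |>
    dplyr::arrange(.data$patient_id, .data$code, .data$day) |>
    dplyr::summarise(
      first_day = .data$day[1],
      age = .data$age[1],
      death_day = .data$death_day[1],
      .by = c("patient_id", "code")
    ) |>
    dplyr::select("patient_id", "code", "first_day", "age", "death_day")
}

#' Preprocess a raw multi-edition registry into timelines
#'
#' Convenience wrapper chaining [merge_editions()], [round_diagnoses()],
#' [filter_nondisease()] and [build_timelines()].
#'
#' @inheritParams merge_editions
#' @return A list with elements `timelines` (see [build_timelines()]),
#'   `merged` (the merged admission tibble), `n_cohort` (number of distinct
#'   patients in the merged registry — the N used by the RA statistic) and
#'   `filter_report`.
#' @export
prepare_timelines <- function(records, latest_edition = NULL,
                              backfill_requires_death = TRUE) {
  merged <- merge_editions(records, latest_edition, backfill_requires_death)
  rounded <- round_diagnoses(merged)
  kept <- filter_nondisease(rounded)
  list(
    timelines = build_timelines(kept),
    merged = merged,
    n_cohort = dplyr::n_distinct(merged$patient_id),
    filter_report = attr(kept, "filter_report")
  )
}
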