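#' Per-patient temporal order indicators for a disease pair
#'
#' For each patient diagnosed with both diseases, the indicator d is +1 when
#' disease `i` was first diagnosed before disease `j`, and -1 otherwise.
#' Patients whose two first-diagnosis days are more than `window_days` apart,
#' or fall on the same day (a tie — d is defined only on \{-1, +1\}), are
#' excluded.
#'
#' @param timelines A timeline tibble from [build_timelines()].
#' @param i,j Three-digit disease codes.
#' @param window_days Maximum inter-diagnosis interval (default 365).
#' @return Tibble with columns `patient_id`, `d` (+1/-1) and `gap` (the
#'   absolute interval in days), one row per contributing patient.
#' @export
order_indicator <- function(timelines, i, j, window_days = 365) {
  if (!i %in% timelines$code || !j %in% timelines$code) {
    rlang::abort(paste0("code not present in timelines: ",
                        if (i %in% timelines$code) j else i),
                 class = "trajmine_record_error")
  }
  di <- dplyr::filter(timelines, .data$code == i)
  dj <- dplyr::filter(timelines, .data$code == j)
  both <- dplyr::inner_join(
    dplyr::select(di, "patient_id", day_i = "first_day"),
    dplyr::select(dj, "patient_id", day_j = "first_day"),
    by = "patient_id"
  )
  both |>
    dplyr::mutate(gap = abs(.data$day_i - .data$day_j)) |>
    dplyr::filter(.data$gap <= window_days, .data$day_i != .data$day_j) |>
    dplyr::mutate(d = ifelse(.data$day_i < .data$day_j, 1L, -1L)) |>
    dplyr::select("patient_id", "d", "gap")
}

#' Directionality score of a disease pair
#'
#' The mean of the per-patient order indicators. A score of +1 means the
#' source disease always preceded the target among contributing patients;
#' 0 means no preferred order.
#'
#' @param indicators Vector of +1/-1 order indicators.
#' @return The mean, in \[-1, 1\].
#' @export
delta_score <- function(indicators) {
  if (length(indicators) == 0) {
    rlang::abort("direction undefined: no ordered patients",
                 class = "trajmine_stat_error")
  }
  mean(indicators)
}

#' Exact two-sided sign test for temporal direction
#'
#' Tests whether forward orderings occur more (or less) often than the 50%
#' expected when the two diagnoses carry no temporal preference: the doubled
#' smaller tail of Binomial(n_total, 1/2), capped at 1.
#'
#' @param n_forward Number of patients with the forward order (+1).
#' @param n_total Number of patients contributing an indicator.
#' @return Two-sided p-value(s).
#' @export
sign_test <- function(n_forward, n_total) {
  if (any(n_total <= 0)) {
    rlang::abort("sign test undefined for n_total = 0",
                 class = "trajmine_stat_error")
  }
  if (any(n_forward < 0 | n_forward > n_total)) {
    rlang::abort("n_forward must lie in [0, n_total]",
                 class = "trajmine_stat_error")
  }
  lower <- stats::pbinom(n_forward, n_total, 0.5)
  upper <- stats::pbinom(n_forward - 1, n_total, 0.5, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Orient significant disease pairs in time
#'
#' For each unordered pair that passed the association filter, computes the
#' directionality score over patients diagnosed with both diseases within
#' the window, tests it with the exact sign test, adjusts across all tested
#' pairs (Benjamini-Hochberg, a separate family from the association stage),
#' and emits each significant pair oriented so that the score is positive
#' (source precedes target).
#'
#' @param timelines A timeline tibble.
#' @param pairs Tibble of unordered pairs with columns `disease_i`,
#'   `disease_j` (e.g. the output of [significant_pairs()]).
#' @param window_days Maximum inter-diagnosis interval (default 365).
#' @param fdr FDR threshold on the sign-test q-value (default 0.1).
#' @return Tibble of directed pairs: `source`, `target`, `n_total`,
#'   `n_forward` (patients with source strictly before target), `delta`,
#'   `p_value`, `q_value`, `interval_mean`, `interval_sd` (sample SD over
#'   forward-ordered patients' gaps), `patient_count` (= `n_forward`).
#'   Pairs with q-value at or above `fdr`, score zero, or no ordered
#'   patients are dropped.
#' @export
directed_pairs <- function(timelines, pairs, window_days = 365, fdr = 0.1) {
  empty <- tibble::tibble(
    source = character(), target = character(), n_total = integer(),
    n_forward = integer(), delta = double(), p_value = double(),
    q_value = double(), interval_mean = double(), interval_sd = double(),
    patient_count = integer()
  )
  if (nrow(pairs) == 0) return(empty)
  tl <- dplyr::select(timelines, "patient_id", "code", "first_day")
  per_patient <- pairs |>
    dplyr::select("disease_i", "disease_j") |>
    dplyr::inner_join(dplyr::rename(tl, disease_i = "code", day_i = "first_day"),
                      by = "disease_i", relationship = "many-to-many") |>
    dplyr::inner_join(dplyr::rename(tl, disease_j = "code", day_j = "first_day"),
                      by = c("disease_j", "patient_id")) |>
    dplyr::mutate(gap = abs(.data$day_i - .data$day_j)) |>
    dplyr::filter(.data$gap <= window_days, .data$day_i != .data$day_j)
  if (nrow(per_patient) == 0) return(empty)
  stats_tbl <- per_patient |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_forward = sum(.data$day_i < .data$day_j),
      fwd_mean = mean(.data$gap[.data$day_i < .data$day_j]),
      fwd_sd = stats::sd(.data$gap[.data$day_i < .data$day_j]),
      rev_mean = mean(.data$gap[.data$day_i > .data$day_j]),
      rev_sd = stats::sd(.data$gap[.data$day_i > .data$day_j]),
      .by = c("disease_i", "disease_j")
    ) |>
    dplyr::mutate(
      delta = (2 * .data$n_forward - .data$n_total) / .data$n_total,
      p_value = sign_test(.data$n_forward, .data$n_total),
      q_value = bh_adjust(.data$p_value)
    )
  # orient so delta > 0: swap source/target (and tail stats) where delta < 0
  stats_tbl |>
    dplyr::mutate(
      flip = .data$delta < 0,
      source = ifelse(.data$flip, .data$disease_j, .data$disease_i),
      target = ifelse(.data$flip, .data$disease_i, .data$disease_j),
      n_forward = ifelse(.data$flip, .data$n_total - .data$n_forward,
                         .data$n_forward),
      delta = abs(.data$delta),
      interval_mean = ifelse(.data$flip, .data$rev_mean, .data$fwd_mean),
      interval_sd = ifelse(.data$flip, .data$rev_sd, .data$fwd_sd)
    ) |>
    dplyr::filter(.data$q_value < fdr, .data$delta != 0) |>
    dplyr::mutate(patient_count = as.integer(.data$n_forward)) |>
    dplyr::select("source", "target", "n_total", "n_forward", "delta",
                  "p_value", "q_value", "interval_mean", "interval_sd",
                  "patient_count") |>
    dplyr::arrange(dplyr::desc(.data$patient_count), .data$source,
                   .data$target)
}
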