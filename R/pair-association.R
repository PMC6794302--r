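#' Count patient-level disease incidences
#'
#' @param timelines A timeline tibble from [build_timelines()].
#' @param n_total Cohort size N. Defaults to the number of distinct patients
#'   in `timelines`; pass the merged-registry patient count when some cohort
#'   members have no disease-coded admission (see [prepare_timelines()]).
#' @return A list with `incidence` (tibble: `code`, `incidence` = number of
#'   patients ever first-diagnosed with that code) and `n_total`.
#' @export
count_incidences <- function(timelines, n_total = NULL) {
  inc <- dplyr::count(timelines, .data$code, name = "incidence")
  n <- dplyr::n_distinct(timelines$patient_id)
  if (is.null(n_total)) n_total <- n
  if (n_total < n) {
    rlang::abort("n_total is smaller than the number of patients in timelines",
                 class = "trajmine_config_error")
  }
  list(incidence = inc, n_total = as.integer(n_total))
}

#' Count windowed disease-pair co-occurrences
#'
#' A patient co-occurs for the unordered pair (i, j) when both diseases
#' appear in the patient's timeline and the two first-diagnosis days lie
#' within `window_days` of each other (boundary inclusive).
#'
#' @inheritParams count_incidences
#' @param window_days Co-occurrence window in days (default 365, one year);
#'   `Inf` counts every co-diagnosed patient regardless of interval.
#' @return Tibble with columns `disease_i`, `disease_j` (i < j lexically)
#'   and `c_ij`. Pairs with zero co-occurring patients are omitted.
#' @export
count_cooccurrence <- function(timelines, window_days = 365) {
  tl <- dplyr::select(timelines, "patient_id", "code", "first_day")
  joined <- dplyr::inner_join(tl, tl, by = "patient_id",
                              relationship = "many-to-many",
                              suffix = c("_i", "_j"))
  joined <- dplyr::filter(
    joined,
    .data$code_i < .data$code_j,
    is.infinite(window_days) |
      abs(.data$first_day_i - .data$first_day_j) <= window_days
  )
  joined |>
    dplyr::count(disease_i = .data$code_i, disease_j = .data$code_j,
                 name = "c_ij")
}

#' Relative association of a disease pair
#'
#' RA compares the observed number of co-diagnosed patients `C_ij` with its
#' random expectation `C* = I_i * I_j / N`:
#' `RA = C_ij / C* = C_ij * N / (I_i * I_j)`.
#' RA > 1 means the two diseases are co-diagnosed more often than expected
#' by chance under independence.
#'
#' @param c_ij Observed co-occurrence count(s).
#' @param i_i,i_j Patient-level incidence counts of the two diseases.
#' @param n_total Cohort size N.
#' @return Numeric RA value(s).
#' @export
#' @examples
#' relative_association(4, 10, 20, 100) # = 2
relative_association <- function(c_ij, i_i, i_j, n_total) {
  if (any(i_i <= 0) || any(i_j <= 0) || any(n_total <= 0)) {
    rlang::abort("RA undefined for zero incidence or empty cohort",
                 class = "trajmine_stat_error")
  }
  c_ij * n_total / (i_i * i_j)
}

#' One-sided binomial tail probability for a co-occurrence count
#'
#' Upper-tail probability P(X >= c_ij) for X ~ Binomial(n, p0), with
#' `p0 = (I_i/N) * (I_j/N)` the chance co-diagnosis probability. One-sided,
#' since only excess co-occurrence (RA > 1) is ever selected.
#'
#' @param c_ij Observed count(s).
#' @param n Number of trials (cohort size).
#' @param p0 Null co-diagnosis probability.
#' @return P-value(s).
#' @export
binomial_pvalue <- function(c_ij, n, p0) {
  if (any(p0 < 0 | p0 > 1)) {
    rlang::abort("p0 must lie in [0, 1]", class = "trajmine_stat_error")
  }
  stats::pbinom(c_ij - 1, n, p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Vector of p-values.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Relative-association statistics for all disease pairs
#'
#' Computes, for every unordered pair of diseases with positive incidence,
#' the windowed co-occurrence count, the RA statistic, its one-sided binomial
#' p-value and the Benjamini-Hochberg q-value (one family over all tested
#' pairs).
#'
#' @inheritParams count_incidences
#' @inheritParams count_cooccurrence
#' @return A tibble with one row per unordered pair (`disease_i` <
#'   `disease_j`): `i_i`, `i_j`, `n`, `c_ij`, `c_star`, `ra`, `p_value`,
#'   `q_value`.
#' @export
pair_associations <- function(timelines, window_days = 365, n_total = NULL) {
  counts <- count_incidences(timelines, n_total)
  inc <- counts$incidence
  n <- counts$n_total
  codes <- sort(inc$code)
  if (length(codes) < 2) {
    return(tibble::tibble(
      disease_i = character(), disease_j = character(), i_i = integer(),
      i_j = integer(), n = integer(), c_ij = integer(), c_star = double(),
      ra = double(), p_value = double(), q_value = double()
    ))
  }
  pairs <- tidyr::expand_grid(disease_i = codes, disease_j = codes) |>
    dplyr::filter(.data$disease_i < .data$disease_j)
  co <- count_cooccurrence(timelines, window_days)
  pairs |>
    dplyr::left_join(co, by = c("disease_i", "disease_j")) |>
    dplyr::mutate(c_ij = dplyr::coalesce(.data$c_ij, 0L)) |>
    dplyr::left_join(dplyr::rename(inc, disease_i = "code", i_i = "incidence"),
                     by = "disease_i") |>
    dplyr::left_join(dplyr::rename(inc, disease_j = "code", i_j = "incidence"),
                     by = "disease_j") |>
    dplyr::mutate(
      n = n,
      c_star = .data$i_i * .data$i_j / .data$n,
      ra = relative_association(.data$c_ij, .data$i_i, .data$i_j, .data$n),
      p_value = binomial_pvalue(.data$c_ij, .data$n,
                                (.data$i_i / .data$n) * (.data$i_j / .data$n)),
      q_value = bh_adjust(.data$p_value)
    ) |>
    dplyr::select("disease_i", "disease_j", "i_i", "i_j", "n", "c_ij",
                  "c_star", "ra", "p_value", "q_value")
}

#' Select significant disease-pair associations
#'
#' Retains pairs co-occurring more than expected by chance (RA above
#' `ra_min`) at the stated false discovery rate.
#'
#' @param stats Pair-statistic tibble from [pair_associations()].
#' @param ra_min RA threshold (strict; default 1).
#' @param fdr FDR threshold on the q-value (strict; default 0.1).
#' @return The filtered tibble.
#' @export
significant_pairs <- function(stats, ra_min = 1, fdr = 0.1) {
  dplyr::filter(stats, .data$ra > ra_min, .data$q_value < fdr)
}
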