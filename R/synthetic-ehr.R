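#' Default three-digit disease codes for simulations
#'
#' Twenty real ICD-9-CM chapter codes spanning the cardiovascular,
#' respiratory, hepatic, infectious, psychiatric and musculoskeletal
#' conditions that dominate inpatient registries (e.g. 295 schizophrenic
#' disorders, 296 episodic mood disorders, 410 acute myocardial infarction,
#' 428 heart failure, 038 septicemia, 571 chronic liver disease, 728
#' disorders of muscle/ligament/fascia).
#'
#' @return Character vector of codes.
#' @export
default_disease_codes <- function() {
  c("038", "250", "295", "296", "401", "410", "414", "428", "486", "496",
    "507", "518", "571", "572", "574", "577", "585", "682", "728", "730")
}

#' Declare a planted directed disease-pair effect
#'
#' @param source,target Three-digit disease codes.
#' @param lift Multiplicative excess co-occurrence: the probability that a
#'   patient has both diseases is `lift` times the product of the marginals.
#' @param interval_mean,interval_sd Mean and SD (days) of the truncated-normal
#'   inter-diagnosis interval (truncated at >= 1 day). Defaults mirror the
#'   scale typical of within-year readmission intervals (114.9 +/- 84.3 days).
#' @param direction_prob Probability that the source diagnosis precedes the
#'   target in a co-diagnosed patient; 0.5 means no temporal preference.
#' @return One-row tibble; bind rows to plant several pairs.
#' @export
planted_pair <- function(source, target, lift,
                         interval_mean = 114.9, interval_sd = 84.3,
                         direction_prob = 0.9) {
  tibble::tibble(
    source = as.character(source), target = as.character(target),
    lift = lift, interval_mean = interval_mean, interval_sd = interval_sd,
    direction_prob = direction_prob
  )
}

#' Simulation configuration for a synthetic admission registry
#'
#' Describes a multi-edition longitudinal inpatient registry: per-disease
#' baseline admission probabilities, planted disease-pair effects with a
#' configurable inter-diagnosis interval distribution and temporal
#' direction, per-code in-hospital death hazards, non-disease (pregnancy /
#' injury / E / V coded) admissions to exercise chapter filtering, and the
#' edition structure in which earlier editions contain only deceased
#' patients.
#'
#' @param n_patients Number of patients in the cohort.
#' @param disease_codes Three-digit codes in play.
#' @param baseline_rates Per-patient probability of ever being admitted for
#'   each code; scalar or named vector (default 0.05 for every code).
#' @param planted_pairs Tibble of planted effects (see [planted_pair()]);
#'   `NULL` for a null registry. A code may be the target of at most one
#'   planted pair.
#' @param death_hazard Probability of in-hospital death at a patient's last
#'   admission, by its principal code; scalar or named vector (default 0.2,
#'   giving roughly the ~20% patient-level death fraction of large inpatient
#'   registries).
#' @param n_editions Number of annual registry editions (labelled as years
#'   ending 2010, e.g. 2006..2010 for five).
#' @param deceased_only_backfill If `TRUE` (default), patients assigned to an
#'   edition before the latest are flagged deceased, so editions partition
#'   the cohort the way a deceased-only merge expects.
#' @param nondisease_fraction Fraction of admissions carrying a non-disease
#'   principal code (default 0.1). Every patient with no disease admission
#'   additionally receives one non-disease admission, so all cohort members
#'   appear in the registry.
#' @param study_window_days Length of the observation window (default 7300
#'   days, ~20 years); admission days for unrelated diseases are uniform
#'   over it.
#' @param latest_edition_share Probability a patient belongs to the latest
#'   edition (default 0.8).
#' @param seed Integer seed; the whole registry is a deterministic function
#'   of the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 10000,
                       disease_codes = default_disease_codes(),
                       baseline_rates = 0.05,
                       planted_pairs = NULL,
                       death_hazard = 0.2,
                       n_editions = 5,
                       deceased_only_backfill = TRUE,
                       nondisease_fraction = 0.1,
                       study_window_days = 7300,
                       latest_edition_share = 0.8,
                       seed = 1) {
  disease_codes <- as.character(disease_codes)
  rates <- expand_named(baseline_rates, disease_codes, "baseline_rates")
  hazard <- expand_named(death_hazard, disease_codes, "death_hazard")
  if (is.null(planted_pairs)) {
    planted_pairs <- planted_pair(character(), character(), double())
  }
  stopifnot(
    n_patients >= 1, n_editions >= 1,
    all(rates >= 0 & rates <= 1),
    all(hazard >= 0 & hazard <= 1),
    nondisease_fraction >= 0, nondisease_fraction < 1,
    latest_edition_share > 0, latest_edition_share <= 1,
    study_window_days >= 2
  )
  if (nrow(planted_pairs) > 0) {
    if (!all(c(planted_pairs$source, planted_pairs$target) %in% disease_codes)) {
      rlang::abort("planted pair codes must be drawn from disease_codes",
                   class = "trajmine_config_error")
    }
    stopifnot(
      all(planted_pairs$lift > 0),
      all(planted_pairs$interval_sd >= 0),
      all(planted_pairs$direction_prob >= 0 & planted_pairs$direction_prob <= 1)
    )
    if (anyDuplicated(planted_pairs$target) > 0) {
      rlang::abort("a code may be the target of at most one planted pair",
                   class = "trajmine_config_error")
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients), disease_codes = disease_codes,
      baseline_rates = rates, planted_pairs = planted_pairs,
      death_hazard = hazard, n_editions = as.integer(n_editions),
      deceased_only_backfill = deceased_only_backfill,
      nondisease_fraction = nondisease_fraction,
      study_window_days = as.integer(study_window_days),
      latest_edition_share = latest_edition_share,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

expand_named <- function(x, codes, what) {
  if (length(x) == 1 && is.null(names(x))) {
    return(stats::setNames(rep(as.double(x), length(codes)), codes))
  }
  if (!all(codes %in% names(x))) {
    rlang::abort(paste0(what, " must name every disease code"),
                 class = "trajmine_config_error")
  }
  as.double(x)[codes] |> stats::setNames(codes)
}

# truncated-normal draw (>= lo) by rejection; mean/sd on the untruncated scale
draw_interval <- function(n, mean, sd, lo = 1) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo]
  }
  round(out)
}

nondisease_code_pool <- function() {
  c("650", "664", "V58", "V20", "E850", "E880", "800", "850", "960", "999")
}

#' Generate a synthetic admission registry
#'
#' Samples a cohort according to a [sim_config()]: each disease is a
#' Bernoulli draw at its baseline rate, planted pairs couple the target's
#' membership to the source's so that the joint probability equals
#' `lift x marginal_i x marginal_j` (capped at 1, with a warning naming the
#' pair when the cap binds) while the target's marginal is preserved;
#' co-diagnosed planted patients get an inter-diagnosis gap from the stated
#' truncated-normal distribution, ordered source-first with probability
#' `direction_prob`; all other admission days are uniform over the study
#' window. Death is attached to a patient's last admission with the hazard
#' of its principal code, and is forced for patients assigned to earlier
#' editions when `deceased_only_backfill` is set. Principal codes carry a
#' random sub-classification decimal (e.g. "728.88") on a fraction of
#' admissions, and secondary diagnosis codes are appended, so three-digit
#' rounding and principal-diagnosis selection are exercised downstream.
#'
#' @param config A [sim_config()].
#' @return An admission tibble (see [admissions]). Byte-identical for an
#'   identical configuration.
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  codes <- config$disease_codes
  np <- length(codes)
  rates <- config$baseline_rates
  w <- config$study_window_days

  present <- matrix(stats::runif(n * np), n, np) <
    matrix(rates, n, np, byrow = TRUE)
  colnames(present) <- codes

  pp <- config$planted_pairs
  if (nrow(pp) > 0) {
    for (k in seq_len(nrow(pp))) {
      i <- pp$source[k]; j <- pp$target[k]
      p_i <- rates[i]; p_j <- rates[j]
      p_cond <- pp$lift[k] * p_j
      if (p_cond > 1) {
        rlang::warn(paste0("planted pair ", i, " -> ", j,
                           ": lift x rate exceeds 1; capped"))
        p_cond <- 1
      }
      p_rest <- if (p_i < 1) max(0, (p_j - p_i * p_cond) / (1 - p_i)) else 0
      u <- stats::runif(n)
      present[, j] <- ifelse(present[, i], u < p_cond, u < p_rest)
    }
  }

  day <- matrix(NA_integer_, n, np, dimnames = list(NULL, codes))
  n_present <- sum(present)
  day[present] <- sample.int(w + 1L, n_present, replace = TRUE) - 1L

  if (nrow(pp) > 0) {
    for (k in seq_len(nrow(pp))) {
      i <- pp$source[k]; j <- pp$target[k]
      both <- which(present[, i] & present[, j])
      if (length(both) == 0) next
      gap <- pmin(draw_interval(length(both), pp$interval_mean[k],
                                pp$interval_sd[k]), w - 1L)
      forward <- stats::runif(length(both)) < pp$direction_prob[k]
      di <- day[both, i]
      dj <- di + ifelse(forward, gap, -gap)
      # shift pairs that fall outside the window back in, keeping the gap
      shift <- pmax(0, -pmin(di, dj)) - pmax(0, pmax(di, dj) - w)
      day[both, i] <- as.integer(di + shift)
      day[both, j] <- as.integer(dj + shift)
    }
  }

  idx <- which(present, arr.ind = TRUE)
  adm <- tibble::tibble(
    patient = idx[, 1],
    code = codes[idx[, 2]],
    day = day[idx]
  )

  # non-disease admissions: a configured fraction of all admissions, plus one
  # for every patient with no disease admission (an inpatient registry only
  # contains admitted patients)
  f <- config$nondisease_fraction
  n_extra <- if (f > 0) round(f / (1 - f) * nrow(adm)) else 0L
  no_disease <- setdiff(seq_len(n), unique(adm$patient))
  extra_pat <- c(
    if (n_extra > 0) sample.int(n, n_extra, replace = TRUE),
    no_disease
  )
  if (length(extra_pat) > 0) {
    adm <- dplyr::bind_rows(adm, tibble::tibble(
      patient = extra_pat,
      code = sample(nondisease_code_pool(), length(extra_pat), replace = TRUE),
      day = sample.int(w + 1L, length(extra_pat), replace = TRUE) - 1L
    ))
  }

  # sub-classification decimals on a fraction of principal codes
  deco <- stats::runif(nrow(adm)) < 0.3
  sub <- sample(0:99, nrow(adm), replace = TRUE)
  is_e <- startsWith(adm$code, "E")
  adm$principal <- ifelse(
    deco & !is_e, paste0(adm$code, ".", sub),
    ifelse(deco & is_e, paste0(adm$code, ".", sub %% 10), adm$code)
  )

  # secondary diagnosis codes (ignored downstream, exercise principal pick)
  n_sec <- sample(0:2, nrow(adm), replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
  sec_codes <- sample(codes, sum(n_sec), replace = TRUE)
  sec_split <- split(sec_codes, rep(seq_len(nrow(adm)), n_sec))
  dx <- as.list(adm$principal)
  if (length(sec_split) > 0) {
    pos <- as.integer(names(sec_split))
    dx[pos] <- Map(c, adm$principal[pos], sec_split)
  }
  adm$diagnosis_codes <- dx

  # editions: one per patient; earlier editions are deceased-only when the
  # backfill flag is set
  ed_labels <- as.character(seq(2011 - config$n_editions, 2010))
  latest <- ed_labels[config$n_editions]
  ed_of_patient <- if (config$n_editions == 1) {
    rep(latest, n)
  } else {
    ifelse(stats::runif(n) < config$latest_edition_share, latest,
           sample(ed_labels[-config$n_editions], n, replace = TRUE))
  }

  # death at the last admission, by that admission's principal code hazard
  adm <- dplyr::arrange(adm, .data$patient, .data$day)
  last_row <- !duplicated(adm$patient, fromLast = TRUE)
  hazard <- unname(config$death_hazard[adm$code])
  hazard[is.na(hazard)] <- 0
  dies <- stats::runif(nrow(adm)) < hazard
  forced <- config$deceased_only_backfill &
    ed_of_patient[adm$patient] != latest
  adm$died_in_hospital <- last_row & (dies | forced)

  age_base <- pmin(95, pmax(18, stats::rnorm(n, 55, 19.6)))
  adm$age_years <- round(age_base[adm$patient] + adm$day / 365.25, 1)

  out <- tibble::tibble(
    patient_id = sprintf("P%07d", adm$patient),
    edition_id = ed_of_patient[adm$patient],
    admission_day = as.integer(adm$day),
    diagnosis_codes = adm$diagnosis_codes,
    died_in_hospital = adm$died_in_hospital,
    age_years = adm$age_years
  )
  out <- dplyr::arrange(out, .data$edition_id, .data$patient_id,
                        .data$admission_day)
  validate_admissions(out)
  out
}

#' Planted ground truth of a simulation configuration
#'
#' Returns, for every ordered pair of configured disease codes, the planted
#' lift and direction probability: non-planted pairs have lift 1 and
#' direction probability 0.5; the reverse of a planted pair has the same
#' lift and the complementary direction probability.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `source`, `target`, `lift`, `direction_prob`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  codes <- config$disease_codes
  all_pairs <- tidyr::expand_grid(source = codes, target = codes) |>
    dplyr::filter(.data$source != .data$target) |>
    dplyr::mutate(lift = 1, direction_prob = 0.5)
  pp <- config$planted_pairs
  if (nrow(pp) == 0) return(all_pairs)
  planted <- dplyr::bind_rows(
    dplyr::select(pp, "source", "target", "lift", "direction_prob"),
    dplyr::tibble(
      source = pp$target, target = pp$source, lift = pp$lift,
      direction_prob = 1 - pp$direction_prob
    )
  )
  all_pairs |>
    dplyr::rows_update(planted, by = c("source", "target"))
}
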