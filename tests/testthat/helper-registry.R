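# Quick builders for hand-crafted fixtures.

make_admissions <- function(pid, day, dx, died = FALSE, edition = "2010",
                            age = 60) {
  n <- max(length(pid), length(day), length(dx))
  as_admissions(tibble::tibble(
    patient_id = rep_len(as.character(pid), n),
    edition_id = rep_len(as.character(edition), n),
    admission_day = rep_len(as.integer(day), n),
    diagnosis_codes = rep_len(as.character(dx), n),
    died_in_hospital = rep_len(died, n),
    age_years = rep_len(age, n)
  ))
}

# timeline tibble straight from (patient, code, day) triples
make_timelines <- function(pid, code, day, death_day = NA_integer_,
                           age = 60) {
  tl <- tibble::tibble(
    patient_id = as.character(pid),
    code = as.character(code),
    first_day = as.integer(day),
    age = rep_len(age, length(pid))
  )
  dd <- tibble::tibble(
    patient_id = unique(tl$patient_id),
    death_day = rep_len(as.integer(death_day), length(unique(tl$patient_id)))
  )
  dplyr::left_join(tl, dd, by = "patient_id")
}

# a timeline set where `n_fwd` of `n_tot` patients have i (day 0) before j
# (day 100), and the rest the reverse
two_code_timelines <- function(n_fwd, n_tot, i = "295", j = "728") {
  pid <- sprintf("p%03d", seq_len(n_tot))
  fwd <- seq_len(n_tot) <= n_fwd
  make_timelines(
    pid = rep(pid, each = 2),
    code = rep(c(i, j), n_tot),
    day = as.vector(rbind(ifelse(fwd, 0L, 100L), ifelse(fwd, 100L, 0L)))
  )
}

# small random registry for greedy-vs-exhaustive checks: every patient gets
# 1..n_codes diseases at random days inside a 3-year window so multi-step
# paths actually occur
random_small_registry <- function(seed, n_patients = 200, n_codes = 6) {
  set.seed(seed)
  codes <- sample(default_disease_codes(), n_codes)
  rows <- lapply(seq_len(n_patients), function(p) {
    k <- sample.int(n_codes, 1)
    mine <- sample(codes, k)
    tibble::tibble(
      patient_id = sprintf("p%04d", p),
      code = mine,
      first_day = sort(sample.int(1100, k)) - 1L,
      age = round(runif(1, 30, 90), 1)
    )
  })
  tl <- dplyr::bind_rows(rows)
  deaths <- tibble::tibble(
    patient_id = sprintf("p%04d", seq_len(n_patients)),
    death_day = ifelse(runif(n_patients) < 0.3,
                       sample.int(1100, n_patients) - 1L, NA_integer_)
  )
  tl <- dplyr::left_join(tl, deaths, by = "patient_id")
  # keep death terminal: drop diagnoses after the death day
  tl[is.na(tl$death_day) | tl$first_day <= tl$death_day, ]
}

# orient every pair with at least one ordered patient by majority vote,
# without any significance filtering (exercises the builder directly)
majority_directed_pairs <- function(timelines, window_days = 365) {
  codes <- sort(unique(timelines$code))
  out <- list()
  for (i in seq_along(codes)) {
    for (j in seq_along(codes)) {
      if (i >= j) next
      ind <- order_indicator(timelines, codes[i], codes[j], window_days)
      if (nrow(ind) == 0) next
      d <- mean(ind$d)
      if (d == 0) next
      fwd <- if (d > 0) c(codes[i], codes[j]) else c(codes[j], codes[i])
      out[[length(out) + 1]] <- tibble::tibble(
        source = fwd[1], target = fwd[2],
        n_total = nrow(ind),
        n_forward = max(sum(ind$d == 1), sum(ind$d == -1)),
        delta = abs(d),
        patient_count = max(sum(ind$d == 1), sum(ind$d == -1))
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(source = character(), target = character(),
                          n_total = integer(), n_forward = integer(),
                          delta = double(), patient_count = integer()))
  }
  dplyr::bind_rows(out)
}
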