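#' Relative risk from a 2x2 table
#'
#' For exposed/unexposed groups with counts `a` (exposed, outcome), `b`
#' (exposed, no outcome), `c` (unexposed, outcome), `d` (unexposed, no
#' outcome): `RR = (a/(a+b)) / (c/(c+d))`. The confidence interval uses the
#' log-RR normal (Wald) approximation with standard error
#' `sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`, and the p-value is the two-sided
#' normal test of log RR against 0.
#'
#' @param a,b,c,d Cell counts.
#' @param ci_level Confidence level (default 0.95).
#' @param correction Add 0.5 to every cell (Haldane-Anscombe) when a zero
#'   cell would make RR or its CI undefined. Off by default; without it a
#'   zero in `a` or `c` aborts.
#' @return One-row tibble: `rr`, `ci_low`, `ci_high`, `p_value`.
#' @export
#' @examples
#' relative_risk(10, 90, 5, 95) # RR = 2
relative_risk <- function(a, b, c, d, ci_level = 0.95, correction = FALSE) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b > 0, c + d > 0)
  if (correction && (a == 0 || c == 0 || b == 0 || d == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  if (a == 0 || c == 0) {
    rlang::abort(
      "relative risk undefined with a zero outcome cell; see `correction`",
      class = "trajmine_stat_error"
    )
  }
  rr <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  tibble::tibble(
    rr = rr,
    ci_low = exp(log(rr) - z * se),
    ci_high = exp(log(rr) + z * se),
    p_value = 2 * stats::pnorm(-abs(log(rr)) / se)
  )
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability P(X >= k) of drawing at least `k` successes in a
#' sample of `n` from a population of `N` containing `K` successes.
#'
#' @param population Population size N.
#' @param successes_in_pop Number of successes K in the population.
#' @param sample_size Sample size n.
#' @param observed Observed successes k in the sample.
#' @return The enrichment p-value.
#' @export
#' @examples
#' hypergeom_enrichment(10, 3, 4, 2) # = 1/3
hypergeom_enrichment <- function(population, successes_in_pop, sample_size,
                                 observed) {
  if (successes_in_pop > population || sample_size > population ||
      observed > min(successes_in_pop, sample_size) || observed < 0) {
    rlang::abort("inconsistent hypergeometric counts",
                 class = "trajmine_stat_error")
  }
  stats::phyper(observed - 1, successes_in_pop,
                population - successes_in_pop, sample_size,
                lower.tail = FALSE)
}

#' Rate (and fold-change) report
#'
#' Expresses `numerator/denominator` as a percentage rounded to a chosen
#' number of decimals, optionally with the fold change of the unrounded
#' rate against a reference incidence.
#'
#' @param numerator,denominator Counts.
#' @param reference_rate Optional reference incidence (a proportion) for the
#'   fold comparison.
#' @param decimals Decimals for the reported percentage (default 1).
#' @return One-row tibble: `rate_pct` (rounded percentage) and `fold`
#'   (`NA` when no reference is given; unrounded).
#' @export
#' @examples
#' rate_report(92, 3674)                  # 2.5%
#' rate_report(92, 3674, 8e-5)$fold       # ~313
rate_report <- function(numerator, denominator, reference_rate = NULL,
                        decimals = 1) {
  if (denominator <= 0) {
    rlang::abort("denominator must be positive",
                 class = "trajmine_stat_error")
  }
  rate <- numerator / denominator
  fold <- if (is.null(reference_rate)) {
    NA_real_
  } else {
    if (reference_rate <= 0) {
      rlang::abort("reference_rate must be positive",
                   class = "trajmine_stat_error")
    }
    rate / reference_rate
  }
  tibble::tibble(rate_pct = round(100 * rate, decimals), fold = fold)
}
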