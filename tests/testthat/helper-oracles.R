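# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and pbinom/phyper tail shortcuts): plain sums over the support.

enum_binom_upper <- function(c_obs, n, p) {
  if (c_obs <= 0) return(1)
  ks <- c_obs:n
  sum(choose(n, ks) * p^ks * (1 - p)^(n - ks))
}

enum_sign_two_sided <- function(k, n) {
  pmf <- choose(n, 0:n) / 2^n
  lower <- sum(pmf[seq_len(k + 1)])
  upper <- sum(pmf[(k + 1):(n + 1)])
  min(1, 2 * min(lower, upper))
}

enum_hyper_upper <- function(N, K, n, k) {
  if (k <= 0) return(1)
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Benjamini-Hochberg step-up, straight from the definition
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Follower counting by per-patient loop, independent of the join-based path
brute_path_followers <- function(timelines, path, window_days = 365) {
  n <- 0L
  deaths <- 0L
  for (pid in unique(timelines$patient_id)) {
    sub <- timelines[timelines$patient_id == pid, ]
    days <- sub$first_day[match(path, sub$code)]
    if (anyNA(days)) next
    gaps <- diff(days)
    if (all(gaps > 0) && all(gaps <= window_days)) {
      n <- n + 1L
      dd <- sub$death_day[1]
      if (!is.na(dd) && dd >= days[length(days)]) deaths <- deaths + 1L
    }
  }
  list(n_followers = n, n_deaths = deaths)
}

# All simple paths of length >= 2 in the directed-pair graph that have at
# least one follower (exhaustive enumeration for tiny registries)
enumerate_supported_paths <- function(dpairs, timelines, window_days = 365) {
  adj <- split(dpairs$target, dpairs$source)
  out <- character()
  walk <- function(path) {
    for (tgt in adj[[path[length(path)]]]) {
      if (tgt %in% path) next
      ext <- c(path, tgt)
      if (brute_path_followers(timelines, ext, window_days)$n_followers > 0) {
        out <<- c(out, paste(ext, collapse = " -> "))
        if (!is.null(adj[[tgt]])) walk(ext)
      }
    }
  }
  for (r in unique(dpairs$source)) walk(r)
  out
}
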