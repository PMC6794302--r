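test_that("the same configuration reproduces the registry byte for byte", {
  cfg <- sim_config(n_patients = 200, seed = 11,
                    planted_pairs = planted_pair("295", "728", 2))
  r1 <- generate_registry(cfg)
  r2 <- generate_registry(cfg)
  expect_identical(r1, r2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_admissions(r1, f1); write_admissions(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("ground truth reports planted parameters and their reversals", {
  null_cfg <- sim_config(n_patients = 10, seed = 1)
  gt <- ground_truth(null_cfg)
  expect_true(all(gt$lift == 1))
  expect_true(all(gt$direction_prob == 0.5))

  cfg <- sim_config(n_patients = 10, seed = 1,
                    planted_pairs = planted_pair("295", "728", 2,
                                                 direction_prob = 0.9))
  gt <- ground_truth(cfg)
  fwd <- dplyr::filter(gt, source == "295", target == "728")
  rev <- dplyr::filter(gt, source == "728", target == "295")
  expect_equal(c(fwd$lift, fwd$direction_prob), c(2, 0.9))
  expect_equal(c(rev$lift, rev$direction_prob), c(2, 0.1))
  other <- dplyr::filter(gt, source == "038", target == "250")
  expect_equal(c(other$lift, other$direction_prob), c(1, 0.5))
})

test_that("deceased-only backfill partitions patients across editions", {
  cfg <- sim_config(n_patients = 2000, n_editions = 3, seed = 5,
                    deceased_only_backfill = TRUE)
  reg <- generate_registry(cfg)
  eds <- split(reg$patient_id, reg$edition_id)
  expect_equal(length(eds), 3)
  for (a in seq_along(eds)) {
    for (b in seq_along(eds)) {
      if (a < b) expect_length(intersect(eds[[a]], eds[[b]]), 0)
    }
  }
  early <- dplyr::filter(reg, edition_id != "2010")
  died <- dplyr::summarise(early, d = any(died_in_hospital),
                           .by = "patient_id")
  expect_true(all(died$d))
})

test_that("every cohort member appears in the registry", {
  cfg <- sim_config(n_patients = 500, baseline_rates = 0.02, seed = 9)
  reg <- generate_registry(cfg)
  expect_equal(dplyr::n_distinct(reg$patient_id), 500)
})

test_that("under independence the empirical RA of every pair is within 3 MC SE of 1", {
  codes <- c("038", "295", "296", "410", "428", "571", "585", "728")
  cfg <- sim_config(n_patients = 5000, disease_codes = codes,
                    baseline_rates = 0.15, n_editions = 1, seed = 17)
  reg <- generate_registry(cfg)
  prep <- prepare_timelines(reg)
  # full-window RA isolates the membership coupling from day placement
  stats <- pair_associations(prep$timelines, window_days = Inf,
                             n_total = prep$n_cohort)
  p0 <- (stats$i_i / stats$n) * (stats$i_j / stats$n)
  se_ra <- sqrt(stats$n * p0 * (1 - p0)) / (stats$n * p0)
  expect_equal(nrow(stats), choose(8, 2))
  expect_true(all(abs(stats$ra - 1) <= 3 * se_ra))
})

test_that("a fully directed planted pair yields order indicators of +1 only", {
  cfg <- sim_config(
    n_patients = 3000, n_editions = 1, seed = 23,
    planted_pairs = planted_pair("295", "728", 3, direction_prob = 1)
  )
  prep <- prepare_timelines(generate_registry(cfg))
  ind <- order_indicator(prep$timelines, "295", "728")
  expect_gt(nrow(ind), 10)
  expect_true(all(ind$d == 1))
  expect_equal(delta_score(ind$d), 1)
})

test_that("planted lift and direction are recovered at moderate scale", {
  cfg <- sim_config(
    n_patients = 20000, n_editions = 1, seed = 31,
    planted_pairs = planted_pair("296", "295", 2.5, direction_prob = 0.8)
  )
  prep <- prepare_timelines(generate_registry(cfg))
  stats <- pair_associations(prep$timelines, n_total = prep$n_cohort)
  pair <- dplyr::filter(stats, disease_i == "295", disease_j == "296")
  # 3 Monte-Carlo SE: SE(RA) ~ lift / sqrt(E[C]) = 2.5 / sqrt(125)
  expect_lt(abs(pair$ra - 2.5), 3 * 2.5 / sqrt(125))
  ind <- order_indicator(prep$timelines, "296", "295")
  expect_lt(abs(mean(ind$d) - 0.6), 0.15)
})

test_that("an uncappable planted probability warns naming the pair", {
  cfg <- sim_config(n_patients = 50, baseline_rates = 0.6, seed = 2,
                    planted_pairs = planted_pair("295", "728", 3))
  expect_warning(generate_registry(cfg), "295 -> 728")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(planted_pairs = planted_pair("295", "999", 2)),
               class = "trajmine_config_error")
  expect_error(sim_config(baseline_rates = 1.5))
  expect_error(sim_config(planted_pairs = dplyr::bind_rows(
    planted_pair("295", "728", 2), planted_pair("296", "728", 2)
  )), class = "trajmine_config_error")
})
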