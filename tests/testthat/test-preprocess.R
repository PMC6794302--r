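test_that("edition merge keeps the latest edition and deceased backfill only", {
  rec <- dplyr::bind_rows(
    make_admissions("A", c(0, 10), c("295", "296"), edition = "2009"),
    make_admissions("B", c(0, 10), c("295", "296"),
                    died = c(FALSE, TRUE), edition = "2009"),
    make_admissions("C", 0, "410", edition = "2010")
  )
  merged <- merge_editions(rec, latest_edition = "2010")
  expect_setequal(unique(merged$patient_id), c("B", "C"))
  # alive-only patient A is dropped entirely, both of B's records kept
  expect_equal(sum(merged$patient_id == "B"), 2)
  expect_identical(merged$edition_id[merged$patient_id == "B"],
                   c("2009", "2009"))
})

test_that("single-edition input merges to itself and unknown editions error", {
  rec <- make_admissions(c("A", "B"), c(0, 5), c("295", "296"))
  expect_equal(merge_editions(rec), rec)
  expect_error(merge_editions(rec, latest_edition = "1999"),
               class = "trajmine_config_error")
})

test_that("cross-edition duplicate patient ids are collapsed with a warning", {
  rec <- dplyr::bind_rows(
    make_admissions("A", 0, "295", died = TRUE, edition = "2009"),
    make_admissions("A", 10, "296", edition = "2010")
  )
  expect_warning(merged <- merge_editions(rec), "more than one")
  expect_equal(nrow(merged), 2)
})

test_that("principal diagnosis is the first charted code", {
  expect_identical(principal_diagnosis(list(c("295.3", "728.88"), "038")),
                   c("295.3", "038"))
  expect_error(principal_diagnosis(list(character())),
               class = "trajmine_record_error")
})

test_that("ICD-9-CM codes truncate to the three-digit level", {
  expect_identical(round_icd9("728.88"), "728")
  expect_identical(round_icd9("295"), "295")
  expect_identical(round_icd9(round_icd9("295.31")), "295") # idempotent
  expect_identical(round_icd9("V58.11"), "V58")
  expect_identical(round_icd9("E850.0"), "E850")
  expect_identical(round_icd9(c("038", "650.1")), c("038", "650"))
  expect_error(round_icd9("7288"), "7288", class = "trajmine_coding_error")
  expect_error(round_icd9("X12"), class = "trajmine_coding_error")
  expect_error(round_icd9("V5"), class = "trajmine_coding_error")
})

test_that("non-disease chapters are dropped and the filter is idempotent", {
  rec <- make_admissions(
    sprintf("p%d", 1:6), 0:5,
    c("650", "V58", "295", "800", "E850", "630")
  )
  kept <- filter_nondisease(rec)
  expect_identical(principal_diagnosis(kept), "295")
  report <- attr(kept, "filter_report")
  expect_setequal(report$category,
                  c("pregnancy", "administrative", "injury",
                    "external_causes"))
  expect_equal(sum(report$n_dropped), 5)
  # boundary codes: 629 and 680 are diseases, 679 and 999 are not
  rec2 <- make_admissions(sprintf("q%d", 1:4), 0:3,
                          c("629", "679", "680", "999"))
  expect_identical(principal_diagnosis(filter_nondisease(rec2)),
                   c("629", "680"))
  expect_equal(filter_nondisease(kept), kept, ignore_attr = TRUE)
})

test_that("timelines collapse to the first admission per disease", {
  rec <- make_admissions(
    rep("p1", 3), c(0, 100, 200), c("295", "295", "728")
  )
  tl <- build_timelines(rec)
  expect_equal(nrow(tl), 2)
  expect_equal(tl$first_day[tl$code == "295"], 0)
  expect_equal(tl$first_day[tl$code == "728"], 200)
  expect_true(all(is.na(tl$death_day)))
})

test_that("death day is the earliest death-flagged admission and is terminal", {
  rec <- make_admissions("p1", 50, "295", died = TRUE)
  tl <- build_timelines(rec)
  expect_equal(tl$death_day, 50)

  rec2 <- make_admissions(rep("p2", 3), c(0, 100, 300),
                          c("295", "410", "728"),
                          died = c(FALSE, TRUE, FALSE))
  expect_warning(tl2 <- build_timelines(rec2), "death day")
  expect_setequal(tl2$code, c("295", "410"))
  expect_true(all(tl2$death_day == 100))
})

test_that("empty record sets give empty timelines", {
  expect_equal(nrow(build_timelines(example_admissions()[0, ])), 0)
})

test_that("timeline entries never exceed a patient's admissions", {
  reg <- generate_registry(sim_config(n_patients = 300, seed = 3))
  prep <- prepare_timelines(reg)
  per_adm <- dplyr::count(prep$merged, patient_id)
  per_tl <- dplyr::count(prep$timelines, patient_id)
  joined <- dplyr::inner_join(per_tl, per_adm, by = "patient_id")
  expect_true(all(joined$n.x <= joined$n.y))
  # retained codes never intersect the excluded chapters
  expect_false(any(!is.na(trajmine:::nondisease_category(prep$timelines$code))))
})
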