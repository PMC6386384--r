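test_that("exclusion filters apply the published age, prisoner and code rules", {
  recs <- make_records(
    person_id = c("a15", "a16", "a99", "a100", "pris", "nocode", "keep"),
    age_years = c(15L, 16L, 99L, 100L, 30L, 30L, 30L),
    prisoner = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    sti_codes = c("T4", "T4", "T4", "T4", "T4", "", "T4")
  )
  out <- apply_exclusions(recs)
  expect_setequal(out$records$person_id, c("a16", "a99", "keep"))
  expect_equal(out$report$n_excluded_age, 2)
  expect_equal(out$report$n_excluded_prisoner, 1)
  expect_equal(out$report$n_excluded_no_codes, 1)
})

test_that("each excluded record is counted once, no-codes first", {
  rec <- make_record(age_years = 15L, prisoner = TRUE, sti_codes = "")
  out <- apply_exclusions(rec)
  expect_equal(out$report$n_excluded_no_codes, 1)
  expect_equal(out$report$n_excluded_age, 0)
  expect_equal(out$report$n_excluded_prisoner, 0)
  # codes in any of the three lists keep a record in
  rec2 <- make_record(sti_codes = "", repro_codes = "R1")
  expect_equal(nrow(apply_exclusions(rec2)$records), 1)
})

test_that("empty input yields an empty all-zero report", {
  out <- apply_exclusions(empty_records())
  expect_equal(nrow(out$records), 0)
  expect_true(all(unlist(out$report) == 0))
})

test_that("same-day records collapse to the de-duplicated code union", {
  recs <- make_records(person_id = c("P1", "P1"),
                       visit_date = c("2014-02-01", "2014-02-01"),
                       sti_codes = c("T4", "C4"),
                       visit_type = c("first", "followup"))
  out <- collapse_same_day(recs)
  expect_equal(nrow(out), 1)
  expect_equal(out$sti_codes, "T4;C4")
  expect_equal(out$visit_type, "first")  # non-code fields from first record

  # different days, different providers: untouched
  apart <- make_records(person_id = c("P1", "P1", "P1"),
                        visit_date = c("2014-02-01", "2014-02-02", "2014-02-02"),
                        provider_id = c("clinic_A", "clinic_A", "clinic_B"))
  expect_equal(nrow(collapse_same_day(apart)), 3)

  # identical duplicates collapse without duplicating codes
  dup <- make_records(person_id = c("P1", "P1"), sti_codes = c("T4", "T4"))
  expect_equal(collapse_same_day(dup)$sti_codes, "T4")
})

test_that("the six-week rule keeps the record with the most diagnosis codes", {
  recs <- make_records(person_id = c("P1", "P1"),
                       visit_date = c("2015-01-01", "2015-01-31"),
                       sti_codes = c("T4", "T4;C4"))
  out <- deduplicate_six_week(recs)
  expect_equal(out$records$visit_date, as.Date("2015-01-31"))
  expect_equal(out$report$n_removed_6week, 1)
})

test_that("records exactly window_days apart both survive", {
  recs <- make_records(person_id = c("P1", "P1"),
                       visit_date = c("2015-01-01", "2015-02-12"))  # day 0, 42
  out <- deduplicate_six_week(recs)
  expect_equal(nrow(out$records), 2)
  close <- make_records(person_id = c("P1", "P1"),
                        visit_date = c("2015-01-01", "2015-02-11"))  # day 41
  expect_equal(nrow(deduplicate_six_week(close)$records), 1)
})

test_that("singletons and code-free records pass through the six-week rule", {
  expect_equal(nrow(deduplicate_six_week(make_record())$records), 1)
  passthrough <- make_records(person_id = c("P1", "P1"),
                              visit_date = c("2015-01-01", "2015-01-10"),
                              sti_codes = c("", ""),
                              repro_codes = c("R1", "R1"))
  expect_equal(nrow(deduplicate_six_week(passthrough)$records), 2)
  expect_error(deduplicate_six_week(make_record(), window_days = 0),
               "positive")
})

test_that("greedy deduplication matches the brute-force oracle", {
  withr::local_seed(2024)
  for (rep in 1:300) {
    inst <- random_dedup_instance(sample(1:6, 1))
    out <- deduplicate_six_week(inst)$records
    cs <- default_code_sets()
    expected <- oracle_six_week(inst$visit_date,
                                cell_n_codes(inst$sti_codes,
                                             cs$diagnosis_codes))
    expect_equal(sort(paste(out$visit_date, out$sti_codes)),
                 sort(paste(inst$visit_date[expected],
                            inst$sti_codes[expected])))
  }
})

test_that("deduplication is idempotent and spaces retained records", {
  withr::local_seed(77)
  for (rep in 1:100) {
    inst <- random_dedup_instance(sample(2:6, 1))
    once <- deduplicate_six_week(inst)$records
    twice <- deduplicate_six_week(once)$records
    expect_equal(as.data.frame(twice), as.data.frame(once))
    expect_lte(nrow(once), nrow(inst))
    gaps <- diff(sort(as.numeric(once$visit_date)))
    expect_true(all(gaps >= 42))
  }
})

test_that("deduplication scope distinguishes provider from person", {
  recs <- make_records(person_id = c("P1", "P1"),
                       visit_date = c("2015-01-01", "2015-01-15"),
                       provider_id = c("clinic_A", "clinic_B"))
  expect_equal(nrow(deduplicate_six_week(recs, scope = "provider")$records), 2)
  expect_equal(nrow(deduplicate_six_week(recs, scope = "person")$records), 1)
})

test_that("the consolidated report satisfies its conservation identity", {
  cfg <- synthetic_config(seed = 13, n_persons = 1500)
  out <- harmonise_records(synthesize_cohort(cfg))
  r <- out$report
  expect_equal(r$n_output,
               r$n_input - r$n_excluded_no_codes - r$n_excluded_age -
                 r$n_excluded_prisoner - r$n_collapsed_same_day -
                 r$n_removed_6week)
  expect_equal(r$n_output, nrow(out$records))
  expect_gt(r$n_removed_6week, 0)  # repeat testers guarantee collisions
})
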