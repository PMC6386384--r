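test_that("visit classification follows the code-set semantics", {
  cases <- list(
    list(codes = "T4", test = TRUE, diag = FALSE,
         cx = "simple", site = "genital"),
    list(codes = "T4;TREAT", test = TRUE, diag = FALSE,
         cx = "complex", site = "genital"),
    list(codes = "TT", test = TRUE, diag = FALSE,
         cx = "simple", site = "triple_site"),
    list(codes = "TT;C4;EXAM", test = TRUE, diag = TRUE,
         cx = "complex", site = "triple_site"),
    list(codes = "C4", test = FALSE, diag = TRUE,
         cx = "simple", site = "genital"),   # diagnosis-only attendance
    list(codes = "", test = FALSE, diag = FALSE,
         cx = "simple", site = "genital")
  )
  for (cs in cases) {
    v <- classify_visit(make_record(sti_codes = cs$codes))
    expect_equal(v$has_test, cs$test, info = cs$codes)
    expect_equal(v$has_diagnosis, cs$diag, info = cs$codes)
    expect_equal(v$complexity, cs$cx, info = cs$codes)
    expect_equal(v$site_scope, cs$site, info = cs$codes)
  }
})

test_that("online visits are always simple; repro codes can make clinic visits complex", {
  online <- classify_visit(make_record(setting = "online",
                                       provider_id = "online_service",
                                       sti_codes = "T4;C4"))
  expect_equal(online$complexity, "simple")
  repro <- classify_visit(make_record(sti_codes = "T4", repro_codes = "R1"))
  expect_equal(repro$complexity, "complex")
})

test_that("treatment-elsewhere codes never count as diagnoses", {
  cs <- default_code_sets(treatment_elsewhere_codes = "TE")
  v <- classify_visit(make_record(sti_codes = "TE"), cs)
  expect_false(v$has_diagnosis)
  expect_false(v$has_test)
  # ... and such records pass through the six-week rule untouched
  recs <- make_records(person_id = c("P1", "P1"),
                       visit_date = c("2015-01-01", "2015-01-05"),
                       sti_codes = c("TE", "TE"))
  expect_equal(nrow(deduplicate_six_week(recs, cs)$records), 2)
})

quarter_fixture <- function() {
  make_records(
    person_id = sprintf("P%d", 1:7),
    visit_date = c("2014-01-10", "2014-02-10", "2014-03-01",
                   "2014-01-20", "2015-05-05", "2015-06-06", "2015-05-30"),
    setting = c(rep("gum_clinic", 4), rep("online", 3)),
    provider_id = c(rep("clinic_A", 4), rep("online_service", 3)),
    sti_codes = c("T4;A1", "T4", "C4", "T4;TREAT", "T4", "T4;C4", "T4")
  )
}

test_that("quarterly summaries count tests-or-diagnoses and diagnoses per setting", {
  q <- quarterly_summaries(quarter_fixture())
  q1c <- q[q$quarter == "2014-Q1" & q$setting_group == "clinic", ]
  expect_equal(q1c$n_tests_or_diagnoses, 4)  # diagnosis-only record included
  expect_equal(q1c$n_diagnoses, 2)
  expect_equal(q1c$positivity, 0.5)
  q2o <- q[q$quarter == "2015-Q2" & q$setting_group == "online", ]
  expect_equal(q2o$n_tests_or_diagnoses, 3)
  expect_equal(q2o$n_diagnoses, 1)
  # pooled consistency: all = clinic + online, per quarter
  for (qt in unique(q$quarter)) {
    parts <- q[q$quarter == qt & q$setting_group != "all", ]
    all_row <- q[q$quarter == qt & q$setting_group == "all", ]
    expect_equal(all_row$n_diagnoses, sum(parts$n_diagnoses))
    expect_equal(all_row$n_tests_or_diagnoses,
                 sum(parts$n_tests_or_diagnoses))
  }
})

test_that("positivity is zero with zero diagnoses and invariant to row order", {
  none <- make_records(person_id = c("P1", "P2"), sti_codes = c("T4", "TT"))
  q <- quarterly_summaries(none)
  expect_true(all(q$positivity == 0))

  fx <- quarter_fixture()
  shuffled <- fx[rev(seq_len(nrow(fx))), ]
  expect_equal(quarterly_summaries(fx), quarterly_summaries(shuffled))
})

test_that("order-only dispatch events never enter the positivity denominator", {
  fx <- quarter_fixture()
  fx$ordered_only <- FALSE
  dispatch <- make_record(person_id = "U1", visit_date = "2015-05-10",
                          setting = "online", provider_id = "online_service",
                          sti_codes = "T4")
  dispatch$ordered_only <- TRUE
  q <- quarterly_summaries(rbind(fx, dispatch))
  expect_equal(q$n_tests_or_diagnoses[q$quarter == "2015-Q2" &
                                        q$setting_group == "online"], 3)
})

test_that("online share reproduces the printed-count ratio", {
  q <- tibble::tibble(
    quarter = rep("2016-Q2", 2),
    setting_group = c("clinic", "online"),
    n_tests_or_diagnoses = c(10024L, 3414L),
    n_diagnoses = c(948L, 230L),
    positivity = c(948 / 10024, 230 / 3414)
  )
  expect_equal(round(100 * online_share(q, "2016-Q2"), 1), 25.4)
  q$n_tests_or_diagnoses <- c(10024L, 0L)
  expect_equal(online_share(q, "2016-Q2"), 0)
  q$n_tests_or_diagnoses <- c(0L, 3414L)
  expect_equal(online_share(q, "2016-Q2"), 1)
  expect_error(online_share(q, "2030-Q1"), "quarter")
})

test_that("percent change is the plain relative difference", {
  expect_equal(percent_change(100, 50), -50)
  expect_equal(percent_change(7, 7), 0)
  expect_error(percent_change(0, 10), "positive baseline")
})
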