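# Visit classification and per-quarter testing/positivity summaries.
#
# Positivity is the composite over chlamydia, gonorrhoea, syphilis and HIV:
# records carrying at least one diagnosis code, divided by records carrying
# at least one test or diagnosis code (diagnosis-only attendances, e.g.
# diagnoses made from symptoms or microscopy without a simple test, stay in
# the denominator). Treatment-elsewhere codes never count as diagnoses.

#' Classify harmonised visits
#'
#' Adds the derived labels used by costing and positivity:
#' * `has_test` - any STI code in the test set;
#' * `has_diagnosis` - any STI code in the diagnosis set (treatment-elsewhere
#'   codes excluded);
#' * `complexity` - `"complex"` when any code across the STI, reproductive
#'   or contraception lists falls outside the test and diagnosis sets
#'   (treatment or examination alongside testing); online visits are always
#'   `"simple"` since no other service is delivered online;
#' * `site_scope` - `"triple_site"` when the TT code is present (genital,
#'   rectal and oral sampling for MSM), else `"genital"`.
#'
#' @param records harmonised attendance records.
#' @param code_sets a [default_code_sets()] object.
#' @return `records` with the four classification columns appended.
#' @export
classify_visits <- function(records, code_sets = default_code_sets()) {
  ts <- code_sets$test_codes
  ds <- code_sets$diagnosis_codes
  non_diag <- code_sets$treatment_elsewhere_codes
  ds_eff <- setdiff(ds, non_diag)
  records$has_test <- cell_has_code(records$sti_codes, ts)
  records$has_diagnosis <- cell_has_code(records$sti_codes, ds_eff)
  all_codes <- paste(records$sti_codes, records$repro_codes,
                     records$contraception_codes, sep = ";")
  fl <- flatten_cells(all_codes)
  other <- logical(fl$n)
  other[fl$row[!code_in_set(fl$code, c(ts, ds))]] <- TRUE
  records$complexity <- ifelse(records$setting == "online", "simple",
                               ifelse(other, "complex", "simple"))
  records$site_scope <- ifelse(
    cell_has_code(records$sti_codes, code_sets$triple_site_code),
    "triple_site", "genital")
  records
}

#' Classify a single visit
#'
#' Scalar wrapper around [classify_visits()] for a one-row record.
#'
#' @param record a one-row record tibble.
#' @inheritParams classify_visits
#' @return A list with `has_test`, `has_diagnosis`, `complexity`,
#'   `site_scope` and `setting`.
#' @export
classify_visit <- function(record, code_sets = default_code_sets()) {
  stopifnot(nrow(record) == 1)
  x <- classify_visits(record, code_sets)
  list(has_test = x$has_test, has_diagnosis = x$has_diagnosis,
       complexity = x$complexity, site_scope = x$site_scope,
       setting = x$setting)
}

# reuse classification columns when the caller has already added them
ensure_classified <- function(records, code_sets) {
  cls <- c("has_test", "has_diagnosis", "complexity", "site_scope")
  if (all(cls %in% names(records))) records
  else classify_visits(records, code_sets)
}

#' Quarterly tests, diagnoses and positivity by setting
#'
#' For every calendar quarter present in the data and each setting group
#' (`clinic` pooling GUM and community clinics, `online` counting completed
#' kits only, and `all` pooling both) counts the records carrying a test or
#' a diagnosis (the positivity denominator), those carrying a diagnosis
#' (the numerator), and their ratio.
#'
#' @param records harmonised, deduplicated attendance records.
#' @param code_sets a [default_code_sets()] object.
#' @return A tibble with columns `quarter`, `setting_group`,
#'   `n_tests_or_diagnoses`, `n_diagnoses`, `positivity` (`NA` when the
#'   denominator is zero), ordered by quarter then group.
#' @export
quarterly_summaries <- function(records, code_sets = default_code_sets()) {
  x <- ensure_classified(records, code_sets)
  x <- x[x$has_test | x$has_diagnosis, , drop = FALSE]
  if ("ordered_only" %in% names(x)) x <- x[!x$ordered_only, , drop = FALSE]
  if (nrow(x) == 0) {
    return(tibble::tibble(quarter = character(), setting_group = character(),
                          n_tests_or_diagnoses = integer(),
                          n_diagnoses = integer(), positivity = numeric()))
  }
  x$quarter <- quarter_label(x$visit_date)
  x$setting_group <- ifelse(x$setting == "online", "online", "clinic")
  per_setting <- x |>
    dplyr::count(.data$quarter, .data$setting_group, wt = NULL,
                 name = "n_tests_or_diagnoses") |>
    dplyr::left_join(
      x |> dplyr::filter(.data$has_diagnosis) |>
        dplyr::count(.data$quarter, .data$setting_group,
                     name = "n_diagnoses"),
      by = c("quarter", "setting_group")
    )
  pooled <- x |>
    dplyr::count(.data$quarter, name = "n_tests_or_diagnoses") |>
    dplyr::left_join(
      x |> dplyr::filter(.data$has_diagnosis) |>
        dplyr::count(.data$quarter, name = "n_diagnoses"),
      by = "quarter"
    ) |>
    dplyr::mutate(setting_group = "all")
  out <- dplyr::bind_rows(per_setting, pooled)
  out$n_diagnoses[is.na(out$n_diagnoses)] <- 0L
  out$positivity <- ifelse(out$n_tests_or_diagnoses > 0,
                           out$n_diagnoses / out$n_tests_or_diagnoses,
                           NA_real_)
  out <- out[order(out$quarter,
                   match(out$setting_group, c("clinic", "online", "all"))), ]
  tibble::as_tibble(out[, c("quarter", "setting_group",
                            "n_tests_or_diagnoses", "n_diagnoses",
                            "positivity")])
}

#' Online share of testing in a quarter
#'
#' Completed online test-or-diagnosis episodes as a proportion of all
#' test-or-diagnosis episodes (clinic plus online) in the quarter.
#'
#' @param summaries output of [quarterly_summaries()].
#' @param quarter quarter label, e.g. `"2016-Q2"`.
#' @return Proportion in \[0, 1\].
#' @export
online_share <- function(summaries, quarter) {
  rows <- summaries[summaries$quarter == quarter &
                      summaries$setting_group %in% c("clinic", "online"), ]
  if (nrow(rows) == 0) stop("quarter not present in summaries: ", quarter)
  denom <- sum(rows$n_tests_or_diagnoses)
  online <- sum(rows$n_tests_or_diagnoses[rows$setting_group == "online"])
  if (denom == 0) return(NA_real_)
  online / denom
}

#' Percent change between two volumes
#'
#' @param before,after positive baseline and comparison values.
#' @return `100 * (after - before) / before`.
#' @export
percent_change <- function(before, after) {
  if (!is.finite(before) || before <= 0) {
    stop("percent_change requires a positive baseline")
  }
  100 * (after - before) / before
}
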