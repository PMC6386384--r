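# Tariff assignment and period cost summaries. Costs are carried unrounded
# and only rounded to whole pounds when printed or exported.

#' Assign a tariff to classified visits
#'
#' Online tests receive the indicative online price. Clinic triple-site
#' (TT) tests receive the MSM tariff whatever the visit's complexity (the
#' tariff is the same for primary and additional activity). Genital clinic
#' tests receive the primary tariff when testing is the sole activity
#' (simple) and the additional tariff within a complex visit.
#' Diagnosis-only clinic attendances are costed by their complexity class
#' like any other visit in the denominator.
#'
#' @param classification a data frame with columns `setting`, `complexity`,
#'   `site_scope` (as produced by [classify_visits()]); one or many rows.
#' @param tariffs a [default_tariffs()] schedule.
#' @return Numeric vector of GBP amounts, one per row.
#' @export
assign_tariff <- function(classification, tariffs = default_tariffs()) {
  dplyr::case_when(
    classification$setting == "online" ~ tariffs$online_price,
    classification$site_scope == "triple_site" ~ tariffs$msm_triple,
    classification$complexity == "simple" ~ tariffs$primary_simple,
    .default = tariffs$additional_complex
  )
}

#' Derived period outcomes from totals
#'
#' The arithmetic that turns period totals into the reported outcome rows:
#' costs are annualised by scaling to twelve months, monthly averages use
#' unrounded intermediates, cost per test is monthly cost over monthly
#' tests and cost per diagnosis is monthly cost over monthly diagnoses
#' (undefined, `NA`, when there are no diagnoses).
#'
#' @param combined_cost total clinic plus online cost over the period, GBP.
#' @param n_clinic_visits,n_online_tests visit counts over the period.
#' @param n_diagnoses diagnosis count over the period.
#' @param n_months period length in months.
#' @return A list with `annualised_cost`, `monthly_cost`, `monthly_tests`,
#'   `monthly_diagnoses`, `cost_per_test`, `cost_per_diagnosis`, all
#'   unrounded.
#' @export
derive_period_outcomes <- function(combined_cost, n_clinic_visits,
                                   n_online_tests, n_diagnoses, n_months) {
  stopifnot(n_months > 0)
  annualised <- combined_cost * 12 / n_months
  monthly_cost <- annualised / 12
  monthly_tests <- (n_clinic_visits + n_online_tests) / n_months
  monthly_diagnoses <- n_diagnoses / n_months
  list(
    annualised_cost = annualised,
    monthly_cost = monthly_cost,
    monthly_tests = monthly_tests,
    monthly_diagnoses = monthly_diagnoses,
    cost_per_test = if (monthly_tests > 0) monthly_cost / monthly_tests
                    else NA_real_,
    cost_per_diagnosis = if (monthly_diagnoses > 0)
      monthly_cost / monthly_diagnoses else NA_real_
  )
}

COST_CATEGORIES <- c("genital_complex", "triple_complex",
                     "genital_simple", "triple_simple")

category_tariff <- function(category, tariffs) {
  switch(category,
         genital_complex = tariffs$additional_complex,
         triple_complex = tariffs$msm_triple,
         genital_simple = tariffs$primary_simple,
         triple_simple = tariffs$msm_triple,
         stop("unknown category: ", category))
}

#' Period cost summary
#'
#' Restricts harmonised records to the period and to visits carrying a test
#' or diagnosis, splits clinic visits into the four tariff categories
#' (genital/triple-site crossed with simple/complex), prices each category,
#' adds online tests at the online price, and derives the outcome rows
#' (annualised and monthly cost, monthly tests and diagnoses, cost per test
#' and per diagnosis) via [derive_period_outcomes()].
#'
#' @param records harmonised, deduplicated attendance records.
#' @param code_sets a [default_code_sets()] object.
#' @param tariffs a [default_tariffs()] schedule.
#' @param period a [study_period()].
#' @return An object of class `period_cost_summary`.
#' @export
period_cost_summary <- function(records, code_sets = default_code_sets(),
                                tariffs = default_tariffs(), period) {
  stopifnot(inherits(period, "study_period"))
  x <- ensure_classified(records, code_sets)
  x <- x[x$visit_date >= period$start_date &
           x$visit_date <= period$end_date, , drop = FALSE]
  x <- x[x$has_test | x$has_diagnosis, , drop = FALSE]
  if ("ordered_only" %in% names(x)) x <- x[!x$ordered_only, , drop = FALSE]

  clinic <- x[x$setting != "online", , drop = FALSE]
  n_online <- sum(x$setting == "online")
  cat_key <- paste(ifelse(clinic$site_scope == "triple_site",
                          "triple", "genital"),
                   clinic$complexity, sep = "_")
  counts <- vapply(COST_CATEGORIES, function(k) sum(cat_key == k), integer(1))
  costs <- vapply(COST_CATEGORIES,
                  function(k) round(counts[[k]] * category_tariff(k, tariffs), 2),
                  numeric(1))
  clinic_total <- sum(costs)
  online_total <- round(n_online * tariffs$online_price, 2)
  combined <- clinic_total + online_total
  outcomes <- derive_period_outcomes(combined, nrow(clinic), n_online,
                                     sum(x$has_diagnosis), period$n_months)
  structure(
    c(list(period = period,
           n_clinic_visits = nrow(clinic),
           n_online_tests = n_online,
           n_diagnoses = sum(x$has_diagnosis),
           category_counts = as.list(counts),
           category_costs = as.list(costs),
           clinic_total_cost = clinic_total,
           online_total_cost = online_total,
           combined_cost = combined),
      outcomes),
    class = "period_cost_summary"
  )
}

#' Share of clinic test visits that are simple
#'
#' Among clinic visits in the period that carry a test code, the fraction
#' classified simple (testing as the sole activity).
#'
#' @inheritParams period_cost_summary
#' @param period optional [study_period()]; omit to use every record.
#' @return Proportion in \[0, 1\], `NA` when there are no test-bearing
#'   clinic visits.
#' @export
simple_test_share <- function(records, code_sets = default_code_sets(),
                              period = NULL) {
  x <- ensure_classified(records, code_sets)
  if (!is.null(period)) {
    x <- x[x$visit_date >= period$start_date &
             x$visit_date <= period$end_date, , drop = FALSE]
  }
  x <- x[x$setting != "online" & x$has_test, , drop = FALSE]
  if (nrow(x) == 0) return(NA_real_)
  mean(x$complexity == "simple")
}

#' Tabular form of a period cost summary
#'
#' @param summary a `period_cost_summary`.
#' @return A two-column tibble (`item`, `value`) with pounds rounded to
#'   whole units, matching the printed presentation.
#' @export
period_summary_table <- function(summary) {
  s <- summary
  gbp <- function(x) round(x)
  tibble::tibble(
    item = c("period", "n_months",
             "clinic_visits", "online_tests",
             paste0("n_", COST_CATEGORIES),
             paste0("cost_", COST_CATEGORIES),
             "clinic_total_cost", "online_total_cost", "combined_cost",
             "annualised_cost", "monthly_cost",
             "monthly_tests", "monthly_diagnoses",
             "cost_per_test", "cost_per_diagnosis"),
    value = c(s$period$name, s$period$n_months,
              s$n_clinic_visits, s$n_online_tests,
              unlist(s$category_counts),
              gbp(unlist(s$category_costs)),
              gbp(s$clinic_total_cost), gbp(s$online_total_cost),
              gbp(s$combined_cost),
              gbp(s$annualised_cost), gbp(s$monthly_cost),
              round(s$monthly_tests), round(s$monthly_diagnoses),
              gbp(s$cost_per_test), gbp(s$cost_per_diagnosis))
  )
}

#' @export
print.period_cost_summary <- function(x, ...) {
  cat(sprintf("Period cost summary: %s (%d months)\n",
              x$period$name, x$period$n_months))
  cat(sprintf("  clinic visits with test/diagnosis: %d\n", x$n_clinic_visits))
  cat(sprintf("  online tests: %d\n", x$n_online_tests))
  cat(sprintf("  clinic cost: GBP %s   online cost: GBP %s\n",
              format(round(x$clinic_total_cost), big.mark = ","),
              format(round(x$online_total_cost), big.mark = ",")))
  cat(sprintf("  combined: GBP %s   annualised: GBP %s\n",
              format(round(x$combined_cost), big.mark = ","),
              format(round(x$annualised_cost), big.mark = ",")))
  cat(sprintf("  monthly tests: %d   monthly diagnoses: %d\n",
              round(x$monthly_tests), round(x$monthly_diagnoses)))
  cat(sprintf("  cost per test: GBP %s   cost per diagnosis: GBP %s\n",
              round(x$cost_per_test),
              if (is.na(x$cost_per_diagnosis)) "undefined"
              else round(x$cost_per_diagnosis)))
  invisible(x)
}
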