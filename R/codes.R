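#' GUMCAD code sets for the four-infection composite
#'
#' Returns the code vocabulary used to classify attendance records:
#' STI test codes, STI diagnosis codes (chlamydia, gonorrhoea, syphilis, HIV),
#' treatment-elsewhere codes (excluded from diagnosis counting), the
#' triple-site test code offered to men who have sex with men, and the
#' genital-only test code.
#'
#' Diagnosis codes carrying site modifiers (e.g. `"B(R,O)"`, `"C4(R,O)"`)
#' are matched by base code: `"B"`, `"B(R)"`, `"B(O)"` and `"B(R,O)"` all
#' match the diagnosis entry `"B(R,O)"`. See [code_in_set()].
#'
#' @param test_codes character vector of test codes.
#' @param diagnosis_codes character vector of diagnosis codes.
#' @param treatment_elsewhere_codes codes recording treatment of a diagnosis
#'   made elsewhere; these never count as diagnoses here. Empty by default
#'   (supply your own extract's codes if it uses them).
#' @param triple_site_code the code marking genital + rectal + oral testing.
#' @param genital_test_code the code marking genital-only testing.
#' @return An object of class `code_sets`.
#' @examples
#' cs <- default_code_sets()
#' cs$test_codes
#' @export
default_code_sets <- function(test_codes = c("T1", "T2", "T3", "T4", "T7", "T8", "TT"),
                              diagnosis_codes = c("A1", "A2", "A3", "A4", "A5",
                                                  "B(R,O)", "C4(R,O)",
                                                  "H1", "H1a", "H1b"),
                              treatment_elsewhere_codes = character(),
                              triple_site_code = "TT",
                              genital_test_code = "T4") {
  stopifnot(is.character(test_codes), is.character(diagnosis_codes),
            is.character(treatment_elsewhere_codes),
            length(triple_site_code) == 1L, length(genital_test_code) == 1L)
  overlap <- intersect(code_base(test_codes), code_base(diagnosis_codes))
  if (length(overlap) > 0) {
    stop("test and diagnosis code sets must be disjoint; overlap: ",
         paste(overlap, collapse = ", "))
  }
  structure(
    list(
      test_codes = test_codes,
      diagnosis_codes = diagnosis_codes,
      treatment_elsewhere_codes = treatment_elsewhere_codes,
      triple_site_code = triple_site_code,
      genital_test_code = genital_test_code
    ),
    class = "code_sets"
  )
}

#' Base form of a GUMCAD code
#'
#' Strips an optional trailing parenthesised site modifier, so
#' `"C4 (R,O)"` and `"C4(R)"` both reduce to `"C4"`.
#'
#' @param codes character vector.
#' @return character vector of base codes.
#' @export
code_base <- function(codes) {
  trimws(sub("\\s*\\([^)]*\\)\\s*$", "", codes))
}

#' Test codes for membership in a code set, modifier-insensitively
#'
#' @param codes character vector of codes as recorded.
#' @param set character vector defining the set (may carry modifiers).
#' @return logical vector, one element per code.
#' @export
code_in_set <- function(codes, set) {
  code_base(codes) %in% code_base(set)
}

# ";"-joined code cell -> character vector (no empties)
split_codes <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)[[1]]
  out[nzchar(out)]
}

join_codes <- function(codes) paste(codes, collapse = ";")

# flatten ";"-joined cells once: (row index, code) pairs, empties dropped
flatten_cells <- function(cells) {
  sp <- strsplit(cells, ";", fixed = TRUE)
  flat <- unlist(sp, use.names = FALSE)
  row <- rep.int(seq_along(sp), lengths(sp))
  ok <- nzchar(flat)
  list(row = row[ok], code = flat[ok], n = length(cells))
}

# any code in the ";"-joined cell lies in `set`
cell_has_code <- function(cells, set) {
  fl <- flatten_cells(cells)
  out <- logical(fl$n)
  out[fl$row[code_in_set(fl$code, set)]] <- TRUE
  out
}

# number of codes in the cell lying in `set`
cell_n_codes <- function(cells, set) {
  fl <- flatten_cells(cells)
  tabulate(fl$row[code_in_set(fl$code, set)], nbins = fl$n)
}

#' London sexual health tariff schedule
#'
#' Unit prices assigned to classified STI testing visits: the primary tariff
#' for a simple genital STI test delivered as the main activity, the
#' additional tariff for a genital STI test delivered alongside a more
#' expensive clinical activity, the triple-site (genital, rectal, oral)
#' tariff which is identical for primary and additional activity, an
#' indicative price per completed online test, and a reference average
#' clinic cost used by the scenario and cross-area models.
#'
#' @param primary_simple GBP, simple genital STI test as main activity.
#' @param additional_complex GBP, genital STI test within a complex visit.
#' @param msm_triple GBP, triple-site test (same for simple and complex).
#' @param online_price GBP per completed online test.
#' @param clinic_reference_cost GBP, average clinic cost used in the
#'   closed-form scenario and area models.
#' @return An object of class `tariff_schedule`.
#' @export
default_tariffs <- function(primary_simple = 80.58,
                            additional_complex = 56.11,
                            msm_triple = 70.24,
                            online_price = 30,
                            clinic_reference_cost = 66) {
  vals <- c(primary_simple, additional_complex, msm_triple,
            online_price, clinic_reference_cost)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all tariffs must be strictly positive")
  }
  structure(
    list(
      primary_simple = primary_simple,
      additional_complex = additional_complex,
      msm_triple = msm_triple,
      online_price = online_price,
      clinic_reference_cost = clinic_reference_cost
    ),
    class = "tariff_schedule"
  )
}

#' Define a study period
#'
#' A named run of whole calendar quarters. Months are counted as calendar
#' months between `start_date` and `end_date` inclusive and must equal three
#' per quarter.
#'
#' @param name period label.
#' @param start_date,end_date `Date` (or ISO string) bounds, inclusive.
#' @return An object of class `study_period` with fields `name`,
#'   `start_date`, `end_date`, `n_months`, `n_quarters`.
#' @export
study_period <- function(name, start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || start_date > end_date) {
    stop("invalid period bounds")
  }
  sy <- as.integer(format(start_date, "%Y")); sm <- as.integer(format(start_date, "%m"))
  ey <- as.integer(format(end_date, "%Y"));   em <- as.integer(format(end_date, "%m"))
  n_months <- (ey - sy) * 12L + (em - sm) + 1L
  if (n_months %% 3L != 0L) {
    stop("a study period must span whole calendar quarters (n_months = ",
         n_months, ")")
  }
  structure(
    list(name = name, start_date = start_date, end_date = end_date,
         n_months = n_months, n_quarters = n_months %/% 3L),
    class = "study_period"
  )
}

#' Default analysis periods
#'
#' The baseline year with no online service (period 1, four quarters of
#' 2014), and the five quarters with the online service fully operational
#' (period 2, Q2 2015 through Q2 2016). The intervening quarter (Q1 2015,
#' service roll-out) belongs to neither period.
#'
#' @return A named list of two [study_period()] objects.
#' @export
default_periods <- function() {
  list(
    period1 = study_period("period1", "2014-01-01", "2014-12-31"),
    period2 = study_period("period2", "2015-04-01", "2016-06-30")
  )
}

# "2014-Q1"-style label for a Date vector
quarter_label <- function(dates) {
  q <- (as.integer(format(dates, "%m")) - 1L) %/% 3L + 1L
  sprintf("%s-Q%d", format(dates, "%Y"), q)
}

# first day of the calendar quarter containing each date
quarter_start <- function(dates) {
  m <- ((as.integer(format(dates, "%m")) - 1L) %/% 3L) * 3L + 1L
  as.Date(sprintf("%s-%02d-01", format(dates, "%Y"), m))
}

#' @export
print.code_sets <- function(x, ...) {
  cat("GUMCAD code sets\n")
  cat("  test:               ", paste(x$test_codes, collapse = ", "), "\n")
  cat("  diagnosis:          ", paste(x$diagnosis_codes, collapse = ", "), "\n")
  cat("  treatment elsewhere:",
      if (length(x$treatment_elsewhere_codes)) paste(x$treatment_elsewhere_codes, collapse = ", ") else "(none)", "\n")
  cat("  triple-site:        ", x$triple_site_code,
      "  genital:", x$genital_test_code, "\n")
  invisible(x)
}

#' @export
print.tariff_schedule <- function(x, ...) {
  cat("Tariff schedule (GBP)\n")
  cat(sprintf("  simple genital (primary):   %8.2f\n", x$primary_simple))
  cat(sprintf("  complex genital (additional):%7.2f\n", x$additional_complex))
  cat(sprintf("  triple-site (MSM):          %8.2f\n", x$msm_triple))
  cat(sprintf("  online test:                %8.2f\n", x$online_price))
  cat(sprintf("  clinic reference cost:      %8.2f\n", x$clinic_reference_cost))
  invisible(x)
}

#' @export
print.study_period <- function(x, ...) {
  cat(sprintf("Study period '%s': %s to %s (%d months, %d quarters)\n",
              x$name, format(x$start_date), format(x$end_date),
              x$n_months, x$n_quarters))
  invisible(x)
}
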