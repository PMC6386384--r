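# Harmonisation of raw attendance extracts: exclusion filters, collapse to
# one record per person per provider per day, and the six-week
# one-test-or-diagnosis-per-person restriction used for positivity.

new_harmonisation_report <- function(n_input = 0L, n_excluded_no_codes = 0L,
                                     n_excluded_age = 0L,
                                     n_excluded_prisoner = 0L,
                                     n_collapsed_same_day = 0L,
                                     n_removed_6week = 0L, n_output = 0L) {
  structure(
    list(n_input = n_input,
         n_excluded_no_codes = n_excluded_no_codes,
         n_excluded_age = n_excluded_age,
         n_excluded_prisoner = n_excluded_prisoner,
         n_collapsed_same_day = n_collapsed_same_day,
         n_removed_6week = n_removed_6week,
         n_output = n_output),
    class = "harmonisation_report"
  )
}

# conservation identity: every input record is accounted for exactly once
check_report <- function(r) {
  ok <- r$n_output == r$n_input - r$n_excluded_no_codes - r$n_excluded_age -
    r$n_excluded_prisoner - r$n_collapsed_same_day - r$n_removed_6week
  if (!ok) stop("harmonisation report fails its conservation identity")
  invisible(r)
}

#' @export
print.harmonisation_report <- function(x, ...) {
  cat("Harmonisation report\n")
  cat(sprintf("  input records:        %8d\n", x$n_input))
  cat(sprintf("  excluded, no codes:   %8d\n", x$n_excluded_no_codes))
  cat(sprintf("  excluded, age:        %8d\n", x$n_excluded_age))
  cat(sprintf("  excluded, prisoner:   %8d\n", x$n_excluded_prisoner))
  cat(sprintf("  collapsed same-day:   %8d\n", x$n_collapsed_same_day))
  cat(sprintf("  removed, 6-week rule: %8d\n", x$n_removed_6week))
  cat(sprintf("  output records:       %8d\n", x$n_output))
  invisible(x)
}

#' Apply record-level exclusion filters
#'
#' Drops records with no codes in any of the three code lists, records of
#' people aged under 16 or 100 and over, and records flagged as prisoners.
#' Each dropped record is counted once under the first matching reason, in
#' the order: no codes, age, prisoner.
#'
#' @param records attendance records (see [read_records()]).
#' @return A list with elements `records` (retained rows, order preserved)
#'   and `report` (a `harmonisation_report` with the exclusion counts
#'   filled in).
#' @export
apply_exclusions <- function(records) {
  records <- validate_records(records)
  no_codes <- !nzchar(records$sti_codes) & !nzchar(records$repro_codes) &
    !nzchar(records$contraception_codes)
  bad_age <- records$age_years < 16L | records$age_years >= 100L
  prisoner <- records$prisoner
  reason <- dplyr::case_when(no_codes ~ "no_codes",
                             bad_age ~ "age",
                             prisoner ~ "prisoner",
                             .default = NA_character_)
  kept <- records[is.na(reason), , drop = FALSE]
  report <- new_harmonisation_report(
    n_input = nrow(records),
    n_excluded_no_codes = sum(reason == "no_codes", na.rm = TRUE),
    n_excluded_age = sum(reason == "age", na.rm = TRUE),
    n_excluded_prisoner = sum(reason == "prisoner", na.rm = TRUE),
    n_output = nrow(kept)
  )
  list(records = kept, report = check_report(report))
}

union_cell <- function(cells) {
  cc <- unlist(strsplit(cells, ";", fixed = TRUE), use.names = FALSE)
  paste(unique(cc[nzchar(cc)]), collapse = ";")
}

#' Collapse to one record per person, provider and day
#'
#' Within each `(person_id, provider_id, visit_date)` group the code lists
#' are replaced by their de-duplicated union (first occurrence wins, input
#' order preserved) and every other field is taken from the group's first
#' record in input order.
#'
#' @param records attendance records with exclusions applied.
#' @return Collapsed records, ordered by each group's first appearance.
#' @export
collapse_same_day <- function(records) {
  if (nrow(records) == 0) return(records)
  key <- paste(records$person_id, records$provider_id,
               records$visit_date, sep = "\r")
  dup_keys <- unique(key[duplicated(key)])
  if (length(dup_keys) == 0) return(records)
  in_dup <- key %in% dup_keys
  records$.ord <- seq_len(nrow(records))
  other <- setdiff(names(records),
                   c("person_id", "provider_id", "visit_date",
                     code_columns, ".ord"))
  merged <- records[in_dup, , drop = FALSE] |>
    dplyr::group_by(.data$person_id, .data$provider_id, .data$visit_date) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(other), ~ .x[[1]]),
      dplyr::across(dplyr::all_of(code_columns), union_cell),
      .ord = min(.data$.ord),
      .groups = "drop"
    )
  out <- dplyr::bind_rows(records[!in_dup, , drop = FALSE], merged) |>
    dplyr::arrange(.data$.ord)
  out$.ord <- NULL
  out[, names(records)[names(records) != ".ord"]]
}

#' Restrict to one test or diagnosis per person per six-week window
#'
#' Applies the positivity-denominator restriction: within each person (and,
#' by default, each provider) at most one test-or-diagnosis record is
#' retained per rolling window. Records carrying no test or diagnosis code
#' pass through untouched.
#'
#' Records are processed in date order. A window opens at the earliest
#' unresolved record and spans `window_days` days, half-open: records
#' strictly less than `window_days` days after the anchor conflict with it;
#' a record exactly `window_days` days later does not. From each conflict
#' set exactly one record is kept - the one with the most diagnosis codes,
#' ties broken by earliest date, then by input order. Any subsequent record
#' closer than `window_days` days to the kept record is also removed, so
#' retained records are always at least `window_days` apart and the
#' operation is idempotent.
#'
#' @param records same-day-collapsed records.
#' @param code_sets a [default_code_sets()] object.
#' @param window_days window length in days (default 42 = six weeks).
#' @param scope `"provider"` (default) restricts within each
#'   person-provider pair, as when each clinic de-duplicates its own
#'   caseload; `"person"` restricts across the whole economy.
#' @return A list with elements `records` and `report` (a
#'   `harmonisation_report` with `n_removed_6week` filled in).
#' @export
deduplicate_six_week <- function(records, code_sets = default_code_sets(),
                                 window_days = 42L,
                                 scope = c("provider", "person")) {
  scope <- match.arg(scope)
  window_days <- as.integer(window_days)
  if (is.na(window_days) || window_days < 1L) {
    stop("window_days must be a positive integer")
  }
  n_in <- nrow(records)
  if (n_in == 0) {
    return(list(records = records,
                report = check_report(new_harmonisation_report())))
  }
  eligible <- cell_has_code(records$sti_codes, code_sets$test_codes) |
    cell_has_code(records$sti_codes, code_sets$diagnosis_codes)
  ndiag <- cell_n_codes(records$sti_codes, code_sets$diagnosis_codes)
  key <- if (scope == "provider") {
    paste(records$person_id, records$provider_id, sep = "\r")
  } else {
    records$person_id
  }
  keep <- !eligible  # pass-through records are always retained
  dates <- as.numeric(records$visit_date)
  idx_el <- which(eligible)
  key_el <- key[idx_el]
  multi <- key_el %in% unique(key_el[duplicated(key_el)])
  keep[idx_el[!multi]] <- TRUE  # singleton groups are trivially retained
  idx_by_group <- split(idx_el[multi], key_el[multi])
  for (idx in idx_by_group) {
    o <- idx[order(dates[idx], idx)]
    keep[o[window_keep(dates[o], ndiag[o], window_days)]] <- TRUE
  }
  out <- records[keep, , drop = FALSE]
  report <- new_harmonisation_report(
    n_input = n_in, n_removed_6week = n_in - nrow(out), n_output = nrow(out)
  )
  list(records = out, report = check_report(report))
}

# core of the six-week rule on one person(-provider) group, sorted by
# (date, input order); returns positions to keep
window_keep <- function(d, ndiag, window) {
  n <- length(d)
  keep <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && d[j + 1L] < d[i] + window) j <- j + 1L
    cluster <- i:j
    best <- cluster[order(-ndiag[cluster], d[cluster], cluster)[1L]]
    keep <- c(keep, best)
    i <- j + 1L
    while (i <= n && d[i] < d[best] + window) i <- i + 1L
  }
  keep
}

#' Run the full harmonisation sequence
#'
#' Exclusion filters, same-day collapse, then the six-week restriction,
#' with a single consolidated [harmonisation report][apply_exclusions].
#' Order-only online dispatch events (`ordered_only = TRUE`) are not
#' attendance records and are dropped before counting; they matter only to
#' [return_rate_estimate()].
#'
#' @inheritParams deduplicate_six_week
#' @param records raw attendance records.
#' @return A list with elements `records` and `report`; the report
#'   satisfies `n_output = n_input - exclusions - collapsed - removed`.
#' @export
harmonise_records <- function(records, code_sets = default_code_sets(),
                              window_days = 42L,
                              scope = c("provider", "person")) {
  records <- validate_records(records)
  if ("ordered_only" %in% names(records)) {
    records <- records[!records$ordered_only, , drop = FALSE]
    records$ordered_only <- NULL
  }
  step1 <- apply_exclusions(records)
  collapsed <- collapse_same_day(step1$records)
  n_collapsed <- nrow(step1$records) - nrow(collapsed)
  step3 <- deduplicate_six_week(collapsed, code_sets,
                                window_days = window_days, scope = scope)
  report <- new_harmonisation_report(
    n_input = step1$report$n_input,
    n_excluded_no_codes = step1$report$n_excluded_no_codes,
    n_excluded_age = step1$report$n_excluded_age,
    n_excluded_prisoner = step1$report$n_excluded_prisoner,
    n_collapsed_same_day = n_collapsed,
    n_removed_6week = step3$report$n_removed_6week,
    n_output = nrow(step3$records)
  )
  list(records = step3$records, report = check_report(report))
}
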