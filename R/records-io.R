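#' @importFrom rlang .data
NULL

# canonical column order of the attendance-record CSV schema
RECORD_COLUMNS <- c(
  "person_id", "visit_date", "setting", "provider_id", "age_years",
  "gender", "msm", "prisoner", "area_code", "visit_type",
  "sti_codes", "repro_codes", "contraception_codes"
)

SETTING_LEVELS <- c("gum_clinic", "community_clinic", "online")
GENDER_LEVELS <- c("female", "male", "other")
VISIT_TYPE_LEVELS <- c("first", "followup")

code_columns <- c("sti_codes", "repro_codes", "contraception_codes")

#' Read attendance records from CSV
#'
#' Reads one-row-per-attendance records in the documented schema:
#' `person_id, visit_date, setting, provider_id, age_years, gender, msm,
#' prisoner, area_code, visit_type, sti_codes, repro_codes,
#' contraception_codes`. Code-list cells are `";"`-delimited; an empty cell
#' means no codes. An optional trailing `ordered_only` logical column (kit
#' dispatched but never returned) is preserved when present.
#'
#' Codes outside the supplied vocabulary are kept verbatim and collected
#' into a parse report attached as `attr(x, "parse_report")`, a tibble of
#' `(row, column, code)`.
#'
#' @param path CSV file path.
#' @param code_sets a [default_code_sets()] object used only to flag unknown
#'   STI codes in the parse report.
#' @return A tibble of attendance records with a `parse_report` attribute.
#' @export
read_records <- function(path, code_sets = default_code_sets()) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(RECORD_COLUMNS, header)
  if (length(missing) > 0) {
    stop("record CSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  has_ordered <- "ordered_only" %in% header
  types <- readr::cols(
    person_id = readr::col_character(),
    visit_date = readr::col_character(),
    setting = readr::col_character(),
    provider_id = readr::col_character(),
    age_years = readr::col_integer(),
    gender = readr::col_character(),
    msm = readr::col_logical(),
    prisoner = readr::col_logical(),
    area_code = readr::col_character(),
    visit_type = readr::col_character(),
    sti_codes = readr::col_character(),
    repro_codes = readr::col_character(),
    contraception_codes = readr::col_character(),
    .default = readr::col_guess()
  )
  x <- readr::read_csv(path, col_types = types, show_col_types = FALSE,
                       progress = FALSE)
  for (col in code_columns) {
    x[[col]][is.na(x[[col]])] <- ""
  }
  dates <- as.Date(x$visit_date, format = "%Y-%m-%d")
  bad <- which(is.na(dates) & !is.na(x$visit_date))
  if (length(bad) > 0) {
    stop("unparseable visit_date (expected ISO-8601) at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  }
  x$visit_date <- dates
  keep <- c(RECORD_COLUMNS, if (has_ordered) "ordered_only")
  x <- x[, keep]

  known <- c(code_sets$test_codes, code_sets$diagnosis_codes,
             code_sets$treatment_elsewhere_codes)
  fl <- flatten_cells(x$sti_codes)
  unk <- !code_in_set(fl$code, known)
  attr(x, "parse_report") <- tibble::tibble(
    row = fl$row[unk], column = rep("sti_codes", sum(unk)),
    code = fl$code[unk]
  )
  x
}

#' Write attendance records to CSV
#'
#' Inverse of [read_records()]: stable column order, ISO dates,
#' `";"`-delimited code cells (written empty when a record carries no
#' codes). Reading the file back reproduces the records field for field.
#'
#' @param records tibble of attendance records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- validate_records(records)
  out <- records[, c(RECORD_COLUMNS,
                     if ("ordered_only" %in% names(records)) "ordered_only")]
  out$visit_date <- format(out$visit_date, "%Y-%m-%d")
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

# structural validation shared by writers and the harmonisation entry point
validate_records <- function(records) {
  if (!is.data.frame(records)) stop("records must be a data frame")
  missing <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing) > 0) {
    stop("records are missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!inherits(records$visit_date, "Date")) {
    records$visit_date <- as.Date(records$visit_date)
  }
  bad_setting <- setdiff(unique(records$setting), SETTING_LEVELS)
  if (length(bad_setting) > 0) {
    stop("unknown setting value(s): ", paste(bad_setting, collapse = ", "))
  }
  for (col in code_columns) {
    records[[col]][is.na(records[[col]])] <- ""
  }
  tibble::as_tibble(records)
}

# empty record table in schema order (used for n = 0 synthesis and tests)
empty_records <- function(ordered_only = FALSE) {
  x <- tibble::tibble(
    person_id = character(), visit_date = as.Date(character()),
    setting = character(), provider_id = character(),
    age_years = integer(), gender = character(), msm = logical(),
    prisoner = logical(), area_code = character(), visit_type = character(),
    sti_codes = character(), repro_codes = character(),
    contraception_codes = character()
  )
  if (ordered_only) x$ordered_only <- logical()
  x
}
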