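# Synthetic attendance-record streams with the statistical structure the
# downstream analysis assumes: a clinic-only baseline era followed by an era
# in which a growing share of testers uses a postal self-sampling service.
# Positivity is a configured marginal probability per setting, not an
# emergent epidemic quantity.

#' Configuration for the synthetic cohort generator
#'
#' @param seed integer seed; all randomness in [synthesize_cohort()] flows
#'   from it.
#' @param n_persons number of testers to simulate.
#' @param study_start,study_end study window (inclusive), whole quarters.
#' @param online_start first day the online service is available.
#' @param clinic_positivity probability a clinic test episode carries a
#'   diagnosis.
#' @param online_positivity probability a completed online test is positive.
#' @param online_uptake_by_quarter fraction of testers choosing the online
#'   service in each calendar quarter from `online_start`'s quarter to
#'   `study_end`'s quarter.
#' @param simple_visit_fraction fraction of clinic test visits where testing
#'   is the only activity (the rest carry an extra service code).
#' @param msm_fraction fraction of testers who are MSM and receive
#'   triple-site (TT) testing in clinic.
#' @param return_rate fraction of dispatched online kits that are returned;
#'   unreturned kits appear as order-only events.
#' @param repeat_tester_fraction fraction of testers with a second visit
#'   7-41 days after the first (within the six-week deduplication window).
#' @param exclusion_fractions named list of probabilities
#'   (`no_codes`, `under_16`, `over_99`, `prisoner`) controlling how many
#'   extra exclusion-triggering records are injected, each expressed as a
#'   fraction of `n_persons`.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_persons = 20000L,
                             study_start = "2014-01-01",
                             study_end = "2016-09-30",
                             online_start = "2015-04-01",
                             clinic_positivity = 0.10,
                             online_positivity = 0.07,
                             online_uptake_by_quarter = c(0.10, 0.16, 0.18,
                                                          0.22, 0.25, 0.37),
                             simple_visit_fraction = 0.39,
                             msm_fraction = 0.105,
                             return_rate = 0.75,
                             repeat_tester_fraction = 0.10,
                             exclusion_fractions = list(no_codes = 0.005,
                                                        under_16 = 0.003,
                                                        over_99 = 0.001,
                                                        prisoner = 0.002)) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  online_start <- as.Date(online_start)
  if (!(study_start < online_start && online_start < study_end)) {
    stop("require study_start < online_start < study_end")
  }
  probs <- c(clinic_positivity, online_positivity, online_uptake_by_quarter,
             simple_visit_fraction, msm_fraction, return_rate,
             repeat_tester_fraction, unlist(exclusion_fractions))
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  need <- c("no_codes", "under_16", "over_99", "prisoner")
  if (!setequal(names(exclusion_fractions), need)) {
    stop("exclusion_fractions must be named: ", paste(need, collapse = ", "))
  }
  n_uptake_quarters <- n_quarters_between(online_start, study_end)
  if (length(online_uptake_by_quarter) != n_uptake_quarters) {
    stop("online_uptake_by_quarter must have one entry per quarter from ",
         "the quarter of online_start to the quarter of study_end (",
         n_uptake_quarters, " quarters)")
  }
  if (n_persons < 0) stop("n_persons must be non-negative")
  structure(
    list(seed = as.integer(seed), n_persons = as.integer(n_persons),
         study_start = study_start, study_end = study_end,
         online_start = online_start,
         clinic_positivity = clinic_positivity,
         online_positivity = online_positivity,
         online_uptake_by_quarter = online_uptake_by_quarter,
         simple_visit_fraction = simple_visit_fraction,
         msm_fraction = msm_fraction,
         return_rate = return_rate,
         repeat_tester_fraction = repeat_tester_fraction,
         exclusion_fractions = exclusion_fractions),
    class = "synthetic_config"
  )
}

n_quarters_between <- function(from, to) {
  f <- quarter_start(as.Date(from)); t <- quarter_start(as.Date(to))
  fy <- as.integer(format(f, "%Y")); fq <- (as.integer(format(f, "%m")) - 1L) %/% 3L
  ty <- as.integer(format(t, "%Y")); tq <- (as.integer(format(t, "%m")) - 1L) %/% 3L
  (ty - fy) * 4L + (tq - fq) + 1L
}

#' Default synthetic-study configuration
#'
#' The conditions the package's worked examples and tests run under: an
#' eleven-quarter study window (2014 Q1 to 2016 Q3) with the online service
#' opening in 2015 Q2; clinic positivity 10%, online positivity 7%; online
#' uptake ramping by quarter to 37% of testers in the final quarter; 39% of
#' clinic test visits simple; 10.5% of testers MSM (triple-site tested); kit
#' return rate 75%.
#'
#' @param seed integer seed passed through to [synthetic_config()].
#' @return A `synthetic_config` object; two calls with the same seed are
#'   identical.
#' @export
default_study_config <- function(seed = 1L) {
  synthetic_config(seed = seed)
}

# clinic sites and their settings; roughly a GUM-led economy
CLINIC_PROVIDERS <- c(clinic_A = "gum_clinic", clinic_B = "gum_clinic",
                      clinic_C = "gum_clinic", clinic_D = "community_clinic",
                      clinic_E = "community_clinic")
ONLINE_PROVIDER <- "online_service"
DIAGNOSIS_DRAW <- c("C4", "A1", "B", "H1")   # chlamydia, gonorrhoea, syphilis, HIV
COMPLEX_EXTRA_DRAW <- c("TREAT", "EXAM")     # non-test service placeholder codes

#' Generate a synthetic attendance-record stream
#'
#' Draws one test episode per person at a uniform date in the study window;
#' from `online_start` each tester chooses the online service with the
#' quarter's configured uptake probability. Clinic episodes carry TT (MSM)
#' or T4 test codes, an extra service code when the visit is complex, and a
#' diagnosis code with the configured positivity; online episodes carry only
#' test and diagnosis codes. A configured fraction of testers revisits the
#' same provider 7-41 days later (colliding with the six-week rule).
#' Unreturned online kits appear as order-only events (empty code list,
#' `ordered_only = TRUE`); exclusion-triggering records (no codes, under 16,
#' 100 or over, prisoner) are injected at the configured rates.
#'
#' @param config a [synthetic_config()] object.
#' @return A tibble of attendance records (with `ordered_only` column),
#'   sorted by date; byte-identical for identical configs.
#' @export
synthesize_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_persons == 0L) {
    return(empty_records(ordered_only = TRUE))
  }
  withr::with_seed(config$seed, generate_stream(config))
}

generate_stream <- function(cf) {
  n <- cf$n_persons
  days <- as.integer(cf$study_end - cf$study_start)

  person_id <- sprintf("P%06d", seq_len(n))
  visit_date <- cf$study_start + sample.int(days + 1L, n, replace = TRUE) - 1L
  msm <- stats::runif(n) < cf$msm_fraction
  gender <- ifelse(msm, "male",
                   sample(GENDER_LEVELS, n, replace = TRUE,
                          prob = c(0.56, 0.42, 0.02)))
  age_years <- sample(16:65, n, replace = TRUE)
  area_code <- sample(sprintf("E010%05d", 1:40), n, replace = TRUE)
  visit_type <- sample(VISIT_TYPE_LEVELS, n, replace = TRUE, prob = c(0.7, 0.3))

  qi <- uptake_quarter_index(visit_date, cf)
  uptake <- ifelse(is.na(qi), 0, cf$online_uptake_by_quarter[pmax(qi, 1L)])
  online <- stats::runif(n) < uptake

  clinic_site <- sample(names(CLINIC_PROVIDERS), n, replace = TRUE)
  provider_id <- ifelse(online, ONLINE_PROVIDER, clinic_site)
  setting <- ifelse(online, "online", unname(CLINIC_PROVIDERS[clinic_site]))

  first <- tibble::tibble(person_id, visit_date, setting, provider_id,
                          age_years, gender, msm, prisoner = FALSE,
                          area_code, visit_type)
  first <- draw_codes(first, cf)

  # second visit inside the dedup window: a plain retest at the same
  # provider (test code only - the episode's diagnosis, if any, is already
  # on the first record), so the six-week rule has collisions to resolve
  # without double-counting infection episodes
  rep_idx <- which(stats::runif(n) < cf$repeat_tester_fraction)
  second <- first[rep_idx, c("person_id", "setting", "provider_id",
                             "age_years", "gender", "msm", "prisoner",
                             "area_code")]
  second$visit_date <- first$visit_date[rep_idx] +
    sample(7:41, length(rep_idx), replace = TRUE)
  second$visit_type <- "followup"
  second <- second[second$visit_date <= cf$study_end, ]
  second <- second[, names(first)[1:10]]
  second$sti_codes <- ifelse(second$setting != "online" & second$msm,
                             "TT", "T4")
  second$repro_codes <- ""
  second$contraception_codes <- ""

  completed <- dplyr::bind_rows(first, second)
  completed$ordered_only <- FALSE

  # one order-only event per unreturned kit; kit dispatches per completed
  # online test are geometric in the return rate
  online_rows <- which(completed$setting == "online")
  unreturned <- NULL
  if (length(online_rows) > 0 && cf$return_rate < 1) {
    n_extra <- stats::rgeom(length(online_rows), cf$return_rate)
    src <- rep(online_rows, n_extra)
    if (length(src) > 0) {
      unreturned <- tibble::tibble(
        person_id = sprintf("U%06d", seq_along(src)),
        visit_date = completed$visit_date[src],
        setting = "online", provider_id = ONLINE_PROVIDER,
        age_years = sample(16:65, length(src), replace = TRUE),
        gender = sample(GENDER_LEVELS, length(src), replace = TRUE,
                        prob = c(0.56, 0.42, 0.02)),
        msm = FALSE, prisoner = FALSE,
        area_code = sample(sprintf("E010%05d", 1:40), length(src),
                           replace = TRUE),
        visit_type = "first",
        sti_codes = "", repro_codes = "", contraception_codes = "",
        ordered_only = TRUE
      )
    }
  }

  excl <- exclusion_records(cf, days)
  out <- dplyr::bind_rows(completed, unreturned, excl)
  dplyr::arrange(out, .data$visit_date, .data$person_id, .data$provider_id)
}

# index into online_uptake_by_quarter; NA before the service opens
uptake_quarter_index <- function(dates, cf) {
  oy <- as.integer(format(cf$online_start, "%Y"))
  oq <- (as.integer(format(cf$online_start, "%m")) - 1L) %/% 3L
  dy <- as.integer(format(dates, "%Y"))
  dq <- (as.integer(format(dates, "%m")) - 1L) %/% 3L
  idx <- (dy - oy) * 4L + (dq - oq) + 1L
  idx[dates < cf$online_start] <- NA_integer_
  idx
}

draw_codes <- function(x, cf) {
  n <- nrow(x)
  is_online <- x$setting == "online"
  test_code <- ifelse(is_online, "T4", ifelse(x$msm, "TT", "T4"))
  pos_p <- ifelse(is_online, cf$online_positivity, cf$clinic_positivity)
  positive <- stats::runif(n) < pos_p
  diag_code <- sample(DIAGNOSIS_DRAW, n, replace = TRUE)
  complex <- !is_online & (stats::runif(n) >= cf$simple_visit_fraction)
  extra_code <- sample(COMPLEX_EXTRA_DRAW, n, replace = TRUE)

  codes <- test_code
  codes <- ifelse(complex, paste(codes, extra_code, sep = ";"), codes)
  codes <- ifelse(positive, paste(codes, diag_code, sep = ";"), codes)
  x$sti_codes <- codes
  x$repro_codes <- ""
  x$contraception_codes <- ""
  x
}

exclusion_records <- function(cf, days) {
  fr <- cf$exclusion_fractions
  counts <- vapply(fr[c("no_codes", "under_16", "over_99", "prisoner")],
                   function(p) stats::rbinom(1L, cf$n_persons, p), integer(1))
  total <- sum(counts)
  if (total == 0) return(NULL)
  kind <- rep(names(counts), counts)
  tibble::tibble(
    person_id = sprintf("X%06d", seq_len(total)),
    visit_date = cf$study_start +
      sample.int(days + 1L, total, replace = TRUE) - 1L,
    setting = unname(CLINIC_PROVIDERS[sample(names(CLINIC_PROVIDERS), total,
                                             replace = TRUE)]),
    provider_id = sample(names(CLINIC_PROVIDERS), total, replace = TRUE),
    age_years = dplyr::case_when(
      kind == "under_16" ~ sample(10:15, total, replace = TRUE),
      kind == "over_99" ~ sample(100:105, total, replace = TRUE),
      .default = sample(16:65, total, replace = TRUE)
    ),
    gender = sample(GENDER_LEVELS, total, replace = TRUE,
                    prob = c(0.56, 0.42, 0.02)),
    msm = FALSE,
    prisoner = kind == "prisoner",
    area_code = sample(sprintf("E010%05d", 1:40), total, replace = TRUE),
    visit_type = "first",
    sti_codes = ifelse(kind == "no_codes", "", "T4"),
    repro_codes = "", contraception_codes = "",
    ordered_only = FALSE
  )
}

#' Estimate the online kit return rate from raw records
#'
#' Completed online tests divided by all online events (completed plus
#' order-only dispatches). Uses the `ordered_only` column when present,
#' otherwise treats an online record with an empty STI code list as an
#' unreturned dispatch.
#'
#' @param records raw (pre-harmonisation) attendance records.
#' @return Proportion in \[0, 1\], or `NA` if there are no online events.
#' @export
return_rate_estimate <- function(records) {
  online <- records[records$setting == "online", , drop = FALSE]
  if (nrow(online) == 0) return(NA_real_)
  unreturned <- if ("ordered_only" %in% names(online)) {
    online$ordered_only
  } else {
    !nzchar(online$sti_codes)
  }
  1 - mean(unreturned)
}

#' Read or write a synthesis configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_synthetic_config()` returns a `synthetic_config`;
#'   `write_synthetic_config()` returns `path` invisibly.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(synthetic_config, y)
}

#' @param config a `synthetic_config` object.
#' @rdname read_synthetic_config
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  y <- unclass(config)
  y$study_start <- format(y$study_start)
  y$study_end <- format(y$study_end)
  y$online_start <- format(y$online_start)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d persons, %s to %s (online from %s)\n",
              x$n_persons, format(x$study_start), format(x$study_end),
              format(x$online_start)))
  cat(sprintf("  positivity clinic %.3f / online %.3f; return rate %.2f\n",
              x$clinic_positivity, x$online_positivity, x$return_rate))
  cat(sprintf("  uptake by quarter: %s\n",
              paste(format(x$online_uptake_by_quarter), collapse = ", ")))
  invisible(x)
}
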