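# Record builders and an independent brute-force implementation of the
# six-week restriction, used as the oracle in property tests.

make_record <- function(person_id = "P1", visit_date = "2014-02-01",
                        setting = "gum_clinic", provider_id = "clinic_A",
                        age_years = 30L, gender = "female", msm = FALSE,
                        prisoner = FALSE, area_code = "E0100001",
                        visit_type = "first", sti_codes = "T4",
                        repro_codes = "", contraception_codes = "") {
  tibble::tibble(
    person_id = person_id, visit_date = as.Date(visit_date),
    setting = setting, provider_id = provider_id,
    age_years = as.integer(age_years), gender = gender, msm = msm,
    prisoner = prisoner, area_code = area_code, visit_type = visit_type,
    sti_codes = sti_codes, repro_codes = repro_codes,
    contraception_codes = contraception_codes
  )
}

make_records <- function(...) {
  args <- list(...)
  n <- max(lengths(args), 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    one <- lapply(args, function(a) a[[min(i, length(a))]])
    do.call(make_record, one)
  }))
}

# Brute-force six-week rule on one person-provider group. Works on a small
# data frame of (date, ndiag, id) by repeatedly resolving the earliest
# unresolved conflict set: all events within `window` days of the earliest
# remaining event conflict; the kept event maximises (ndiag, -date, -id)
# lexicographically; everything within `window` days of the kept event is
# then discarded before recursing. Returns kept ids, any order.
oracle_six_week <- function(dates, ndiag, window = 42) {
  df <- data.frame(date = as.numeric(dates), ndiag = ndiag,
                   id = seq_along(dates))
  kept <- integer(0)
  while (nrow(df) > 0) {
    anchor <- min(df$date)
    conflict <- df[df$date < anchor + window, , drop = FALSE]
    rank <- order(conflict$ndiag, -conflict$date, -conflict$id,
                  decreasing = TRUE)
    best <- conflict[rank[1], ]
    kept <- c(kept, best$id)
    df <- df[df$date >= anchor + window & df$date >= best$date + window, ,
             drop = FALSE]
  }
  sort(kept)
}

# random small dedup instance: n events for one person in a 120-day span
random_dedup_instance <- function(n_events) {
  dates <- as.Date("2015-01-01") + sample(0:119, n_events, replace = TRUE)
  ndiag <- sample(0:3, n_events, replace = TRUE)
  codes <- vapply(ndiag, function(k) {
    paste(c("T4", rep("C4", 0), sample(c("A1", "A2", "A3", "B", "H1"), k)),
          collapse = ";")
  }, character(1))
  make_records(person_id = rep("P1", n_events),
               visit_date = as.character(dates), sti_codes = codes)
}
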