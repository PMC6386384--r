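# Closed-form whole-system scenario models.
#
# With clinic unit cost C, online/clinic cost ratio r, online share of
# testing f, clinic positivity p, online/clinic positivity ratio rho,
# dispatch cost share s and kit return rate R (total testing volume held
# constant):
#
#   blended cost per test        C * [(1 - f) + f * r]
#   blended cost per diagnosis   C * [(1 - f) + f * r] / (p * [(1 - f) + f * rho])
#   cost per completed online test   c * [s / R + (1 - s)],  c = r * C
#
# The cost-per-diagnosis curve is constant in f exactly when rho = r: more
# online testing lowers the system's cost per diagnosis precisely when the
# positivity ratio exceeds the cost ratio.

#' Scenario model parameters
#'
#' @param clinic_cost average clinic cost per test, GBP (C).
#' @param cost_ratio online unit cost over clinic unit cost (r).
#' @param online_fraction share of tests done online (f).
#' @param clinic_positivity probability a clinic test is positive (p).
#' @param positivity_ratio online positivity over clinic positivity (rho).
#' @param dispatch_fraction share of the online test cost incurred when a
#'   kit is sent out (s).
#' @param return_rate fraction of dispatched kits returned (R).
#' @param online_cost online cost per completed test, GBP; defaults to
#'   `cost_ratio * clinic_cost`.
#' @return An object of class `scenario_params`.
#' @export
scenario_params <- function(clinic_cost = 66,
                            cost_ratio = 0.45,
                            online_fraction = 0.37,
                            clinic_positivity = 0.10,
                            positivity_ratio = 0.7,
                            dispatch_fraction = 0.15,
                            return_rate = 0.75,
                            online_cost = cost_ratio * clinic_cost) {
  if (clinic_cost <= 0) stop("clinic_cost must be positive")
  if (cost_ratio <= 0 || positivity_ratio <= 0) {
    stop("cost_ratio and positivity_ratio must be positive")
  }
  in01 <- function(x) is.finite(x) && x >= 0 && x <= 1
  if (!in01(online_fraction) || !in01(clinic_positivity) ||
      !in01(dispatch_fraction) || !in01(return_rate)) {
    stop("online_fraction, clinic_positivity, dispatch_fraction and ",
         "return_rate must lie in [0, 1]")
  }
  structure(
    list(clinic_cost = clinic_cost, cost_ratio = cost_ratio,
         online_fraction = online_fraction,
         clinic_positivity = clinic_positivity,
         positivity_ratio = positivity_ratio,
         dispatch_fraction = dispatch_fraction,
         return_rate = return_rate, online_cost = online_cost),
    class = "scenario_params"
  )
}

#' Blended cost per test
#'
#' Average cost per test across the whole system,
#' `C * ((1 - f) + f * r)`: linear in the online fraction, falling
#' whenever online tests are cheaper than clinic ones.
#'
#' @param params a [scenario_params()] object.
#' @return GBP per test.
#' @export
blended_cost_per_test <- function(params) {
  with(params, clinic_cost * ((1 - online_fraction) +
                                online_fraction * cost_ratio))
}

#' Blended cost per diagnosis
#'
#' Average cost per positive across the whole system,
#' `C * ((1 - f) + f * r) / (p * ((1 - f) + f * rho))`. At `rho = r` this
#' equals `C / p` for every online fraction; it decreases with f when the
#' positivity ratio exceeds the cost ratio and increases when it falls
#' below.
#'
#' @param params a [scenario_params()] object with `clinic_positivity > 0`.
#' @return GBP per diagnosis.
#' @export
blended_cost_per_diagnosis <- function(params) {
  p <- params$clinic_positivity
  if (p <= 0) stop("clinic_positivity must be positive")
  f <- params$online_fraction
  denom <- (1 - f) + f * params$positivity_ratio
  if (denom <= 0) stop("degenerate scenario: zero blended positivity")
  blended_cost_per_test(params) / (p * denom)
}

#' Break-even positivity ratio
#'
#' The positivity ratio at which shifting tests online leaves the blended
#' cost per diagnosis unchanged - equal to the cost ratio. Above it, more
#' online testing lowers cost per diagnosis; below it, raises it.
#'
#' @param params a [scenario_params()] object.
#' @return The cost ratio r.
#' @export
break_even_positivity_ratio <- function(params) {
  params$cost_ratio
}

#' Cost per completed online test under partial kit return
#'
#' Each completed test requires `1 / R` kit dispatches; the dispatch share
#' `s` of the unit cost is spent on every dispatch and the remainder only
#' on returned kits, giving `c * (s / R + (1 - s))`.
#'
#' @param params a [scenario_params()] object with `return_rate > 0`.
#' @return GBP per completed online test.
#' @export
cost_per_completed_test <- function(params) {
  R <- params$return_rate
  if (R <= 0) stop("return_rate must be positive")
  s <- params$dispatch_fraction
  params$online_cost * (s / R + (1 - s))
}

#' Area profile
#'
#' @param name area label.
#' @param urban_rural_class rural/urban classification string.
#' @param clinic_positivity,online_positivity chlamydia positivity in the
#'   area's clinics and online service, in (0, 1].
#' @return An object of class `area_profile`.
#' @export
area_profile <- function(name, urban_rural_class,
                         clinic_positivity, online_positivity) {
  if (clinic_positivity <= 0 || clinic_positivity > 1 ||
      online_positivity <= 0 || online_positivity > 1) {
    stop("positivities must lie in (0, 1]")
  }
  structure(list(name = name, urban_rural_class = urban_rural_class,
                 clinic_positivity = clinic_positivity,
                 online_positivity = online_positivity),
            class = "area_profile")
}

#' Cost per diagnosis in an area, clinic vs online
#'
#' Divides each setting's unit cost by the area's positivity in that
#' setting and rounds to the nearest pound for reporting: clinic uses the
#' reference clinic cost, online the online price.
#'
#' @param area an [area_profile()].
#' @param tariffs a [default_tariffs()] schedule supplying
#'   `clinic_reference_cost` and `online_price`.
#' @return Named numeric vector `c(clinic = ..., online = ...)`, GBP.
#' @export
area_cost_per_diagnosis <- function(area, tariffs = default_tariffs()) {
  stopifnot(inherits(area, "area_profile"))
  c(clinic = round(tariffs$clinic_reference_cost / area$clinic_positivity),
    online = round(tariffs$online_price / area$online_positivity))
}

#' Read area profiles from CSV
#'
#' Schema: `area_name, urban_rural_class, clinic_positivity,
#' online_positivity` (positivities as proportions). The packaged fixture
#' `system.file("extdata", "area_profiles.csv", package = "stiecon")`
#' carries the four reference areas.
#'
#' @param path CSV path.
#' @return A list of [area_profile()] objects, named by area.
#' @export
read_area_profiles <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    area_name = readr::col_character(),
    urban_rural_class = readr::col_character(),
    clinic_positivity = readr::col_double(),
    online_positivity = readr::col_double()
  ), progress = FALSE)
  profiles <- lapply(seq_len(nrow(x)), function(i) {
    area_profile(x$area_name[i], x$urban_rural_class[i],
                 x$clinic_positivity[i], x$online_positivity[i])
  })
  stats::setNames(profiles, x$area_name)
}

#' Cross-area cost-per-diagnosis table
#'
#' @param profiles list of [area_profile()] objects.
#' @param tariffs a [default_tariffs()] schedule.
#' @return A tibble with one row per area and the clinic and online cost
#'   per diagnosis in whole pounds.
#' @export
area_comparison_table <- function(profiles, tariffs = default_tariffs()) {
  rows <- lapply(profiles, function(a) {
    cpd <- area_cost_per_diagnosis(a, tariffs)
    tibble::tibble(area = a$name, urban_rural_class = a$urban_rural_class,
                   clinic_positivity = a$clinic_positivity,
                   online_positivity = a$online_positivity,
                   cost_per_diagnosis_clinic = cpd[["clinic"]],
                   cost_per_diagnosis_online = cpd[["online"]])
  })
  dplyr::bind_rows(rows)
}

SCENARIO_MODELS <- c("cost_per_test", "cost_per_diagnosis", "return_rate")

#' Sweep a scenario model over a parameter grid
#'
#' Evaluates one of the closed-form models at each grid value of a single
#' parameter, all others held at `base`.
#'
#' @param model `"cost_per_test"` ([blended_cost_per_test()]),
#'   `"cost_per_diagnosis"` ([blended_cost_per_diagnosis()]) or
#'   `"return_rate"` ([cost_per_completed_test()]).
#' @param vary name of the [scenario_params()] field to vary.
#' @param grid numeric vector of values for `vary`.
#' @param base a [scenario_params()] object.
#' @return A tibble with columns `vary` (the grid, in input order) and
#'   `value` (the model output, GBP).
#' @export
sweep_scenario <- function(model = SCENARIO_MODELS, vary, grid,
                           base = scenario_params()) {
  model <- match.arg(model)
  if (!vary %in% names(unclass(base))) {
    stop("unknown scenario parameter: ", vary)
  }
  fn <- switch(model,
               cost_per_test = blended_cost_per_test,
               cost_per_diagnosis = blended_cost_per_diagnosis,
               return_rate = cost_per_completed_test)
  values <- vapply(grid, function(v) {
    args <- unclass(base)
    args[[vary]] <- v
    # keep online_cost tied to the cost ratio unless swept directly
    if (vary %in% c("clinic_cost", "cost_ratio")) {
      args$online_cost <- args$cost_ratio * args$clinic_cost
    }
    fn(do.call(scenario_params, args))
  }, numeric(1))
  tibble::tibble(!!vary := grid, value = values)
}
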