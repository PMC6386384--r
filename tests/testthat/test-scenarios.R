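test_that("blended cost per test interpolates linearly between clinic and online", {
  expect_equal(blended_cost_per_test(scenario_params(online_fraction = 0)), 66)
  expect_equal(blended_cost_per_test(
    scenario_params(online_fraction = 1, cost_ratio = 0.5)), 33)
  expect_equal(blended_cost_per_test(
    scenario_params(online_fraction = 0.37, cost_ratio = 0.45)),
    66 * (0.63 + 0.37 * 0.45))
  # linear, decreasing in f for r < 1
  f <- seq(0, 1, by = 0.1)
  v <- vapply(f, function(x) blended_cost_per_test(
    scenario_params(online_fraction = x, cost_ratio = 0.5)), numeric(1))
  expect_true(all(diff(v) < 0))
  expect_equal(diff(v), rep(diff(v)[1], 10))
})

test_that("cost per diagnosis hits the clinic-only limit and baseline anchor", {
  expect_equal(blended_cost_per_diagnosis(
    scenario_params(online_fraction = 0, clinic_positivity = 0.1)), 660)
  base <- scenario_params(clinic_cost = 66, clinic_positivity = 0.10,
                          online_fraction = 0.3, cost_ratio = 0.5,
                          positivity_ratio = 1)
  expect_equal(blended_cost_per_diagnosis(base), 561)
})

test_that("the break-even positivity ratio equals the cost ratio", {
  expect_equal(break_even_positivity_ratio(scenario_params(cost_ratio = 0.5)),
               0.5)
  expect_equal(break_even_positivity_ratio(scenario_params(cost_ratio = 1)), 1)
  # at rho = r the cost per diagnosis is C/p for every online fraction
  for (r in c(0.4, 0.45, 0.7)) {
    for (f in seq(0, 1, by = 0.05)) {
      p <- scenario_params(online_fraction = f, cost_ratio = r,
                           positivity_ratio = r, clinic_positivity = 0.1)
      expect_equal(blended_cost_per_diagnosis(p), 66 / 0.1)
    }
  }
})

test_that("cost per diagnosis is monotone in the online fraction on either side", {
  cpd <- function(f, rho, r = 0.45) blended_cost_per_diagnosis(
    scenario_params(online_fraction = f, cost_ratio = r,
                    positivity_ratio = rho))
  f <- seq(0, 1, by = 0.1)
  above <- vapply(f, cpd, numeric(1), rho = 0.7)
  below <- vapply(f, cpd, numeric(1), rho = 0.3)
  expect_true(all(diff(above) < 0))
  expect_true(all(diff(below) > 0))
  expect_lt(cpd(0.4, 0.7), cpd(0.2, 0.7))
})

test_that("return-rate cost curve anchors at the nominal online cost", {
  pars <- function(R, s = 0.15) scenario_params(online_cost = 33,
                                                return_rate = R,
                                                dispatch_fraction = s)
  expect_equal(cost_per_completed_test(pars(1)), 33)
  expect_equal(cost_per_completed_test(pars(0.5)), 37.95)
  expect_equal(cost_per_completed_test(pars(0.4, s = 0)), 33)
  expect_error(cost_per_completed_test(pars(0)), "positive")
  # decreasing in R; markup over the nominal cost exceeds 10% below R = 0.6
  R <- seq(0.2, 1, by = 0.05)
  v <- vapply(R, function(r) cost_per_completed_test(pars(r)), numeric(1))
  expect_true(all(diff(v) < 0))
  markup <- v / 33 - 1
  expect_true(all(markup[R < 0.6] > 0.10))
  expect_true(all(markup[R > 0.6] < 0.10))
})

test_that("area cost per diagnosis divides unit cost by positivity", {
  tf <- default_tariffs()
  se_london <- area_profile("SE London", "Urban", 0.075, 0.041)
  expect_equal(area_cost_per_diagnosis(se_london, tf),
               c(clinic = 880, online = 732))
  area_c <- area_profile("Area C", "Rural with hub towns", 0.055, 0.055)
  expect_equal(area_cost_per_diagnosis(area_c, tf),
               c(clinic = 1200, online = 545))
  # equal positivities and equal unit costs give an equal pair
  eq <- area_cost_per_diagnosis(area_profile("x", "y", 0.05, 0.05),
                                default_tariffs(online_price = 66))
  expect_equal(eq[["clinic"]], eq[["online"]])
  expect_error(area_profile("bad", "z", 0, 0.05), "positivities")
})

test_that("the packaged area profiles load and tabulate", {
  path <- system.file("extdata", "area_profiles.csv", package = "stiecon")
  profiles <- read_area_profiles(path)
  expect_length(profiles, 4)
  tab <- area_comparison_table(profiles)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("cost_per_diagnosis_clinic",
                    "cost_per_diagnosis_online") %in% names(tab)))
})

test_that("parameter sweeps evaluate the model along the grid in order", {
  base <- scenario_params(cost_ratio = 0.5, clinic_cost = 66)
  out <- sweep_scenario("cost_per_test", "online_fraction",
                        c(0, 0.5, 1), base)
  expect_equal(out$value, c(66, 49.5, 33))
  expect_equal(out$online_fraction, c(0, 0.5, 1))
  expect_equal(nrow(sweep_scenario("cost_per_test", "online_fraction",
                                   numeric(0), base)), 0)
  expect_error(sweep_scenario("cost_per_test", "nonsense", 0:1, base),
               "unknown scenario parameter")
  # sweeping the cost ratio re-ties the online cost to the clinic cost
  rr <- sweep_scenario("return_rate", "cost_ratio", c(0.5, 1),
                       scenario_params(return_rate = 1))
  expect_equal(rr$value, c(33, 66))
})
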