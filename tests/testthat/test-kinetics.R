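test_that("survival has its closed-form limits", {
  # A = 0: no denaturation under any program
  none <- arrhenius_kinetics(-Inf, 2.5e5)
  expect_identical(survival_fraction(none, stpp_ramp()), 1)
  expect_identical(survival_fraction(none, tpp_step(66.3)), 1)

  # a hold at the half-life rate leaves exactly half
  k <- calibrate_kinetics(51, 2.5e5)
  expect_equal(survival_fraction(k, tpp_step(51)), 0.5, tolerance = 1e-12)
})

test_that("kinetics constructor rejects non-finite parameters", {
  expect_error(arrhenius_kinetics(NA, 1e5), class = "thermoshift_invalid_kinetics")
  expect_error(arrhenius_kinetics(Inf, 1e5), class = "thermoshift_invalid_kinetics")
  expect_error(arrhenius_kinetics(3, -1), class = "thermoshift_invalid_kinetics")
})

test_that("ramp quadrature matches the fixed-step product oracle", {
  # the spec-anchored case: ramp to 57 degC at 0.2 degC/s, Ea = 250 kJ/mol,
  # A chosen so rate(52 degC) = ln 2 / 180
  ea <- 2.5e5
  log_a <- log(log(2) / 180) + ea / (8.314 * (52 + 273.15))
  k <- arrhenius_kinetics(log_a, ea)
  prog <- stpp_ramp(57, 0.2)
  expect_equal(survival_fraction(k, prog), euler_survival(k, prog),
               tolerance = 1e-6)
})

test_that("quadrature agrees with the oracle over random programs and kinetics", {
  set.seed(101)
  for (i in 1:100) {
    k <- calibrate_kinetics(runif(1, 45, 60), runif(1, 2e5, 6e5))
    prog <- heating_program(hp_hold(runif(1, 30, 45), runif(1, 1, 120)),
                            hp_ramp(37, runif(1, 50, 70), runif(1, 0.05, 1)))
    s <- survival_fraction(k, prog)
    expect_lt(abs(s - euler_survival(k, prog)), 1e-6)
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("survival is multiplicative over program concatenation", {
  set.seed(11)
  for (i in 1:20) {
    k <- calibrate_kinetics(runif(1, 45, 60), runif(1, 3e5, 6e5))
    p1 <- tpp_step(runif(1, 40, 55))
    p2 <- heating_program(hp_ramp(37, runif(1, 50, 60), 0.2))
    expect_equal(survival_fraction(k, hp_concat(p1, p2)),
                 survival_fraction(k, p1) * survival_fraction(k, p2),
                 tolerance = 1e-12)
  }
})

test_that("survival is monotone in temperature, duration, and ramp rate", {
  k <- calibrate_kinetics(51)
  s_temp <- sapply(c(45, 50, 55, 60), function(T) survival_fraction(k, tpp_step(T)))
  expect_true(all(diff(s_temp) < 0))
  s_dur <- sapply(c(60, 180, 600), function(d) survival_fraction(k, tpp_step(51, d)))
  expect_true(all(diff(s_dur) < 0))
  # slower ramps expose the sample longer: survival non-increasing as rate drops
  s_rate <- sapply(c(1, 0.5, 0.2, 0.1), function(r) survival_fraction(k, stpp_ramp(57, r)))
  expect_true(all(diff(s_rate) < 0))
})

test_that("isothermal equivalent temperature is the identity for holds", {
  k <- calibrate_kinetics(51)
  expect_equal(isothermal_equivalent_temperature(k, tpp_step(50)), 50,
               tolerance = 0.01)
})

test_that("equivalent temperature falls as the reference duration grows", {
  k <- calibrate_kinetics(51)
  prog <- stpp_ramp()
  t180 <- isothermal_equivalent_temperature(k, prog, 180)
  t360 <- isothermal_equivalent_temperature(k, prog, 360)
  expect_lt(t360, t180)
})

test_that("degenerate survival yields a no-solution error", {
  none <- arrhenius_kinetics(-Inf, 2.5e5)
  expect_error(isothermal_equivalent_temperature(none, tpp_step(50)),
               class = "thermoshift_no_solution")
})

test_that("calibration hits its defining equation and plausible steepness", {
  k <- calibrate_kinetics(51, 2.5e5)
  expect_equal(survival_fraction(k, tpp_step(51)), 0.5, tolerance = 1e-12)
  # 10 degrees below the melting point almost nothing denatures in 3 min
  expect_gt(survival_fraction(k, tpp_step(41)), 0.95)
  expect_gt(survival_fraction(calibrate_kinetics(51), tpp_step(41)), 0.95)
})

test_that("calibrated melting behavior round-trips through curve fitting", {
  k <- calibrate_kinetics(51)
  ladder <- tpp_default_ladder()
  surv <- sapply(ladder, function(T) survival_fraction(k, tpp_step(T)))
  fit <- fit_melt_curve(ladder, surv)
  expect_true(fit$converged)
  expect_equal(tm50(fit), 51, tolerance = 0.5)
})

test_that("the standard ramp maps near the reported isothermal equivalent", {
  k <- calibrate_kinetics(51)
  te <- isothermal_equivalent_temperature(k, stpp_ramp(57, 0.2))
  expect_gte(te, 50); expect_lte(te, 54)
  # root-finder against a grid-scan oracle
  grid <- seq(45, 60, by = 0.001)
  s_target <- survival_fraction(k, stpp_ramp(57, 0.2))
  iso_surv <- exp(-arrhenius_rate(k, grid) * 180)
  expect_equal(te, grid[which.min(abs(iso_surv - s_target))], tolerance = 0.01)
})
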