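test_that("a null experiment without noise has identical condition channels", {
  sim <- simulate_experiment(
    proteome_spec(50), treatment_effect(),
    experiment_design("STPP_UP", n_replicates = 2),
    noise_model(cv = 0, background = 0, missing_rate = 0, seed = 1)
  )
  x <- sim$matrix$intensities
  meta <- sim$matrix$channel_meta
  for (role in c("test", "control")) {
    jt <- which(meta$role == role & meta$condition == "treated")
    ju <- which(meta$role == role & meta$condition == "untreated")
    expect_equal(x[, jt], x[, ju], ignore_attr = TRUE)
  }
})

test_that("identical seeds give identical experiments", {
  args <- list(proteome_spec(100), treatment_effect(tm_shifts = c("3" = 2)),
               experiment_design("TPP", n_replicates = 2),
               noise_model(cv = 0.2, missing_rate = 0.05, seed = 42))
  s1 <- do.call(simulate_experiment, args)
  s2 <- do.call(simulate_experiment, args)
  expect_identical(s1$matrix$intensities, s2$matrix$intensities)
  expect_identical(s1$ground_truth, s2$ground_truth)
  args2 <- args
  args2[[4]] <- noise_model(cv = 0.2, missing_rate = 0.05, seed = 43)
  s3 <- do.call(simulate_experiment, args2)
  expect_false(identical(s1$matrix$intensities, s3$matrix$intensities))
})

test_that("a planted shift reproduces the thermal-model survival ratio exactly", {
  # plateau and background off so the channel ratio is the pure survival ratio
  prot <- proteome_spec(20, plateau_mean = 0, plateau_sd = 0)
  eff <- treatment_effect(tm_shifts = c("5" = 4))
  sim <- simulate_experiment(prot, eff, experiment_design("STPP_UP", n_replicates = 2),
                             noise_model(cv = 0, background = 0, seed = 7))
  gt <- sim$ground_truth
  meta <- sim$matrix$channel_meta
  x <- sim$matrix$intensities
  jt <- which(meta$role == "test" & meta$condition == "treated" & meta$replicate == 1)
  ju <- which(meta$role == "test" & meta$condition == "untreated" & meta$replicate == 1)
  ratio <- x[5, jt] / x[5, ju]
  k_ctrl <- calibrate_kinetics(gt$tm50[5], gt$activation_energy[5])
  k_trt <- calibrate_kinetics(gt$tm50[5] + 4, gt$activation_energy[5])
  oracle <- survival_fraction(k_trt, stpp_ramp()) / survival_fraction(k_ctrl, stpp_ramp())
  expect_gt(ratio, 1)
  expect_equal(ratio, oracle, tolerance = 1e-9)
  # the 37 degC control channels barely move: recalibrating the melting point
  # changes 3-minute survival at 37 degC only in the fourth decimal
  ct <- which(meta$role == "control" & meta$condition == "treated" & meta$replicate == 1)
  cu <- which(meta$role == "control" & meta$condition == "untreated" & meta$replicate == 1)
  expect_equal(x[5, ct] / x[5, cu], 1, tolerance = 1e-3)
})

test_that("noise-free TPP intensities are non-increasing along the ladder", {
  sim <- simulate_experiment(proteome_spec(40), treatment_effect(),
                             experiment_design("TPP", n_replicates = 2),
                             noise_model(cv = 0, background = 0, seed = 3))
  meta <- sim$matrix$channel_meta
  x <- sim$matrix$intensities
  ladder <- sort(unique(meta$temperature))
  cols <- sapply(ladder, function(tt) {
    which(meta$temperature == tt & meta$condition == "untreated" & meta$replicate == 1)
  })
  profiles <- x[, cols]
  expect_true(all(apply(profiles, 1, function(v) all(diff(v) <= 1e-9))))
})

test_that("missingness matches its nominal rate within binomial error", {
  sim <- simulate_experiment(proteome_spec(500), treatment_effect(),
                             experiment_design("STPP_UP", n_replicates = 3),
                             noise_model(cv = 0.1, missing_rate = 0.1, seed = 9))
  frac <- mean(sim$matrix$intensities == 0)
  n <- length(sim$matrix$intensities)
  expect_lt(abs(frac - 0.1), 4 * sqrt(0.1 * 0.9 / n))
})

test_that("overfull plexes and bad effect indices are design errors", {
  expect_error(experiment_design("STPP_UP", n_replicates = 5), class = "thermoshift_design")
  expect_error(experiment_design("TPP", n_replicates = 6), class = "thermoshift_design")
  expect_error(
    simulate_experiment(proteome_spec(10), treatment_effect(tm_shifts = c("11" = 2)),
                        experiment_design("STPP_UP", n_replicates = 2),
                        noise_model(seed = 1)),
    class = "thermoshift_invalid_spec"
  )
})

test_that("isothermal layout heats test channels with a constant hold", {
  des <- experiment_design("ISOTHERMAL", n_replicates = 2, t_max = 55)
  test_prog <- des$programs[[which(des$channels$role == "test")[1]]]
  expect_equal(test_prog, isothermal_hold(55))
})
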