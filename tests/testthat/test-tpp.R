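worked_profile <- c(0.1, 0.1, 0.2, 0.4, 0.6, 0.8, 1.0, 1.0, 1.0, 1.0)

test_that("abundance score is the mean at the two lowest temperatures", {
  ladder <- tpp_default_ladder()
  expect_equal(abundance_score(c(0.2, 0.4, rep(0, 8)), ladder), 0.3)
  expect_equal(abundance_score(rep(0, 10), ladder), 0)
  # permutation invariance: an unsorted ladder gives the same answer
  perm <- sample(10)
  expect_equal(abundance_score(worked_profile[perm], ladder[perm]),
               abundance_score(worked_profile, ladder))
})

test_that("stability score matches the direct-sum oracle and its identities", {
  ladder <- tpp_default_ladder()
  # direct arithmetic: sum(profile) - 10 * mean(two lowest)
  expect_equal(stability_score(worked_profile, ladder),
               sum(worked_profile) - 10 * 0.1, tolerance = 1e-12)
  expect_equal(stability_score(worked_profile, ladder), 5.2, tolerance = 1e-12)
  # a constant (pure abundance) profile scores zero
  expect_equal(stability_score(rep(0.7, 10), ladder), 0, tolerance = 1e-12)
  # antisymmetry: reflecting the excess about the baseline negates the score
  mirrored <- 0.1 - (worked_profile - 0.1)
  expect_equal(stability_score(mirrored, ladder), -5.2, tolerance = 1e-12)
})

test_that("stability score is invariant to constant shifts and linear in the profile", {
  ladder <- tpp_default_ladder()
  set.seed(10)
  for (i in 1:50) {
    fc <- rnorm(10)
    c0 <- rnorm(1, sd = 5)
    expect_lt(abs(stability_score(fc + c0, ladder) - stability_score(fc, ladder)),
              1e-12)
    fc2 <- rnorm(10)
    expect_lt(abs(stability_score(2 * fc + 3 * fc2, ladder) -
                    (2 * stability_score(fc, ladder) + 3 * stability_score(fc2, ladder))),
              1e-12)
  }
})

test_that("fewer than two temperatures is an error", {
  expect_error(abundance_score(0.5, 37), class = "thermoshift_invalid_profile")
})

test_that("stability score grows monotonically with the planted shift", {
  # noise-free profiles straight from the kinetics (log2 of intensities is
  # exact here), so monotonicity is a property of the score, not of a refit
  ladder <- tpp_default_ladder()
  scores <- vapply(c(0.5, 1.5, 3, 4.5, 6), function(dtm) {
    eff <- treatment_effect(tm_shifts = c("1" = dtm), target_tm50 = 51,
                            target_activation_energy = DEFAULT_ACTIVATION_ENERGY)
    # a fixed small plateau keeps log2 finite at fully-denaturing temperatures
    sim <- simulate_experiment(proteome_spec(5, plateau_mean = 0.02, plateau_sd = 0),
                               eff, experiment_design("TPP", n_replicates = 2),
                               noise_model(cv = 0, background = 0, seed = 77))
    meta <- sim$matrix$channel_meta
    h <- log2(sim$matrix$intensities)
    fc <- vapply(ladder, function(tt) {
      jt <- which(meta$condition == "treated" & meta$temperature == tt & meta$replicate == 1)
      ju <- which(meta$condition == "untreated" & meta$temperature == tt & meta$replicate == 1)
      h[1, jt] - h[1, ju]
    }, numeric(1))
    stability_score(fc, ladder)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_gt(scores[1], 0)
})

test_that("abundance decoys keep a near-zero stability score without noise", {
  prot <- proteome_spec(100)
  eff <- treatment_effect(abundance_log2fc = c("2" = 1))
  sim <- simulate_experiment(prot, eff, experiment_design("TPP", n_replicates = 2),
                             noise_model(cv = 0, seed = 13))
  tab <- run_tpp(apply_qc_filters(sim$matrix)$matrix)
  drow <- tab[tab$protein == "P00002", ]
  expect_lt(abs(drow$stability_score), 0.5)
  expect_identical(drow$class, "none")
  # the glog transform compresses fold changes a little near its linear range
  expect_equal(drow$abundance_score, 1, tolerance = 0.15)
})

test_that("the planted target classifies as a hit with decoys at none", {
  sim <- simulate_tpp_benchmark(seed = 14)
  tab <- run_tpp(apply_qc_filters(sim$matrix)$matrix)
  trow <- tab[tab$protein == benchmark_target_id(), ]
  expect_identical(trow$class, "hit")
  expect_gt(trow$stability_score, 3)
  expect_lt(trow$fdr, 0.01)
  drows <- tab[tab$protein %in% benchmark_decoy_ids(), ]
  expect_true(all(drows$class == "none"))
})

test_that("hit takes precedence over candidate and the class invariants hold", {
  sim <- simulate_tpp_benchmark(seed = 15, n_proteins = 1000)
  tab <- run_tpp(apply_qc_filters(sim$matrix)$matrix)
  hits <- tab[tab$class == "hit", ]
  cands <- tab[tab$class == "candidate", ]
  expect_true(all(hits$stability_score > 3 & hits$fdr < 0.01))
  expect_true(all(cands$stability_score > 2 & cands$fdr < 0.05))
  expect_false(any(cands$stability_score > 3 & cands$fdr < 0.01))
})

test_that("layout validation catches missing ladders and replicates", {
  sim <- simulate_stpp_benchmark(seed = 16, n_proteins = 60)
  expect_error(score_tpp(apply_qc_filters(sim$matrix)$matrix),
               class = "thermoshift_design")
  sim2 <- simulate_experiment(proteome_spec(60), treatment_effect(),
                              experiment_design("TPP", n_replicates = 1),
                              noise_model(seed = 1))
  expect_error(score_tpp(apply_qc_filters(sim2$matrix)$matrix),
               class = "thermoshift_design")
})
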