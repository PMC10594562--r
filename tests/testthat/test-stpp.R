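stpp_meta <- function(n_replicates = 3) {
  experiment_design("STPP_UP", n_replicates = n_replicates)$channels
}

test_that("zero control fold change leaves the matrix untouched", {
  meta <- stpp_meta()
  set.seed(1)
  x <- matrix(rnorm(20 * nrow(meta), 15), 20, nrow(meta))
  # force identical control channels across conditions: delta is exactly zero
  ct <- which(meta$role == "control" & meta$condition == "treated")
  cu <- which(meta$role == "control" & meta$condition == "untreated")
  x[, ct] <- x[, cu]
  res <- abundance_correction(x, meta)
  expect_equal(res$delta, rep(0, 20), ignore_attr = TRUE)
  expect_identical(res$matrix, x)
})

test_that("the correction reproduces the worked arithmetic case", {
  meta <- stpp_meta()
  x <- matrix(0, 1, nrow(meta))
  x[, meta$role == "test" & meta$condition == "untreated"] <- 10.0
  x[, meta$role == "test" & meta$condition == "treated"] <- 12.0
  x[, meta$role == "control" & meta$condition == "treated"] <- 21.0
  x[, meta$role == "control" & meta$condition == "untreated"] <- 20.0
  res <- abundance_correction(x, meta)
  expect_equal(res$delta, 1, ignore_attr = TRUE)
  expect_equal(unique(res$matrix[, meta$role == "test" & meta$condition == "untreated"]),
               11.0)
  expect_equal(unique(res$matrix[, meta$role == "test" & meta$condition == "treated"]),
               12.0)
})

test_that("correction commutes with adding a constant to a protein's channels", {
  meta <- stpp_meta()
  set.seed(2)
  x <- matrix(rnorm(10 * nrow(meta), 15), 10, nrow(meta))
  shifted <- x + 3.7
  expect_equal(abundance_correction(shifted, meta)$matrix,
               abundance_correction(x, meta)$matrix + 3.7)
})

test_that("a planted abundance-only effect is cancelled without noise", {
  prot <- proteome_spec(30, plateau_mean = 0, plateau_sd = 0)
  eff <- treatment_effect(abundance_log2fc = c("4" = 1))
  sim <- simulate_experiment(prot, eff, experiment_design("STPP_UP", n_replicates = 3),
                             noise_model(cv = 0, background = 0, seed = 5))
  h <- log2(sim$matrix$intensities)  # noise-free: plain log2 is exact
  meta <- sim$matrix$channel_meta
  res <- abundance_correction(h, meta)
  tt <- which(meta$role == "test" & meta$condition == "treated")
  tu <- which(meta$role == "test" & meta$condition == "untreated")
  contrast <- rowMeans(res$matrix[, tt]) - rowMeans(res$matrix[, tu])
  expect_equal(res$delta[4], 1, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(contrast[4], 0, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("incomplete designs are rejected by name", {
  meta <- stpp_meta()[-1, ]
  x <- matrix(0, 2, nrow(meta))
  expect_error(abundance_correction(x, meta), class = "thermoshift_design")
})

test_that("vacuous thresholds make every protein a hit", {
  sim <- simulate_stpp_benchmark(seed = 6, n_proteins = 300)
  mat <- apply_qc_filters(sim$matrix)$matrix
  tab <- run_stpp(mat, fc_threshold = 0, p_threshold = 1.0000001)
  expect_true(all(tab$hit))
})

test_that("the planted target is the strongest unflagged hit", {
  sim <- simulate_stpp_benchmark(seed = 7)
  tab <- run_stpp(apply_qc_filters(sim$matrix)$matrix)
  unflagged <- tab[tab$hit & !tab$correction_driven, ]
  expect_gt(nrow(unflagged), 0)
  expect_identical(unflagged$protein[1], benchmark_target_id())
  expect_identical(tab$protein[which.max(tab$log2fc)], benchmark_target_id())
  expect_false(any(unflagged$protein %in% benchmark_decoy_ids()))
})

test_that("correction-driven flagging follows its sign-and-dominance rule", {
  tab <- data.frame(protein = letters[1:5],
                    log2fc = c(1.0, 1.0, -0.8, 1.0, 0.6),
                    t = 10, df = 8, p = 1e-8, adj_p = 1e-6,
                    control_log2fc = c(-1.0, 0, 0.9, -0.3, 0.4),
                    hit = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                    correction_driven = FALSE)
  class(tab) <- c("stpp_score_table", class(tab))
  out <- flag_correction_driven(tab, theta = 0.5)
  expect_identical(out$correction_driven,
                   c(TRUE,   # enrichment fully from the correction
                     FALSE,  # delta = 0 never flags
                     TRUE,   # mirrored in the negative direction
                     FALSE,  # opposing but below the dominance threshold
                     FALSE)) # non-hits untouched
})

test_that("a kinetically stabilized target is a hit and not flagged", {
  prot <- proteome_spec(1000)
  eff <- treatment_effect(tm_shifts = c("1" = 4), target_tm50 = 51,
                          target_activation_energy = DEFAULT_ACTIVATION_ENERGY)
  sim <- simulate_experiment(prot, eff, experiment_design("STPP_UP", n_replicates = 3),
                             noise_model(cv = 0.1, seed = 8))
  tab <- run_stpp(apply_qc_filters(sim$matrix)$matrix)
  row <- tab[tab$protein == "P00001", ]
  expect_true(row$hit)
  expect_false(row$correction_driven)
  expect_lt(abs(row$control_log2fc), 0.3)
})

test_that("stpp scoring rejects single-replicate designs", {
  sim <- simulate_experiment(proteome_spec(20), treatment_effect(),
                             experiment_design("STPP_UP", n_replicates = 1),
                             noise_model(seed = 1))
  expect_error(run_stpp(apply_qc_filters(sim$matrix)$matrix),
               class = "thermoshift_invalid_test")
})
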