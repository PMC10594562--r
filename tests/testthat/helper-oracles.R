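# Independent oracles and shared fixtures for the test suite.

# Fixed-step (dt = 0.01 s) midpoint product integrator: the brute-force
# time-stepping oracle for survival under arbitrary programs.
euler_survival <- function(kinetics, program, dt = 0.01) {
  total <- 0
  for (seg in program$segments) {
    if (seg$kind == "hold") {
      total <- total + arrhenius_rate(kinetics, seg$temperature) * seg$duration
    } else {
      dur <- (seg$to - seg$from) / seg$rate
      n <- ceiling(dur / dt)
      d <- dur / n
      mid <- (seq_len(n) - 0.5) * d
      total <- total + sum(arrhenius_rate(kinetics, seg$from + seg$rate * mid)) * d
    }
  }
  exp(-total)
}

# 6-row toy matrix exercising exactly one QC rule per row plus one clean row
make_filter_toy <- function() {
  proteins <- data.frame(
    protein_id = c("REV1", "CON1", "SITE1", "LOWPEP", "ZEROCH", "CLEAN"),
    gene_name = c("r", "c", "s", "l", "z", "k"),
    reverse = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    contaminant = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    site_only = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    unique_peptides = c(5L, 5L, 5L, 1L, 5L, 5L)
  )
  ints <- matrix(1000, 6, 4)
  ints[5, 2] <- 0
  meta <- data.frame(channel = 1:4,
                     condition = rep(c("treated", "untreated"), 2),
                     replicate = rep(1:2, each = 2),
                     role = "test", temperature = NA_real_)
  intensity_matrix(ints, meta, proteins)
}

# standard planted-effect benchmark: 1 canonical stabilized target (protein 1,
# +4 degC at the proteome-typical melting point) and 20 abundance-only decoys
benchmark_effect <- function() {
  treatment_effect(
    tm_shifts = c("1" = 4),
    abundance_log2fc = stats::setNames(rep(c(1, -1), 10), 2:21),
    target_tm50 = 51,
    target_activation_energy = DEFAULT_ACTIVATION_ENERGY
  )
}

benchmark_decoy_ids <- function() sprintf("P%05d", 2:21)
benchmark_target_id <- function() "P00001"

simulate_stpp_benchmark <- function(seed, n_proteins = 2000, n_replicates = 3,
                                    cv = 0.1) {
  simulate_experiment(proteome_spec(n_proteins), benchmark_effect(),
                      experiment_design("STPP_UP", n_replicates = n_replicates),
                      noise_model(cv = cv, seed = seed))
}

simulate_tpp_benchmark <- function(seed, n_proteins = 2000, n_replicates = 2,
                                   cv = 0.1) {
  simulate_experiment(proteome_spec(n_proteins), benchmark_effect(),
                      experiment_design("TPP", n_replicates = n_replicates),
                      noise_model(cv = cv, seed = seed))
}

# multiplicative-noise matrix with an additive background floor and channel
# loadings: the scenario where a log2 transform under-corrects low intensities
simulate_noise_matrix <- function(n = 2000, n_channels = 6, cv = 0.2,
                                  background = 2^16, seed = 1) {
  set.seed(seed)
  base <- 2^stats::rnorm(n, 20, 2)
  sdlog <- sqrt(log(1 + cv^2))
  x <- vapply(seq_len(n_channels), function(j) {
    base * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog)) + background
  }, numeric(n))
  loadings <- seq(0.8, 1.5, length.out = n_channels)
  sweep(x, 2, loadings, "*")
}

sd_vs_mean_spearman <- function(h) {
  stats::cor(apply(h, 1, stats::sd), rank(rowMeans(h)), method = "spearman")
}
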