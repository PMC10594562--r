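#' Simulated proteome specification
#'
#' Distributions the simulator draws each protein from: melting point (T_m-50
#' under a 3-minute hold), base reporter abundance, denaturation activation
#' energy, and unique peptide count. Defaults centre the melting points at the
#' 51 degC mammalian average.
#'
#' @param n_proteins number of proteins (>= 1).
#' @param tm50_mean,tm50_sd Normal distribution of T_m-50 (degC). The default
#'   sd of 4 degC reproduces the typical spread of mammalian melting points
#'   across a TPP ladder.
#' @param log2_abundance_mean,log2_abundance_sd log-normal base reporter
#'   intensity, parameterized on the log2 scale (defaults 20 and 2: typical
#'   corrected reporter intensities around 1e6 spanning ~3 orders of
#'   magnitude).
#' @param activation_energy_mean,activation_energy_sd Normal distribution of
#'   the Arrhenius activation energy (J/mol), truncated to be positive.
#' @param unique_peptides_lambda unique peptide counts are `1 + Poisson(lambda)`.
#' @param plateau_mean,plateau_sd Normal distribution (truncated to
#'   \[0, 0.2\]) of the per-protein non-melting plateau: the soluble fraction
#'   is `plateau + (1 - plateau) * survival`, mirroring the residual soluble
#'   fraction real melting curves retain at high temperature. A nonzero
#'   plateau keeps fully-denatured proteins at a small genuine signal, as in
#'   real reporter data.
#' @return An object of class `proteome_spec`.
#' @export
proteome_spec <- function(n_proteins,
                          tm50_mean = 51, tm50_sd = 4,
                          log2_abundance_mean = 20, log2_abundance_sd = 2,
                          activation_energy_mean = DEFAULT_ACTIVATION_ENERGY,
                          activation_energy_sd = 5e4,
                          unique_peptides_lambda = 6,
                          plateau_mean = 0.03, plateau_sd = 0.01) {
  if (!is.numeric(n_proteins) || n_proteins < 1) {
    ts_error("n_proteins must be >= 1", "invalid_spec")
  }
  if (tm50_sd < 0 || log2_abundance_sd < 0 || activation_energy_sd < 0 ||
      plateau_sd < 0) {
    ts_error("sd parameters must be >= 0", "invalid_spec")
  }
  if (plateau_mean < 0 || plateau_mean > 0.2) {
    ts_error("plateau_mean must lie in [0, 0.2]", "invalid_spec")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 tm50_mean = tm50_mean, tm50_sd = tm50_sd,
                 log2_abundance_mean = log2_abundance_mean,
                 log2_abundance_sd = log2_abundance_sd,
                 activation_energy_mean = activation_energy_mean,
                 activation_energy_sd = activation_energy_sd,
                 unique_peptides_lambda = unique_peptides_lambda,
                 plateau_mean = plateau_mean, plateau_sd = plateau_sd),
            class = "proteome_spec")
}

#' Planted treatment effects
#'
#' Ground-truth effects of the treated condition: melting-point shifts
#' (positive = drug-stabilized, negative = destabilized) and heating-
#' independent base-abundance fold changes. A protein may carry both. Shifts
#' are applied to the treated condition only, by recalibrating the
#' pre-exponential factor at fixed activation energy so the treated T_m-50
#' moves by exactly the requested amount.
#'
#' @param tm_shifts named numeric vector: names are protein indices, values
#'   melting-point shifts in degC.
#' @param abundance_log2fc named numeric vector: names are protein indices,
#'   values log2 fold changes of base abundance (treated vs untreated).
#' @param target_tm50,target_activation_energy optional baseline melting point
#'   (degC) and activation energy (J/mol) assigned to the shifted proteins
#'   instead of their random proteome draw. Pinning the planted target to the
#'   proteome's typical values makes a recovery benchmark test the pipeline
#'   rather than the luck of the target's own draw (a target melting above
#'   T_max is physically invisible to the ramp). Default `NULL`: drawn.
#' @return An object of class `treatment_effect`.
#' @export
treatment_effect <- function(tm_shifts = numeric(0), abundance_log2fc = numeric(0),
                             target_tm50 = NULL, target_activation_energy = NULL) {
  chk <- function(x, what) {
    if (length(x) && (is.null(names(x)) || anyNA(suppressWarnings(as.integer(names(x)))))) {
      ts_error(sprintf("%s must be named by protein index", what), "invalid_spec")
    }
    x
  }
  structure(list(tm_shifts = chk(tm_shifts, "tm_shifts"),
                 abundance_log2fc = chk(abundance_log2fc, "abundance_log2fc"),
                 target_tm50 = target_tm50,
                 target_activation_energy = target_activation_energy),
            class = "treatment_effect")
}

#' Default TPP temperature ladder
#'
#' The 10-point ladder of the standard TPP protocol. The published protocol
#' text lists "68.6" between 55.5 and 62 degC, almost certainly a transposition
#' of 58.6; the default uses 58.6 degC and sorts ascending, while
#' `verbatim = TRUE` returns the ladder exactly as printed.
#' @param verbatim return the ladder as printed, including the 68.6 entry.
#' @export
tpp_default_ladder <- function(verbatim = FALSE) {
  if (verbatim) return(c(37, 40.4, 44, 46.9, 49.8, 52.9, 55.5, 68.6, 62, 66.3))
  sort(c(37, 40.4, 44, 46.9, 49.8, 52.9, 55.5, 58.6, 62, 66.3))
}

#' Experiment design: layout, heating programs, and plexing
#'
#' Three layouts are supported. `TPP`: every ladder temperature is a 3-minute
#' hold, with condition x replicate multiplexed per temperature (the 2D-TPP
#' arrangement, up to a 10-plex per temperature). `STPP_UP`: per condition and
#' replicate one ramped "test" channel (37 degC for 5 s, then a linear ramp to
#' `t_max`) and one "control" channel held at 37 degC for 3 min, all in a
#' single up-to-16-plex. `ISOTHERMAL`: as STPP_UP but the test channel is a
#' 3-minute hold at `t_max`.
#'
#' @param layout one of `"TPP"`, `"STPP_UP"`, `"ISOTHERMAL"`.
#' @param n_replicates replicates per condition.
#' @param temperature_ladder TPP ladder in degC (TPP layout only).
#' @param t_max ramp/hold end temperature in degC (STPP_UP / ISOTHERMAL).
#' @param ramp_rate ramp rate in degC/s (STPP_UP).
#' @return An object of class `experiment_design` carrying the channel table
#'   (condition, replicate, role, temperature) and per-channel heating
#'   programs.
#' @export
experiment_design <- function(layout = c("STPP_UP", "TPP", "ISOTHERMAL"),
                              n_replicates = 3,
                              temperature_ladder = tpp_default_ladder(),
                              t_max = 57, ramp_rate = 0.2) {
  layout <- match.arg(layout)
  if (n_replicates < 1) ts_error("n_replicates must be >= 1", "invalid_spec")
  conditions <- c("treated", "untreated")
  if (layout == "TPP") {
    if (is.unsorted(temperature_ladder, strictly = TRUE)) {
      temperature_ladder <- sort(unique(temperature_ladder))
    }
    if (length(temperature_ladder) < 2) {
      ts_error("TPP ladder needs at least 2 temperatures", "invalid_spec")
    }
    per_temp <- length(conditions) * n_replicates
    if (per_temp > 10) {
      ts_error(sprintf(
        "design error: %d condition x replicate channels per temperature exceed a 10-plex",
        per_temp), "design")
    }
    grid <- expand.grid(condition = conditions, replicate = seq_len(n_replicates),
                        temperature = temperature_ladder,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$role <- NA_character_
    programs <- lapply(grid$temperature, tpp_step)
  } else {
    roles <- c("test", "control")
    n_channels <- length(conditions) * n_replicates * length(roles)
    if (n_channels > 16) {
      ts_error(sprintf("design error: %d channels exceed a TMTpro 16-plex", n_channels),
               "design")
    }
    grid <- expand.grid(condition = conditions, replicate = seq_len(n_replicates),
                        role = roles,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$temperature <- NA_real_
    test_program <- if (layout == "STPP_UP") stpp_ramp(t_max, ramp_rate)
                    else isothermal_hold(t_max)
    programs <- lapply(grid$role, function(r) {
      if (r == "test") test_program else tpp_step(37)
    })
  }
  grid$channel <- seq_len(nrow(grid))
  structure(list(layout = layout, n_replicates = n_replicates,
                 temperature_ladder = if (layout == "TPP") temperature_ladder else NULL,
                 t_max = t_max, ramp_rate = ramp_rate,
                 channels = grid[, c("channel", "condition", "replicate", "role",
                                     "temperature")],
                 programs = programs),
            class = "experiment_design")
}

#' Measurement noise model
#'
#' Multiplicative log-normal noise with a given coefficient of variation,
#' applied per measurement on top of an additive background floor, plus
#' missing-at-random dropout written as zeros (the MaxQuant convention).
#' Identical seeds give identical simulated data.
#'
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param background additive non-negative intensity floor; keeps channels at
#'   fully-denaturing temperatures at a small nonzero signal, as in real data.
#' @param missing_rate probability a measurement is absent (in \[0, 1)).
#' @param seed integer RNG seed.
#' @export
noise_model <- function(cv = 0.1, background = 1000, missing_rate = 0, seed = 1L) {
  if (cv < 0) ts_error("cv must be >= 0", "invalid_spec")
  if (background < 0) ts_error("background must be >= 0", "invalid_spec")
  if (missing_rate < 0 || missing_rate >= 1) {
    ts_error("missing_rate must be in [0, 1)", "invalid_spec")
  }
  structure(list(cv = cv, background = background, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate a reporter-intensity experiment with known ground truth
#'
#' For every protein and channel the noise-free signal is
#' `base * 2^(abundance effect, treated only) * soluble(kinetics(condition),
#' program(channel))`, with `soluble = plateau + (1 - plateau) * survival`,
#' where the control-condition kinetics are calibrated so
#' the protein's T_m-50 matches its drawn melting point and the treated
#' kinetics are recalibrated (same activation energy) for any planted shift.
#' The background floor is added and multiplicative log-normal noise (unit
#' mean) applied; missing values are written as zeros.
#'
#' @param proteome a [proteome_spec()].
#' @param effect a [treatment_effect()].
#' @param design an [experiment_design()].
#' @param noise a [noise_model()].
#' @return A list with `matrix` (an [intensity_matrix()]) and `ground_truth`
#'   (data frame of every drawn parameter and planted effect).
#' @export
simulate_experiment <- function(proteome, effect, design, noise) {
  stopifnot(inherits(proteome, "proteome_spec"), inherits(effect, "treatment_effect"),
            inherits(design, "experiment_design"), inherits(noise, "noise_model"))
  n <- proteome$n_proteins
  idx_tm <- as.integer(names(effect$tm_shifts))
  idx_ab <- as.integer(names(effect$abundance_log2fc))
  if (length(idx_tm) && any(idx_tm < 1 | idx_tm > n)) {
    ts_error("tm_shifts index out of range", "invalid_spec")
  }
  if (length(idx_ab) && any(idx_ab < 1 | idx_ab > n)) {
    ts_error("abundance_log2fc index out of range", "invalid_spec")
  }
  set.seed(noise$seed)

  tm50 <- stats::rnorm(n, proteome$tm50_mean, proteome$tm50_sd)
  tm50 <- pmin(pmax(tm50, 38), 69.5)   # keep inside the calibratable window
  ea <- stats::rnorm(n, proteome$activation_energy_mean, proteome$activation_energy_sd)
  ea <- pmax(ea, 1e4)
  base <- 2^stats::rnorm(n, proteome$log2_abundance_mean, proteome$log2_abundance_sd)
  peptides <- 1L + stats::rpois(n, proteome$unique_peptides_lambda)
  if (length(idx_tm)) {
    if (!is.null(effect$target_tm50)) tm50[idx_tm] <- effect$target_tm50
    if (!is.null(effect$target_activation_energy)) {
      ea[idx_tm] <- effect$target_activation_energy
    }
  }

  plateau <- stats::rnorm(n, proteome$plateau_mean, proteome$plateau_sd)
  plateau <- pmin(pmax(plateau, 0), 0.2)

  tm_shift <- numeric(n); tm_shift[idx_tm] <- effect$tm_shifts
  ab_fc <- numeric(n); ab_fc[idx_ab] <- effect$abundance_log2fc
  tm50_treated <- pmin(pmax(tm50 + tm_shift, 38), 69.5)

  # log pre-exponential per protein and condition (closed-form calibration)
  log_a_for <- function(tm) log(log(2) / 180) + ea / (GAS_CONSTANT * (tm + CELSIUS_OFFSET))
  log_a_ctrl <- log_a_for(tm50)
  log_a_trt <- log_a_for(tm50_treated)

  chans <- design$channels
  n_ch <- nrow(chans)
  signal <- matrix(0, n, n_ch)
  # cache survival per (program, condition) combination; TPP holds vectorize
  for (j in seq_len(n_ch)) {
    log_a <- if (chans$condition[j] == "treated") log_a_trt else log_a_ctrl
    prog <- design$programs[[j]]
    if (length(prog$segments) == 1L && prog$segments[[1]]$kind == "hold") {
      seg <- prog$segments[[1]]
      expo <- exp(log_a - ea / (GAS_CONSTANT * (seg$temperature + CELSIUS_OFFSET))) *
        seg$duration
      surv <- exp(-expo)
    } else {
      surv <- vapply(seq_len(n), function(i) {
        survival_fraction(arrhenius_kinetics(log_a[i], ea[i]), prog)
      }, numeric(1))
    }
    fc <- if (chans$condition[j] == "treated") 2^ab_fc else 1
    signal[, j] <- base * fc * (plateau + (1 - plateau) * surv)
  }

  values <- signal + noise$background
  if (noise$cv > 0) {
    sdlog <- sqrt(log(1 + noise$cv^2))
    values <- values * exp(matrix(stats::rnorm(n * n_ch, -sdlog^2 / 2, sdlog), n, n_ch))
  }
  if (noise$missing_rate > 0) {
    values[matrix(stats::runif(n * n_ch) < noise$missing_rate, n, n_ch)] <- 0
  }

  ids <- sprintf("P%05d", seq_len(n))
  proteins <- data.frame(protein_id = ids, gene_name = sprintf("GENE%05d", seq_len(n)),
                         reverse = FALSE, contaminant = FALSE, site_only = FALSE,
                         unique_peptides = peptides)
  gt <- data.frame(protein_id = ids, tm50 = tm50, activation_energy = ea,
                   plateau = plateau,
                   base_log2 = log2(base), tm_shift = tm_shift,
                   abundance_log2fc = ab_fc,
                   is_stability_target = tm_shift != 0,
                   is_abundance_effect = ab_fc != 0)
  list(matrix = intensity_matrix(values, chans, proteins), ground_truth = gt)
}

#' Write simulator ground truth as a sidecar TSV
#' @param ground_truth the `ground_truth` element of [simulate_experiment()].
#' @param path output path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  utils::write.table(ground_truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
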