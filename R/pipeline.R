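#' Read and validate a run configuration
#'
#' Configurations are YAML (or an equivalent nested list) with a fixed schema;
#' unknown keys anywhere are rejected before any computation, so typos fail
#' fast instead of silently using defaults.
#'
#' Top-level keys: `seed` (integer), `layout` (`STPP_UP`/`TPP`/`ISOTHERMAL`),
#' `design` (`n_replicates`, `t_max`, `ramp_rate`, `temperature_ladder`),
#' `simulation` (`n_proteins`, `tm50`/`abundance`/`activation_energy` blocks
#' with `mean`+`sd`, `effects` with `tm_shifts`/`abundance_log2fc` maps,
#' `noise` with `cv`/`background`/`missing_rate`), and `thresholds`
#' (`fc`, `p`, `hit_score`, `hit_fdr`, `candidate_score`, `candidate_fdr`,
#' `theta`).
#'
#' @param config path to a YAML file or a nested list.
#' @return validated config list with defaults merged, class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) ts_error(sprintf("config file not found: %s", config), "io")
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  schema <- list(
    seed = NULL, layout = NULL,
    design = list(n_replicates = NULL, t_max = NULL, ramp_rate = NULL,
                  temperature_ladder = NULL),
    simulation = list(
      n_proteins = NULL,
      tm50 = list(mean = NULL, sd = NULL),
      abundance = list(log2_mean = NULL, log2_sd = NULL),
      activation_energy = list(mean = NULL, sd = NULL),
      effects = list(tm_shifts = NA, abundance_log2fc = NA),
      noise = list(cv = NULL, background = NULL, missing_rate = NULL)
    ),
    thresholds = list(fc = NULL, p = NULL, hit_score = NULL, hit_fdr = NULL,
                      candidate_score = NULL, candidate_fdr = NULL, theta = NULL)
  )
  check_keys <- function(x, sch, path) {
    if (!is.list(x)) return(invisible())
    unknown <- setdiff(names(x), names(sch))
    if (length(unknown)) {
      ts_error(sprintf("unknown config key%s: %s",
                       if (length(unknown) > 1) "s" else "",
                       paste0(path, unknown, collapse = ", ")), "schema")
    }
    for (k in names(x)) {
      if (is.list(sch[[k]]) && !anyNA(sch[[k]][1])) {
        check_keys(x[[k]], sch[[k]], paste0(path, k, "."))
      }
    }
  }
  check_keys(config, schema, "")

  defaults <- list(
    seed = 1L, layout = "STPP_UP",
    design = list(n_replicates = 3L, t_max = 57, ramp_rate = 0.2,
                  temperature_ladder = tpp_default_ladder()),
    simulation = list(
      n_proteins = 2000L,
      tm50 = list(mean = 51, sd = 4),
      abundance = list(log2_mean = 20, log2_sd = 2),
      activation_energy = list(mean = DEFAULT_ACTIVATION_ENERGY, sd = 5e4),
      effects = list(tm_shifts = list(), abundance_log2fc = list()),
      noise = list(cv = 0.1, background = 1000, missing_rate = 0)
    ),
    thresholds = list(fc = 0.5, p = 0.001, hit_score = 3, hit_fdr = 0.01,
                      candidate_score = 2, candidate_fdr = 0.05, theta = 0.5)
  )
  merged <- modifyList(defaults, config)
  if (!merged$layout %in% c("STPP_UP", "TPP", "ISOTHERMAL")) {
    ts_error(sprintf("schema error in field 'layout': unknown layout '%s'", merged$layout),
             "schema")
  }
  if (!is.numeric(merged$simulation$n_proteins) || merged$simulation$n_proteins < 1) {
    ts_error("schema error in field 'simulation.n_proteins': must be >= 1", "schema")
  }
  structure(merged, class = c("run_config", "list"))
}

config_objects <- function(config) {
  sim <- config$simulation
  effects <- sim$effects
  as_named <- function(x) {
    if (is.null(x) || length(x) == 0) return(numeric(0))
    stats::setNames(as.numeric(unlist(x)), names(x))
  }
  list(
    proteome = proteome_spec(
      n_proteins = sim$n_proteins,
      tm50_mean = sim$tm50$mean, tm50_sd = sim$tm50$sd,
      log2_abundance_mean = sim$abundance$log2_mean,
      log2_abundance_sd = sim$abundance$log2_sd,
      activation_energy_mean = sim$activation_energy$mean,
      activation_energy_sd = sim$activation_energy$sd
    ),
    effect = treatment_effect(tm_shifts = as_named(effects$tm_shifts),
                              abundance_log2fc = as_named(effects$abundance_log2fc)),
    design = experiment_design(layout = config$layout,
                               n_replicates = config$design$n_replicates,
                               temperature_ladder = config$design$temperature_ladder,
                               t_max = config$design$t_max,
                               ramp_rate = config$design$ramp_rate),
    noise = noise_model(cv = sim$noise$cv, background = sim$noise$background,
                        missing_rate = sim$noise$missing_rate,
                        seed = config$seed)
  )
}

#' Simulate an experiment from a run config and write its files
#'
#' Writes `protein_groups.tsv` (the proteinGroups-dialect table),
#' `ground_truth.tsv` (every planted effect), `channel_map.tsv`, and
#' `config.json` (the resolved configuration) into `out_dir`.
#'
#' @param config a path, list, or [read_run_config()] result.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
cli_simulate <- function(config, out_dir) {
  config <- read_run_config(config)
  obj <- config_objects(config)
  sim <- simulate_experiment(obj$proteome, obj$effect, obj$design, obj$noise)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    protein_groups = file.path(out_dir, "protein_groups.tsv"),
    ground_truth = file.path(out_dir, "ground_truth.tsv"),
    channel_map = file.path(out_dir, "channel_map.tsv"),
    config = file.path(out_dir, "config.json")
  )
  write_protein_groups(sim$matrix, paths$protein_groups)
  write_ground_truth(sim$ground_truth, paths$ground_truth)
  utils::write.table(sim$matrix$channel_meta, paths$channel_map, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Run the read -> filter -> normalize -> score chain on a proteinGroups file
#'
#' @param config a path, list, or [read_run_config()] result (thresholds and
#'   seed are taken from it).
#' @param mode `"stpp"` or `"tpp"`; validated against the channel map's layout.
#' @param protein_groups path to the proteinGroups-dialect TSV.
#' @param channel_map path to the channel map TSV (as written by
#'   [cli_simulate()]) or a data frame.
#' @param out_dir output directory; receives `scores.tsv`,
#'   `filter_report.json`, and `run_metadata.json`.
#' @return invisibly, the score table.
#' @export
cli_run <- function(config, mode = c("stpp", "tpp"), protein_groups, channel_map,
                    out_dir) {
  mode <- match.arg(mode)
  config <- read_run_config(config)
  if (is.character(channel_map)) {
    if (!file.exists(channel_map)) {
      ts_error(sprintf("channel map file not found: %s", channel_map), "io")
    }
    channel_map <- utils::read.delim(channel_map)
  }
  mat <- read_protein_groups(protein_groups, channel_map)
  message(sprintf("[read] %d proteins x %d channels", nrow(mat$intensities),
                  ncol(mat$intensities)))
  is_tpp_layout <- any(!is.na(mat$channel_meta$temperature))
  if (mode == "tpp" && !is_tpp_layout) {
    ts_error("design error: mode 'tpp' needs a temperature-ladder layout but the channel map has no temperatures",
             "design")
  }
  if (mode == "stpp" && is_tpp_layout) {
    ts_error("design error: mode 'stpp' needs test/control roles but the channel map is a temperature ladder",
             "design")
  }
  filt <- apply_qc_filters(mat)
  message(sprintf("[filter] kept %d of %d proteins (flags %d, peptides %d, completeness %d)",
                  filt$report$kept, filt$report$input, filt$report$flags,
                  filt$report$peptides, filt$report$completeness))
  th <- config$thresholds
  scores <- if (mode == "stpp") {
    run_stpp(filt$matrix, fc_threshold = th$fc, p_threshold = th$p, theta = th$theta)
  } else {
    run_tpp(filt$matrix, hit_score = th$hit_score, hit_fdr = th$hit_fdr,
            candidate_score = th$candidate_score, candidate_fdr = th$candidate_fdr)
  }
  message(sprintf("[score] %d proteins scored", nrow(scores)))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(scores, file.path(out_dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(filt$report, file.path(out_dir, "filter_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  cfg_path <- file.path(out_dir, "resolved_config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE, pretty = TRUE)
  meta <- list(mode = mode, seed = config$seed,
               config_md5 = unname(tools::md5sum(cfg_path)),
               package_version = as.character(utils::packageVersion("thermoshift")),
               r_version = R.version.string,
               n_input = filt$report$input, n_scored = nrow(scores))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(scores)
}
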