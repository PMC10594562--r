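#' Reporter-intensity matrix with channel and protein metadata
#'
#' The protein-level container consumed by every pipeline stage: a proteins x
#' channels matrix of non-negative TMT reporter intensities, per-channel
#' metadata (condition, replicate, role or ladder temperature), and per-protein
#' QC annotations mirroring MaxQuant proteinGroups columns (decoy, contaminant
#' and identified-only-by-site flags, unique peptide counts).
#'
#' @param intensities numeric matrix, proteins in rows, channels in columns,
#'   all values non-negative (0 encodes a missing measurement).
#' @param channel_meta data frame with one row per channel and columns
#'   `channel` (integer label), `condition` (`"treated"` / `"untreated"`),
#'   `replicate` (integer), `role` (`"test"` / `"control"` for single-plex
#'   layouts, `NA` for TPP), `temperature` (degC for TPP channels, `NA`
#'   otherwise).
#' @param proteins data frame with one row per protein and columns
#'   `protein_id`, `gene_name`, `reverse`, `contaminant`, `site_only`
#'   (logicals), `unique_peptides` (integer >= 0). Missing flag columns
#'   default to all-`FALSE`.
#' @return An object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(intensities, channel_meta, proteins) {
  intensities <- as.matrix(intensities)
  if (!is.numeric(intensities) || any(!is.finite(intensities)) || any(intensities < 0)) {
    ts_error("intensities must be finite and non-negative", "invalid_matrix")
  }
  channel_meta <- as.data.frame(channel_meta)
  if (nrow(channel_meta) != ncol(intensities)) {
    ts_error("channel_meta must describe every intensity column exactly once",
             "invalid_matrix")
  }
  for (col in c("channel", "condition", "replicate")) {
    if (is.null(channel_meta[[col]])) {
      ts_error(sprintf("channel_meta lacks required column '%s'", col), "invalid_matrix")
    }
  }
  if (is.null(channel_meta$role)) channel_meta$role <- NA_character_
  if (is.null(channel_meta$temperature)) channel_meta$temperature <- NA_real_

  proteins <- as.data.frame(proteins)
  if (nrow(proteins) != nrow(intensities)) {
    ts_error("proteins must describe every intensity row exactly once", "invalid_matrix")
  }
  if (is.null(proteins$protein_id)) ts_error("proteins needs a protein_id column", "invalid_matrix")
  if (is.null(proteins$gene_name)) proteins$gene_name <- proteins$protein_id
  for (flag in c("reverse", "contaminant", "site_only")) {
    if (is.null(proteins[[flag]])) proteins[[flag]] <- FALSE
    proteins[[flag]] <- as.logical(proteins[[flag]])
  }
  if (is.null(proteins$unique_peptides)) proteins$unique_peptides <- 2L
  if (any(proteins$unique_peptides < 0)) {
    ts_error("unique_peptides must be >= 0", "invalid_matrix")
  }
  rownames(intensities) <- proteins$protein_id
  colnames(intensities) <- paste0("Reporter intensity corrected ", channel_meta$channel)
  structure(list(intensities = intensities, channel_meta = channel_meta,
                 proteins = proteins),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix: %d proteins x %d channels>\n",
              nrow(x$intensities), ncol(x$intensities)))
  conds <- table(x$channel_meta$condition)
  cat("  channels:", paste(sprintf("%s=%d", names(conds), conds), collapse = ", "), "\n")
  if (any(!is.na(x$channel_meta$temperature))) {
    cat("  temperatures:", paste(sort(unique(x$channel_meta$temperature)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$intensities)

# row subset preserving metadata
im_subset <- function(mat, keep) {
  intensity_matrix(mat$intensities[keep, , drop = FALSE],
                   mat$channel_meta,
                   mat$proteins[keep, , drop = FALSE])
}

# columns (indices) matching channel metadata predicates
im_channels <- function(mat, condition = NULL, role = NULL, temperature = NULL,
                        replicate = NULL) {
  meta <- mat$channel_meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(condition)) keep <- keep & meta$condition %in% condition
  if (!is.null(role)) keep <- keep & !is.na(meta$role) & meta$role %in% role
  if (!is.null(temperature)) {
    keep <- keep & !is.na(meta$temperature) &
      vapply(meta$temperature, function(t) any(abs(t - temperature) < 1e-9), logical(1))
  }
  if (!is.null(replicate)) keep <- keep & meta$replicate %in% replicate
  which(keep)
}
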