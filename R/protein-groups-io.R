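#' Write an intensity matrix as a MaxQuant proteinGroups-style table
#'
#' Tab-separated, with the columns the downstream reader consumes: "Protein
#' IDs", "Gene names", the "+"-flag columns "Reverse", "Potential
#' contaminant", "Only identified by site", "Unique peptides", and one
#' "Reporter intensity corrected k" column per channel. Optionally appends
#' synthetic decoy, contaminant and site-only rows so the QC filter cascade
#' can be exercised on files with known composition.
#'
#' @param mat an [intensity_matrix()].
#' @param path output file path.
#' @param n_decoys,n_contaminants,n_site_only counts of flagged rows to
#'   append. Appended rows carry the per-channel median intensities, are
#'   deterministic, and are named `REV__DECOY1...`, `CON__CONT1...`,
#'   `SITE__ONLY1...`.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(mat, path, n_decoys = 0, n_contaminants = 0,
                                 n_site_only = 0) {
  stopifnot(inherits(mat, "intensity_matrix"))
  flag <- function(x) ifelse(x, "+", "")
  df <- data.frame(
    `Protein IDs` = mat$proteins$protein_id,
    `Gene names` = mat$proteins$gene_name,
    Reverse = flag(mat$proteins$reverse),
    `Potential contaminant` = flag(mat$proteins$contaminant),
    `Only identified by site` = flag(mat$proteins$site_only),
    `Unique peptides` = mat$proteins$unique_peptides,
    check.names = FALSE
  )
  ints <- mat$intensities
  extra <- function(n, prefix, which_flag) {
    if (n == 0) return(NULL)
    rows <- data.frame(
      `Protein IDs` = paste0(prefix, seq_len(n)),
      `Gene names` = paste0(prefix, seq_len(n)),
      Reverse = "", `Potential contaminant` = "", `Only identified by site` = "",
      `Unique peptides` = 3L, check.names = FALSE
    )
    rows[[which_flag]] <- "+"
    rows
  }
  extras <- rbind(extra(n_decoys, "REV__DECOY", "Reverse"),
                  extra(n_contaminants, "CON__CONT", "Potential contaminant"),
                  extra(n_site_only, "SITE__ONLY", "Only identified by site"))
  if (!is.null(extras)) {
    med <- apply(ints, 2, stats::median)
    ints <- rbind(ints, matrix(rep(med, each = nrow(extras)), nrow = nrow(extras),
                               dimnames = list(extras$`Protein IDs`, colnames(ints))))
    df <- rbind(df, extras)
  }
  int_df <- as.data.frame(apply(ints, 2, function(x) sprintf("%.17g", x)),
                          check.names = FALSE)
  out <- cbind(df, int_df)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a proteinGroups-style table
#'
#' Parses the dialect written by [write_protein_groups()] (and real MaxQuant
#' proteinGroups files restricted to the same columns). In flag columns, `"+"`
#' parses to `TRUE` and anything else to `FALSE`; if a flag column is absent
#' it is treated as all-`FALSE` with a warning.
#'
#' @param path file to read.
#' @param channel_map data frame assigning every reporter column: columns
#'   `channel` (the k in "Reporter intensity corrected k"), `condition`,
#'   `replicate`, and optionally `role` and `temperature`.
#' @return an [intensity_matrix()].
#' @export
read_protein_groups <- function(path, channel_map) {
  if (!file.exists(path)) ts_error(sprintf("file not found: %s", path), "io")
  channel_map <- as.data.frame(channel_map)
  stopifnot(!is.null(channel_map$channel))
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)

  reporter_cols <- grep("^Reporter intensity corrected ", names(tab), value = TRUE)
  file_channels <- as.integer(sub("^Reporter intensity corrected ", "", reporter_cols))
  wanted <- paste0("Reporter intensity corrected ", channel_map$channel)
  missing_cols <- setdiff(wanted, reporter_cols)
  if (length(missing_cols)) {
    ts_error(paste0("reporter columns absent from file: ",
                    paste(missing_cols, collapse = ", ")), "schema")
  }
  unmapped <- setdiff(file_channels, channel_map$channel)
  if (length(unmapped)) {
    ts_error(paste0("reporter columns present but not in channel_map: ",
                    paste0("Reporter intensity corrected ", unmapped, collapse = ", ")),
             "schema")
  }

  parse_flag <- function(name) {
    if (is.null(tab[[name]])) {
      warning(sprintf("flag column '%s' missing; treating as all-FALSE", name))
      return(rep(FALSE, nrow(tab)))
    }
    v <- trimws(as.character(tab[[name]]))
    !is.na(v) & v == "+"
  }
  proteins <- data.frame(
    protein_id = as.character(tab[["Protein IDs"]]),
    gene_name = if (!is.null(tab[["Gene names"]])) as.character(tab[["Gene names"]])
                else as.character(tab[["Protein IDs"]]),
    reverse = parse_flag("Reverse"),
    contaminant = parse_flag("Potential contaminant"),
    site_only = parse_flag("Only identified by site"),
    unique_peptides = if (!is.null(tab[["Unique peptides"]]))
      as.integer(tab[["Unique peptides"]]) else 2L
  )
  ints <- as.matrix(tab[, wanted, drop = FALSE])
  storage.mode(ints) <- "double"
  ints[is.na(ints)] <- 0
  intensity_matrix(ints, channel_map, proteins)
}

#' Apply the protein-level QC filter cascade
#'
#' Removes, in order: (1) rows flagged as reverse (decoy) hits, potential
#' contaminants, or identified only by site; (2) rows quantified with fewer
#' than `min_unique_peptides` unique peptides; (3) when `require_complete`,
#' rows lacking a strictly positive signal in every channel. Each removed row
#' is attributed to the first rule that removes it; filtering is idempotent.
#'
#' @param mat an [intensity_matrix()].
#' @param min_unique_peptides minimum unique peptide count to keep (default 2).
#' @param require_complete drop rows with any zero/absent channel (default TRUE).
#' @return A list with `matrix` (the filtered [intensity_matrix()]) and
#'   `report` (counts: `input`, `flags`, `peptides`, `completeness`, `kept`).
#' @export
apply_qc_filters <- function(mat, min_unique_peptides = 2, require_complete = TRUE) {
  stopifnot(inherits(mat, "intensity_matrix"))
  p <- mat$proteins
  by_flag <- p$reverse | p$contaminant | p$site_only
  by_pept <- !by_flag & p$unique_peptides < min_unique_peptides
  by_complete <- if (require_complete) {
    !by_flag & !by_pept & apply(mat$intensities <= 0, 1, any)
  } else rep(FALSE, nrow(p))
  keep <- !(by_flag | by_pept | by_complete)
  report <- list(input = nrow(p), flags = sum(by_flag), peptides = sum(by_pept),
                 completeness = sum(by_complete), kept = sum(keep))
  if (report$kept == 0L) warning("QC filters removed every protein")
  out <- im_subset(mat, keep)
  if (anyDuplicated(out$proteins$protein_id)) {
    ts_error("protein ids not unique after filtering", "invalid_matrix")
  }
  list(matrix = out, report = report)
}
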