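#' Abundance score of a fold-change profile
#'
#' The mean log2 fold change at the two lowest ladder temperatures, where no
#' appreciable denaturation has occurred; a proxy for expression-level
#' (non-thermal) differences between conditions.
#'
#' @param fc numeric vector or matrix (proteins x temperatures) of log2 fold
#'   changes, ordered as `temperatures`.
#' @param temperatures ladder temperatures in degC (>= 2, any order).
#' @return numeric score(s).
#' @export
abundance_score <- function(fc, temperatures) {
  fc <- if (is.matrix(fc)) fc else matrix(fc, nrow = 1)
  stopifnot(ncol(fc) == length(temperatures))
  if (length(temperatures) < 2L) {
    ts_error("need at least 2 ladder temperatures", "invalid_profile")
  }
  o <- order(temperatures)
  rowMeans(fc[, o[1:2], drop = FALSE])
}

#' Stability score of a fold-change profile
#'
#' Sum over all ladder temperatures of (log2 fold change - abundance score).
#' Subtracting the abundance score makes the statistic exactly invariant to
#' any constant (pure abundance) shift of the profile, so it isolates
#' heating-dependent enrichment: a drug-stabilized protein accumulates
#' positive contributions at the temperatures where the control condition has
#' already denatured.
#'
#' @inheritParams abundance_score
#' @export
stability_score <- function(fc, temperatures) {
  fc <- if (is.matrix(fc)) fc else matrix(fc, nrow = 1)
  ab <- abundance_score(fc, temperatures)
  rowSums(fc) - length(temperatures) * ab
}

#' Score a TPP experiment: per-temperature fold changes, stability scores,
#' significance, and hit classification
#'
#' From a per-temperature variance-stabilized TPP matrix, builds per-replicate
#' fold-change profiles (treated minus untreated, paired by replicate),
#' computes per-replicate abundance and stability scores, tests the replicate
#' stability scores against zero with the moderated one-sample machinery, and
#' assigns tail-area FDRs to the replicate-averaged scores with [score_fdr()].
#' Classification follows the published two-tier rule: `hit` when stability
#' score > `hit_score` and FDR < `hit_fdr`; otherwise `candidate` when score >
#' `candidate_score` and FDR < `candidate_fdr`; otherwise `none`.
#'
#' @param mat an [intensity_matrix()] with a TPP layout (or a `vst_fit` plus
#'   `channel_meta`). Normalization groups are the ladder temperatures.
#' @param transformed optional pre-transformed matrix; when `NULL` the
#'   intensities are variance-stabilized per temperature first.
#' @param hit_score,hit_fdr,candidate_score,candidate_fdr class thresholds.
#' @return A data frame of class `tpp_score_table`: `protein`,
#'   `abundance_score`, `stability_score`, `t`, `p`, `fdr`, `class`, sorted by
#'   FDR then decreasing score.
#' @export
score_tpp <- function(mat, transformed = NULL,
                      hit_score = 3, hit_fdr = 0.01,
                      candidate_score = 2, candidate_fdr = 0.05) {
  stopifnot(inherits(mat, "intensity_matrix"))
  meta <- mat$channel_meta
  temps <- sort(unique(meta$temperature[!is.na(meta$temperature)]))
  if (length(temps) < 2L) {
    ts_error("design error: TPP scoring needs a temperature ladder (>= 2 temperatures)",
             "design")
  }
  reps <- sort(unique(meta$replicate))
  if (length(reps) < 2L) ts_error("need >= 2 replicates per condition", "design")
  for (cond in c("treated", "untreated")) {
    for (r in reps) {
      have <- meta$temperature[meta$condition == cond & meta$replicate == r]
      if (!all(temps %in% have)) {
        ts_error(sprintf(
          "design error: condition '%s' replicate %s misses ladder temperatures", cond, r),
          "design")
      }
    }
  }
  if (is.null(transformed)) {
    transformed <- variance_stabilize(mat, groups = meta$temperature)$matrix
  }

  n <- nrow(transformed)
  stab <- matrix(NA_real_, n, length(reps))
  abund <- matrix(NA_real_, n, length(reps))
  for (k in seq_along(reps)) {
    fc <- vapply(temps, function(tt) {
      jt <- im_channels(mat, condition = "treated", temperature = tt, replicate = reps[k])
      ju <- im_channels(mat, condition = "untreated", temperature = tt, replicate = reps[k])
      rowMeans(transformed[, jt, drop = FALSE]) -
        rowMeans(transformed[, ju, drop = FALSE])
    }, numeric(n))
    abund[, k] <- abundance_score(fc, temps)
    stab[, k] <- stability_score(fc, temps)
  }
  rownames(stab) <- mat$proteins$protein_id

  test <- moderated_one_sample(stab)
  fdr <- score_fdr(test$score)
  cls <- ifelse(test$score > hit_score & fdr$fdr < hit_fdr, "hit",
         ifelse(test$score > candidate_score & fdr$fdr < candidate_fdr, "candidate",
                "none"))
  res <- data.frame(protein = mat$proteins$protein_id,
                    abundance_score = rowMeans(abund),
                    stability_score = test$score,
                    t = test$t, p = test$p, fdr = fdr$fdr, class = cls,
                    row.names = NULL)
  res <- res[order(res$fdr, -res$stability_score), ]
  rownames(res) <- NULL
  class(res) <- c("tpp_score_table", class(res))
  res
}

#' Run the full TPP readout on a filtered intensity matrix
#'
#' Per-temperature variance stabilization (accounting for the globally
#' decreasing signal at higher temperatures), optional batch-effect removal,
#' then [score_tpp()].
#'
#' @param mat a filtered [intensity_matrix()] with a TPP layout.
#' @param batch optional batch label per channel; additive batch effects are
#'   removed with the condition contrast protected.
#' @param ... thresholds passed to [score_tpp()].
#' @return a `tpp_score_table`.
#' @export
run_tpp <- function(mat, batch = NULL, ...) {
  stopifnot(inherits(mat, "intensity_matrix"))
  vst <- variance_stabilize(mat, groups = mat$channel_meta$temperature)
  h <- vst$matrix
  if (!is.null(batch)) {
    h <- remove_batch_effects(h, batch, mat$channel_meta$condition)
  }
  score_tpp(mat, transformed = h, ...)
}
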