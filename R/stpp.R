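#' Validate an STPP-UP channel layout
#'
#' Every (condition, replicate) pair must contribute exactly one ramped "test"
#' channel and one 37 degC "control" channel.
#' @param channel_meta channel metadata data frame (see [intensity_matrix()]).
#' @return `channel_meta`, invisibly, or a design error.
#' @export
validate_stpp_design <- function(channel_meta) {
  meta <- as.data.frame(channel_meta)
  if (any(is.na(meta$role))) {
    ts_error("design error: STPP-UP layout requires a role (test/control) per channel",
             "design")
  }
  combos <- expand.grid(condition = unique(meta$condition),
                        replicate = unique(meta$replicate),
                        role = c("test", "control"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    k <- sum(meta$condition == combos$condition[i] &
             meta$replicate == combos$replicate[i] &
             meta$role == combos$role[i])
    if (k != 1L) {
      ts_error(sprintf(
        "design error: condition '%s' replicate %s needs exactly one '%s' channel (found %d)",
        combos$condition[i], combos$replicate[i], combos$role[i], k), "design")
    }
  }
  invisible(meta)
}

#' Base-abundance correction from the 37 degC control channels
#'
#' Per protein, the control-batch log2 fold change `delta` is the mean over
#' replicates of (treated control - untreated control) on the transformed
#' scale; `delta` is added to every untreated test channel, so differences
#' that exist already without heating are cancelled from the test contrast
#' and only heating-dependent (thermal-stability) differences remain.
#' Treated test channels are unchanged.
#'
#' @param x transformed (variance-stabilized, log2-scale) matrix, proteins x
#'   channels.
#' @param channel_meta channel metadata matching `x` columns.
#' @param replicate_matched add the per-replicate `delta_r` to the matching
#'   untreated test channel instead of the replicate-averaged `delta`
#'   (default `FALSE`: averaging is the lower-variance choice).
#' @return A list with `matrix` (corrected) and `delta` (per-protein
#'   control-batch log2 fold change).
#' @export
abundance_correction <- function(x, channel_meta, replicate_matched = FALSE) {
  x <- as.matrix(x)
  meta <- validate_stpp_design(channel_meta)
  ctrl_t <- which(meta$role == "control" & meta$condition == "treated")
  ctrl_u <- which(meta$role == "control" & meta$condition == "untreated")
  test_u <- which(meta$role == "test" & meta$condition == "untreated")
  delta <- rowMeans(x[, ctrl_t, drop = FALSE]) - rowMeans(x[, ctrl_u, drop = FALSE])
  out <- x
  if (replicate_matched) {
    for (j in test_u) {
      r <- meta$replicate[j]
      jt <- ctrl_t[meta$replicate[ctrl_t] == r]
      ju <- ctrl_u[meta$replicate[ctrl_u] == r]
      out[, j] <- x[, j] + (x[, jt] - x[, ju])
    }
  } else {
    out[, test_u] <- x[, test_u, drop = FALSE] + delta
  }
  list(matrix = out, delta = delta)
}

#' Call STPP-UP hits from corrected test channels
#'
#' Moderated test of the treated test channels against the abundance-corrected
#' untreated test channels. When the correction used the replicate-averaged
#' control fold change (the default), the added offset is itself an estimate,
#' so its sampling variance is propagated into the standard error: the
#' per-protein variance is pooled within all four condition-by-role groups
#' (`d = n - 4` residual df) and the contrast variance factor is
#' `1/n_Tt + 1/n_Ut + 1/n_Tc + 1/n_Uc`. Ignoring the correction term (a plain
#' two-group test on the corrected channels) is anticonservative: the same
#' realized correction offset is shared by every untreated test replicate and
#' never shows up in the residual variance. With `correction = "matched"`
#' (per-replicate correction) the offset noise is already inside the corrected
#' channels and the plain two-group test applies.
#'
#' A protein is a hit when its adjusted p-value and absolute log2 fold change
#' pass the configured thresholds (defaults follow the published volcano
#' classification: |log2FC| > 0.5, adjusted p < 0.001).
#'
#' @param x corrected matrix (from [abundance_correction()]).
#' @param channel_meta channel metadata matching `x`.
#' @param delta per-protein control-batch log2 fold change, retained in the
#'   output for correction-driven flagging.
#' @param fc_threshold,p_threshold hit thresholds.
#' @param correction `"averaged"` (default) or `"matched"`: how
#'   [abundance_correction()] was applied, which determines the variance
#'   bookkeeping above.
#' @return A data frame of class `stpp_score_table`, sorted by adjusted p:
#'   `protein`, `log2fc`, `t`, `p`, `adj_p`, `control_log2fc`, `hit`,
#'   `correction_driven`.
#' @export
call_stpp_hits <- function(x, channel_meta, delta, fc_threshold = 0.5,
                           p_threshold = 0.001,
                           correction = c("averaged", "matched")) {
  correction <- match.arg(correction)
  meta <- validate_stpp_design(channel_meta)
  x <- as.matrix(x)
  test_t <- which(meta$role == "test" & meta$condition == "treated")
  test_u <- which(meta$role == "test" & meta$condition == "untreated")
  if (length(test_t) < 2L || length(test_u) < 2L) {
    ts_error("need >= 2 replicates per side", "invalid_test")
  }
  if (correction == "matched") {
    res <- moderated_ttest(x, test_t, test_u)
  } else {
    ctrl_t <- which(meta$role == "control" & meta$condition == "treated")
    ctrl_u <- which(meta$role == "control" & meta$condition == "untreated")
    grps <- list(test_t, test_u, ctrl_t, ctrl_u)
    ns <- lengths(grps)
    ss <- 0
    for (g in grps) {
      xg <- x[, g, drop = FALSE]
      ss <- ss + rowSums((xg - rowMeans(xg))^2)
    }
    d <- sum(ns) - 4L
    s2 <- ss / d
    fc <- rowMeans(x[, test_t, drop = FALSE]) - rowMeans(x[, test_u, drop = FALSE])
    hyper <- squeeze_variances(s2, d)
    post <- posterior_variance(s2, d, hyper$prior_df, hyper$prior_var)
    se <- sqrt(post * sum(1 / ns))
    tt <- fc / se
    dft <- hyper$prior_df + d
    p <- if (is.finite(dft)) 2 * stats::pt(-abs(tt), dft) else 2 * stats::pnorm(-abs(tt))
    res <- data.frame(protein = if (!is.null(rownames(x))) rownames(x)
                                else seq_len(nrow(x)),
                      log2fc = fc, t = tt, df = dft, p = p,
                      adj_p = stats::p.adjust(p, method = "BH"), row.names = NULL)
    attr(res, "prior_df") <- hyper$prior_df
    attr(res, "prior_var") <- hyper$prior_var
  }
  res$control_log2fc <- delta
  res$hit <- res$adj_p < p_threshold & abs(res$log2fc) > fc_threshold
  res$correction_driven <- FALSE
  res <- res[order(res$adj_p, -abs(res$log2fc)), ]
  rownames(res) <- NULL
  class(res) <- c("stpp_score_table", class(res))
  res
}

#' Flag hits driven by the abundance correction
#'
#' A hit is flagged when its apparent enrichment is "mostly" the added
#' correction rather than thermal stabilization: the control-batch fold change
#' `delta` points opposite to the corrected enrichment it creates
#' (`sign(delta) == -sign(log2fc)`) and is at least `theta` times its
#' magnitude. Non-hits are untouched.
#'
#' @param table an [call_stpp_hits()] result.
#' @param theta dominance fraction (default 0.5).
#' @return the table with `correction_driven` updated.
#' @export
flag_correction_driven <- function(table, theta = 0.5) {
  stopifnot(inherits(table, "stpp_score_table"))
  d <- table$control_log2fc
  flag <- table$hit & d != 0 & sign(d) == -sign(table$log2fc) &
    abs(d) >= theta * abs(table$log2fc)
  table$correction_driven <- flag
  table
}

#' Run the full STPP-UP readout on a filtered intensity matrix
#'
#' Variance-stabilizes the channels with one normalization group per heating
#' program (ramped test channels, 37 degC control channels), applies the
#' base-abundance correction from the control channels, calls hits on the
#' test contrast, and flags correction-driven hits.
#'
#' @param mat a filtered [intensity_matrix()] with an STPP-UP (or isothermal)
#'   layout.
#' @param fc_threshold,p_threshold,theta see [call_stpp_hits()] and
#'   [flag_correction_driven()].
#' @param replicate_matched see [abundance_correction()].
#' @return an `stpp_score_table`.
#' @export
run_stpp <- function(mat, fc_threshold = 0.5, p_threshold = 0.001, theta = 0.5,
                     replicate_matched = FALSE) {
  stopifnot(inherits(mat, "intensity_matrix"))
  validate_stpp_design(mat$channel_meta)
  vst <- variance_stabilize(mat, groups = mat$channel_meta$role)
  corr <- abundance_correction(vst$matrix, mat$channel_meta,
                               replicate_matched = replicate_matched)
  tab <- call_stpp_hits(corr$matrix, mat$channel_meta, corr$delta,
                        fc_threshold = fc_threshold, p_threshold = p_threshold,
                        correction = if (replicate_matched) "matched" else "averaged")
  flag_correction_driven(tab, theta = theta)
}
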