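#' Tail-area false discovery rates for score statistics
#'
#' Estimates per-protein FDR for a vector of scores (e.g. stability scores)
#' without parametric p-values: scores are z-transformed by robust centering
#' and scaling (median and MAD), the null scale is re-estimated from the
#' scores inside the central 75% quantile band (a truncation heuristic: the
#' bulk of proteins is assumed unaffected), two-sided normal tail areas are
#' formed, and tail-area FDR is computed as the null-proportion-scaled
#' Benjamini-Hochberg step-up, which is monotone non-increasing in `|z|`.
#'
#' @param scores numeric vector of at least 50 finite scores.
#' @param central_band central quantile mass used for null-scale estimation
#'   (default 0.75).
#' @return A list with `fdr` (per-protein tail-area FDR, same order as
#'   `scores`), `z` (null-standardized scores), `sigma` (fitted null scale on
#'   the MAD-standardized axis), and `eta0` (estimated null proportion).
#' @export
score_fdr <- function(scores, central_band = 0.75) {
  ok <- is.finite(scores)
  if (sum(ok) < 50L) ts_error("need >= 50 finite scores", "invalid_scores")
  s <- scores[ok]
  med <- stats::median(s)
  scale0 <- stats::mad(s)
  if (scale0 == 0) ts_error("score distribution degenerate (MAD = 0)", "degenerate")
  z <- (s - med) / scale0

  lo <- (1 - central_band) / 2
  qs <- stats::quantile(z, c(lo, 1 - lo), names = FALSE)
  z0 <- z[z >= qs[1] & z <= qs[2]]
  # sd of a standard normal truncated to its central `central_band` mass
  b <- stats::qnorm(0.5 + central_band / 2)
  k0 <- sqrt(1 - 2 * b * stats::dnorm(b) / central_band)
  sigma <- stats::sd(z0) / k0
  if (!is.finite(sigma) || sigma <= 0) ts_error("null scale estimation failed", "degenerate")

  zz <- z / sigma
  eta0 <- min(1, mean(abs(zz) <= b) / central_band)
  p <- 2 * stats::pnorm(-abs(zz))
  n <- length(p)
  o <- order(p)
  fdr_sorted <- pmin(1, eta0 * p[o] * n / seq_len(n))
  fdr_sorted <- rev(cummin(rev(fdr_sorted)))
  fdr <- numeric(n); fdr[o] <- fdr_sorted

  out_fdr <- rep(NA_real_, length(scores)); out_fdr[ok] <- fdr
  out_z <- rep(NA_real_, length(scores)); out_z[ok] <- zz
  list(fdr = out_fdr, z = out_z, sigma = sigma, eta0 = eta0)
}
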