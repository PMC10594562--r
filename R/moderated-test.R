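#' Empirical-Bayes moderated two-sample t-test
#'
#' Per protein, the log2 fold change is the difference of group means and the
#' pooled sample variance `s^2` has `d = nA + nB - 2` degrees of freedom.
#' Variances are shrunk toward a prior: the hyperparameters `d0` (prior df)
#' and `s0^2` (prior variance) are fit across proteins by moment-matching the
#' scaled-F distribution of `s^2` on the log scale (Smyth's closed-form
#' estimator), the posterior variance is
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)`, and the moderated statistic
#' `t = log2FC / (s~ sqrt(1/nA + 1/nB))` is referred to a t distribution on
#' `d0 + d` degrees of freedom. Two-sided p-values are Benjamini-Hochberg
#' adjusted.
#'
#' @param x numeric matrix (proteins x channels) on a log2-like scale.
#' @param treat_cols,ref_cols column indices of the two groups (>= 2 each).
#' @param prior_df override for `d0`; `0` disables moderation (ordinary
#'   equal-variance t-test), `Inf` fully pools. Default `NULL`: estimate.
#' @return data frame (`protein`, `log2fc`, `t`, `df`, `p`, `adj_p`) with the
#'   fitted hyperparameters in attributes `prior_df` and `prior_var`.
#' @export
moderated_ttest <- function(x, treat_cols, ref_cols, prior_df = NULL) {
  x <- as.matrix(x)
  na <- length(treat_cols); nb <- length(ref_cols)
  if (na < 2L || nb < 2L) ts_error("need >= 2 channels per side", "invalid_test")
  d <- na + nb - 2L
  if (d < 1L) ts_error("zero residual degrees of freedom", "invalid_test")
  xa <- x[, treat_cols, drop = FALSE]; xb <- x[, ref_cols, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ss <- rowSums((xa - ma)^2) + rowSums((xb - mb)^2)
  s2 <- ss / d
  fc <- ma - mb

  hyper <- if (is.null(prior_df)) squeeze_variances(s2, d)
           else forced_squeeze(s2, d, prior_df)
  post <- posterior_variance(s2, d, hyper$prior_df, hyper$prior_var)
  se <- sqrt(post * (1 / na + 1 / nb))
  tt <- fc / se
  dft <- hyper$prior_df + d
  p <- if (is.finite(dft)) 2 * stats::pt(-abs(tt), dft) else 2 * stats::pnorm(-abs(tt))
  res <- data.frame(protein = if (!is.null(rownames(x))) rownames(x) else seq_len(nrow(x)),
                    log2fc = fc, t = tt, df = dft, p = p,
                    adj_p = stats::p.adjust(p, method = "BH"),
                    row.names = NULL)
  attr(res, "prior_df") <- hyper$prior_df
  attr(res, "prior_var") <- hyper$prior_var
  res
}

# Smyth's closed-form moment estimator of (d0, s0^2) from log sample variances
squeeze_variances <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) ts_error("too few positive variances to moderate", "invalid_test")
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(emean)
  }
  list(prior_df = d0, prior_var = s0)
}

forced_squeeze <- function(s2, d, prior_df) {
  if (prior_df == 0) return(list(prior_df = 0, prior_var = NA_real_))
  est <- squeeze_variances(s2, d)
  list(prior_df = prior_df, prior_var = est$prior_var)
}

posterior_variance <- function(s2, d, d0, s02) {
  if (d0 == 0) return(s2)
  if (!is.finite(d0)) return(rep(s02, length(s2)))
  (d0 * s02 + d * s2) / (d0 + d)
}

# solve trigamma(x) = y; monotone decreasing, bracketed bisection via uniroot
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  f <- function(lx) trigamma(exp(lx)) - y
  exp(stats::uniroot(f, c(log(1e-8), log(1e8)), tol = 1e-14)$root)
}

#' Moderated one-sample test of per-replicate scores against zero
#'
#' The per-protein replicate scores (e.g. per-replicate stability scores) are
#' tested against zero with the same variance-shrinkage machinery as
#' [moderated_ttest()]: `t = mean / (s~ / sqrt(n))` on `d0 + n - 1` df.
#'
#' @param scores numeric matrix, proteins x replicates (>= 2 replicates).
#' @return data frame (`protein`, `score`, `t`, `df`, `p`, `adj_p`).
#' @export
moderated_one_sample <- function(scores) {
  scores <- as.matrix(scores)
  n <- ncol(scores)
  if (n < 2L) ts_error("need >= 2 replicates", "invalid_test")
  d <- n - 1L
  m <- rowMeans(scores)
  s2 <- rowSums((scores - m)^2) / d
  hyper <- squeeze_variances(s2, d)
  post <- posterior_variance(s2, d, hyper$prior_df, hyper$prior_var)
  tt <- m / sqrt(post / n)
  dft <- hyper$prior_df + d
  p <- if (is.finite(dft)) 2 * stats::pt(-abs(tt), dft) else 2 * stats::pnorm(-abs(tt))
  res <- data.frame(protein = if (!is.null(rownames(scores))) rownames(scores)
                              else seq_len(nrow(scores)),
                    score = m, t = tt, df = dft, p = p,
                    adj_p = stats::p.adjust(p, method = "BH"), row.names = NULL)
  attr(res, "prior_df") <- hyper$prior_df
  attr(res, "prior_var") <- hyper$prior_var
  res
}
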