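#' Generalized-log variance stabilizing normalization
#'
#' Transforms each channel with `h_c(x) = glog2((x - a_c) / b_c)`, where
#' `glog2(y) = log2(y + sqrt(y^2 + 1))`. The affine offset `a_c` absorbs the
#' additive background of the channel (the "background correction") and the
#' scale `b_c` both equalizes channel loadings and sets the intensity below
#' which the transform linearizes, so measurement variance becomes
#' approximately independent of signal. Parameters are fit per channel within
#' each normalization group by least-trimmed squares (trim fraction 10%)
#' against per-protein group means, then the scales receive a final exact
#' median-equalization within the group.
#'
#' Groups express the layout, and channels sharing a group must measure the
#' same quantity per protein up to noise and the channel transform: one group
#' per ladder temperature for TPP (normalizing each temperature independently
#' accounts for the globally decreasing signal at higher temperatures), and
#' one group per role (ramped test channels vs 37 degC control channels) for
#' STPP-UP/isothermal layouts, since each protein carries a systematic,
#' protein-specific survival offset between the two heating programs that the
#' per-protein group-mean model must not be asked to absorb.
#'
#' @param mat an [intensity_matrix()] or plain numeric matrix.
#' @param groups factor/vector over channels defining normalization groups.
#'   Defaults per the layout: ladder temperature if present, then role if
#'   present, else a single group.
#' @param trim fraction of proteins excluded from the fit as potential
#'   outliers (default 0.1).
#' @return A list of class `vst_fit` with `matrix` (transformed values, log2
#'   scale) and `params` (data frame of per-channel `a`, `b`, `group`).
#' @export
variance_stabilize <- function(mat, groups = NULL, trim = 0.1) {
  is_im <- inherits(mat, "intensity_matrix")
  x <- if (is_im) mat$intensities else as.matrix(mat)
  if (is.null(groups)) {
    groups <- if (is_im && any(!is.na(mat$channel_meta$temperature))) {
      mat$channel_meta$temperature
    } else if (is_im && !any(is.na(mat$channel_meta$role))) {
      mat$channel_meta$role
    } else rep(1L, ncol(x))
  }
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(x))

  out <- x * NA_real_
  params <- data.frame(channel = seq_len(ncol(x)), group = as.character(groups),
                       a = NA_real_, b = NA_real_)
  for (g in levels(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2L) {
      ts_error(sprintf("normalization group '%s' has a single channel", g), "degenerate_group")
    }
    xg <- x[, cols, drop = FALSE]
    if (all(xg == 0)) {
      ts_error(sprintf("normalization group '%s' is all zero", g), "degenerate_group")
    }
    fit <- vst_fit_group(xg, trim = trim)
    out[, cols] <- fit$h
    params$a[cols] <- fit$a
    params$b[cols] <- fit$b
  }
  structure(list(matrix = out, params = params), class = "vst_fit")
}

glog2 <- function(y) asinh(y) / log(2)

# fit one normalization group by trimmed profile maximum likelihood on
# (a_c, log b_c): Gaussian ML of transformed values around per-protein means
# includes the log-Jacobian of the transform, which pins down the scales
# (plain least squares is degenerate: inflating every b collapses all
# residuals). Then an exact median equalization through the scale parameters.
vst_fit_group <- function(xg, trim = 0.1, outer_iterations = 2L) {
  # canonical internal channel order, so the fit (and its floating-point
  # path) is invariant to how the caller ordered the columns
  key <- rank(apply(xg, 2, stats::median), ties.method = "first")
  ord <- order(key)
  fit <- vst_fit_group_ordered(xg[, ord, drop = FALSE], trim,
                               outer_iterations = outer_iterations)
  inv <- order(ord)
  list(h = fit$h[, inv, drop = FALSE], a = fit$a[inv], b = fit$b[inv])
}

vst_fit_group_ordered <- function(xg, trim = 0.1, outer_iterations = 2L,
                                  maxit = 100L) {
  n <- nrow(xg); C <- ncol(xg)
  b0 <- pmax(apply(xg, 2, stats::quantile, probs = 0.25), 1e-9)
  theta <- c(rep(0, C), rep(0, C))   # alpha (a / b0), log(b / b0)
  keep_n <- max(2L, floor((1 - trim) * n))
  ln2 <- log(2)

  transform_all <- function(theta) {
    a <- theta[seq_len(C)] * b0
    b <- b0 * exp(theta[C + seq_len(C)])
    y <- sweep(sweep(xg, 2, a, "-"), 2, b, "/")
    list(h = asinh(y) / ln2, y = y, a = a, b = b)
  }
  trim_set <- seq_len(n)
  eps <- 1e-12
  # profile nll: (M/2) log(RSS) - sum log h'(x), both over the trimmed set
  obj <- function(theta) {
    tr <- transform_all(theta)
    yk <- tr$y[trim_set, , drop = FALSE]
    r <- (tr$h - rowMeans(tr$h))[trim_set, , drop = FALSE]
    m <- length(r)
    rss <- sum(r^2)
    logjac <- -m * log(ln2) - length(trim_set) * sum(log(tr$b)) -
      0.5 * sum(log1p(yk^2))
    (m / 2) * log(rss / m + eps) - logjac
  }
  grad <- function(theta) {
    tr <- transform_all(theta)
    r <- tr$h - rowMeans(tr$h)
    r[-trim_set, ] <- 0
    m <- length(trim_set) * C
    rss <- sum(r^2)
    denom2 <- 1 + tr$y^2
    denom <- sqrt(denom2)
    pref <- (m / 2) / (rss + m * eps)
    # d h / d a = -1 / (ln2 b denom); d h / d log b = -y / (ln2 denom)
    dh_da <- sweep(-1 / (ln2 * denom), 2, tr$b, "/")
    dh_ds <- -tr$y / (ln2 * denom)
    # d log h' / d a = y / (b denom2); d log h' / d log b = -1 / denom2
    dj_da <- sweep(tr$y / denom2, 2, tr$b, "/")
    dj_ds <- -1 / denom2
    dj_da[-trim_set, ] <- 0; dj_ds[-trim_set, ] <- 0
    ga <- (pref * colSums(2 * r * dh_da) - colSums(dj_da)) * b0
    gs <- pref * colSums(2 * r * dh_ds) - colSums(dj_ds)
    c(ga, gs)
  }

  for (it in seq_len(outer_iterations)) {
    tr <- transform_all(theta)
    r <- tr$h - rowMeans(tr$h)
    ss <- rowSums(r^2)
    trim_set <- order(ss)[seq_len(keep_n)]
    opt <- stats::optim(theta, obj, grad, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-12))
    theta <- opt$par
  }

  tr <- transform_all(theta)
  a <- tr$a; b <- tr$b
  # exact median equalization: for a monotone transform the channel median is
  # determined by the middle raw order statistics, so solve for b_c directly
  mids <- apply(xg, 2, middle_values)
  med_h <- vapply(seq_len(C), function(c) mean(glog2((mids[, c] - a[c]) / b[c])),
                  numeric(1))
  target <- mean(med_h)
  for (c in seq_len(C)) {
    if (any(mids[, c] - a[c] <= 0)) next
    f <- function(logb) mean(glog2((mids[, c] - a[c]) / exp(logb))) - target
    lo <- log(b[c]) - 20; hi <- log(b[c]) + 20
    if (f(lo) * f(hi) < 0) {
      b[c] <- exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
    }
  }
  y <- sweep(sweep(xg, 2, a, "-"), 2, b, "/")
  list(h = asinh(y) / ln2, a = a, b = b)
}

middle_values <- function(x) {
  s <- sort(x); n <- length(s)
  if (n %% 2L == 1L) rep(s[(n + 1L) / 2L], 2L) else s[c(n / 2L, n / 2L + 1L)]
}

#' Remove additive batch effects
#'
#' Per protein, subtracts batch means estimated from a linear model in which
#' the condition contrast is retained as a covariate, so balanced condition
#' effects pass through unchanged. A single batch is returned unchanged; a
#' design in which some batch lacks a condition level is rejected as
#' confounded.
#'
#' @param x numeric matrix (proteins x channels), typically variance-stabilized.
#' @param batch batch label per channel.
#' @param condition condition label per channel.
#' @return matrix of the same shape.
#' @export
remove_batch_effects <- function(x, batch, condition) {
  x <- as.matrix(x)
  batch <- as.factor(batch); condition <- as.factor(condition)
  stopifnot(length(batch) == ncol(x), length(condition) == ncol(x))
  if (nlevels(batch) < 2L) return(x)
  if (any(table(batch, condition) == 0)) {
    ts_error("confounded design: every batch must contain every condition", "confounded")
  }
  design <- stats::model.matrix(~condition)
  limma::removeBatchEffect(x, batch = batch, design = design)
}
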