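#' Sigmoid melting curve
#'
#' Soluble fraction as a decreasing logistic in temperature,
#' `f(T) = (1 - plateau) / (1 + exp(steepness * (T - midpoint))) + plateau`.
#' The `plateau` is the non-denaturing fraction remaining at high temperature;
#' at the `midpoint` the curve passes through `(1 + plateau) / 2`.
#'
#' @param midpoint curve midpoint in degC.
#' @param steepness transition steepness in 1/degC (> 0).
#' @param plateau high-temperature plateau fraction in \[0, 1).
#' @return An object of class `melt_curve`.
#' @export
melt_curve <- function(midpoint, steepness, plateau = 0) {
  if (!is.finite(midpoint)) ts_error("midpoint must be finite", "invalid_curve")
  if (!is.finite(steepness) || steepness <= 0) {
    ts_error("steepness must be finite and > 0", "invalid_curve")
  }
  if (!is.finite(plateau) || plateau < 0 || plateau >= 1) {
    ts_error("plateau must lie in [0, 1)", "invalid_curve")
  }
  structure(list(midpoint = midpoint, steepness = steepness, plateau = plateau),
            class = "melt_curve")
}

#' @rdname melt_curve
#' @param curve a `melt_curve`.
#' @param temperature temperature(s) in degC.
#' @export
melt_fraction <- function(curve, temperature) {
  stopifnot(inherits(curve, "melt_curve"))
  (1 - curve$plateau) / (1 + exp(curve$steepness * (temperature - curve$midpoint))) +
    curve$plateau
}

#' Fit a melting curve to fraction-versus-temperature data
#'
#' Nonlinear least squares over a fixed multi-start grid, so the fit is
#' deterministic given the data. Data that cannot define a melting transition
#' (near-constant fractions, or a fit that fails from every start) yield a
#' flagged failure, not an exception.
#'
#' @param temperatures vector of at least 4 distinct temperatures (degC).
#' @param fractions soluble fractions at those temperatures (finite).
#' @return A list of class `melt_curve_fit` with elements `curve` (a
#'   [melt_curve()] or `NULL`), `rss` (residual sum of squares), `converged`,
#'   and `message`.
#' @export
fit_melt_curve <- function(temperatures, fractions) {
  stopifnot(is.numeric(temperatures), is.numeric(fractions),
            length(temperatures) == length(fractions))
  if (length(unique(temperatures)) < 4L) {
    ts_error("need at least 4 distinct temperatures", "invalid_curve")
  }
  if (!all(is.finite(fractions))) ts_error("fractions must be finite", "invalid_curve")
  ord <- order(temperatures)
  tt <- temperatures[ord]; ff <- fractions[ord]

  failed <- function(msg) {
    structure(list(curve = NULL, rss = NA_real_, converged = FALSE, message = msg),
              class = "melt_curve_fit")
  }
  if (diff(range(ff)) < 0.05) return(failed("no melting transition in the data"))

  # data-driven midpoint guess: first crossing of the half-range level
  half <- (max(ff) + min(ff)) / 2
  below <- which(ff <= half)
  tm_guess <- if (length(below)) tt[below[1]] else stats::median(tt)
  starts <- expand.grid(
    midpoint  = unique(pmin(pmax(c(tm_guess - 4, tm_guess, tm_guess + 4), 30), 90)),
    steepness = c(0.3, 0.8, 2),
    plateau   = c(0, 0.1)
  )

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      ff ~ (1 - plateau) / (1 + exp(steepness * (tt - midpoint))) + plateau,
      start = as.list(starts[i, ]),
      lower = c(midpoint = 20, steepness = 1e-3, plateau = 0),
      upper = c(midpoint = 95, steepness = 25, plateau = 0.999),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )), error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(failed("nonlinear least squares failed from every start"))

  cf <- stats::coef(best$fit)
  if (cf[["plateau"]] >= 0.999 || cf[["steepness"]] <= 2e-3) {
    return(failed("degenerate fit (no resolvable transition)"))
  }
  structure(list(
    curve = melt_curve(cf[["midpoint"]], cf[["steepness"]], min(cf[["plateau"]], 1 - 1e-9)),
    rss = best$rss, converged = TRUE, message = "ok"
  ), class = "melt_curve_fit")
}

#' @export
print.melt_curve_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<melt_curve_fit: midpoint %.2f degC, steepness %.3f /degC, plateau %.3f, RSS %.3g>\n",
                x$curve$midpoint, x$curve$steepness, x$curve$plateau, x$rss))
  } else {
    cat(sprintf("<melt_curve_fit: FAILED (%s)>\n", x$message))
  }
  invisible(x)
}

#' Melting temperature relative to a reference temperature
#'
#' T_m-50: the temperature at which the soluble fraction falls to 50% of its
#' value at the reference (lowest ladder) temperature. Closed form from the
#' sigmoid; errors if the 50% level lies at or below the plateau and is never
#' reached.
#'
#' @param curve a [melt_curve()] or a converged [fit_melt_curve()] result.
#' @param reference_temperature reference in degC (default 37).
#' @return temperature in degC.
#' @export
tm50 <- function(curve, reference_temperature = 37) {
  if (inherits(curve, "melt_curve_fit")) {
    if (!curve$converged) ts_error("cannot take tm50 of a failed fit", "no_tm50")
    curve <- curve$curve
  }
  stopifnot(inherits(curve, "melt_curve"))
  level <- 0.5 * melt_fraction(curve, reference_temperature)
  if (level <= 0) ts_error("reference fraction must be > 0", "no_tm50")
  if (curve$plateau >= level) {
    ts_error("plateau at or above the 50% level: the curve never reaches it", "no_tm50")
  }
  # solve (1 - p) / (1 + e^{k (T - Tm)}) + p = level
  arg <- (1 - curve$plateau) / (level - curve$plateau) - 1
  curve$midpoint + log(arg) / curve$steepness
}
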