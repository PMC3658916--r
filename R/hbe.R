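# Histogram-based LFDR estimation on z-transformed p-values, after Efron's
# two-group mixture: f(z) = Pi0 f0(z) + (1 - Pi0) f1(z).

#' Transform p-values to z-scores
#'
#' `z = qnorm(p)` after clamping p into `[eps, 1 - eps]`. Clamping matters
#' because discrete exact tests routinely produce p-values of exactly 1,
#' which would otherwise map to infinity.
#'
#' @param p Vector of p-values in (0, 1].
#' @param eps Clamping tolerance.
#' @return Vector of finite z-values.
#' @export
z_from_p <- function(p, eps = 1e-12) {
  check_pvalues(p)
  stats::qnorm(pmin(pmax(p, eps), 1 - eps))
}

#' Fit the marginal z-density by histogram Poisson regression
#'
#' Bins the z-values into `bins` equal-width bins (padded by 1% of the data
#' range on each side), models the bin counts by a log-linear Poisson
#' regression on a natural-spline basis with `df` degrees of freedom, and
#' normalizes the fitted curve to integrate to 1 over the grid. This is the
#' standard smooth-histogram estimate of the mixture marginal used by
#' large-scale empirical-Bayes methods.
#'
#' @param z Vector of z-values (length at least 2, not all identical).
#' @param bins Number of histogram bins.
#' @param df Degrees of freedom of the spline basis.
#' @return An object of class `hbe_density` with the fitted grid and an
#'   interpolator; `predict()` evaluates the density at new z-values.
#' @export
fit_marginal_density <- function(z, bins = 120, df = 7) {
  if (length(z) < 2L) stop("need at least 2 z-values", call. = FALSE)
  rng <- range(z)
  if (diff(rng) == 0) {
    stop("all z-values identical; density estimation needs more varied data",
         call. = FALSE)
  }
  pad <- 0.01 * diff(rng)
  breaks <- seq(rng[1] - pad, rng[2] + pad, length.out = bins + 1L)
  h <- graphics::hist(z, breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  width <- diff(breaks)[1]
  basis <- splines::ns(mids, df = df)
  fit <- suppressWarnings(stats::glm(counts ~ basis, family = stats::poisson()))
  lambda <- exp(stats::predict(fit))
  dens <- lambda / (sum(lambda) * width)
  structure(
    list(mids = mids, breaks = breaks, counts = counts, density = dens,
         bins = bins, df = df,
         interp = stats::approxfun(mids, dens, rule = 2)),
    class = "hbe_density"
  )
}

#' @param object An `hbe_density` fit.
#' @param newdata Z-values at which to evaluate the fitted density.
#' @param ... Unused.
#' @rdname fit_marginal_density
#' @export
predict.hbe_density <- function(object, newdata, ...) {
  object$interp(newdata)
}

#' Empirical null from the central z-values (truncated-normal MLE)
#'
#' Fits a normal null density N(delta, sigma^2) to the z-values falling in a
#' central quantile window covering `central_fraction` of the data, by
#' maximizing the truncated-normal likelihood on that window. This recovers
#' the null component when most categories are null and the tails hold the
#' signal. With `central_fraction >= 1` the window is unbounded and the fit
#' reduces to the ordinary normal MLE.
#'
#' @param z Vector of z-values.
#' @param central_fraction Fraction of the data in the central window.
#' @return List with elements `delta` (mean), `sigma` (sd) and `window`.
#' @export
fit_empirical_null <- function(z, central_fraction = 0.5) {
  if (length(z) < 2L) stop("need at least 2 z-values", call. = FALSE)
  if (central_fraction >= 1) {
    a <- -Inf; b <- Inf
    zc <- z
  } else {
    qs <- stats::quantile(z, c((1 - central_fraction) / 2,
                               (1 + central_fraction) / 2), names = FALSE)
    a <- qs[1]; b <- qs[2]
    zc <- z[z >= a & z <= b]
  }
  if (length(zc) < 2L) {
    stop("fewer than 2 z-values in the central window", call. = FALSE)
  }
  nll <- function(par) {
    mu <- par[1]; sd <- exp(par[2])
    mass <- stats::pnorm(b, mu, sd) - stats::pnorm(a, mu, sd)
    if (mass <= 0) return(Inf)
    -sum(stats::dnorm(zc, mu, sd, log = TRUE)) + length(zc) * log(mass)
  }
  s0 <- stats::sd(zc)
  if (!is.finite(s0) || s0 <= 0) s0 <- 0.1
  # Nelder-Mead: the profile in log sigma flattens for narrow windows and
  # gradient methods can run off the ridge
  opt <- stats::optim(c(mean(zc), log(s0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(delta = opt$par[1], sigma = exp(opt$par[2]), window = c(a, b))
}

#' Histogram-based LFDR estimators (HBE, HBE-EN)
#'
#' Estimates per-category LFDRs as the ratio `f0(z_i) / f(z_i)` capped at 1,
#' where `f` is the smoothed marginal of the z-transformed p-values and `f0`
#' is either the theoretical standard-normal null (HBE) or an empirical null
#' fitted to the central z-values (HBE-EN). The printed estimator carries no
#' null-proportion factor; supply `pi0` to multiply the ratio by an assumed
#' null proportion.
#'
#' @param p Vector of p-values in (0, 1].
#' @param null `"theoretical"` (standard normal f0) or `"empirical"`
#'   (truncated-normal MLE f0).
#' @param bins,df Histogram and spline parameters of the marginal fit.
#' @param central_fraction Central window for the empirical null.
#' @param pi0 Optional null proportion multiplying the density ratio.
#' @return Vector of LFDR estimates in \[0, 1\], aligned with `p`.
#' @export
lfdr_hbe <- function(p, null = c("theoretical", "empirical"), bins = 120,
                     df = 7, central_fraction = 0.5, pi0 = NULL) {
  null <- match.arg(null)
  z <- z_from_p(p)
  fit <- fit_marginal_density(z, bins = bins, df = df)
  f <- predict(fit, z)
  f0 <- if (null == "theoretical") {
    stats::dnorm(z)
  } else {
    en <- fit_empirical_null(z, central_fraction)
    stats::dnorm(z, en$delta, en$sigma)
  }
  ratio <- f0 / f
  if (!is.null(pi0)) ratio <- pi0 * ratio
  pmin(ratio, 1)
}
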