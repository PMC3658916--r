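# Binomial-based LFDR estimation from ranked p-values.

check_pvalues <- function(p) {
  if (length(p) < 1L) stop("need at least one p-value", call. = FALSE)
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Nonlocal (Bayesian) FDR estimate at a significance level
#'
#' Estimates the ratio of expected false discoveries to expected discoveries
#' at level `alpha` as `min(m * alpha / #\{p_j <= alpha\}, 1)`. With zero
#' discoveries the estimate is the conservative value 1.
#'
#' @param p Vector of p-values in (0, 1].
#' @param alpha Significance level in (0, 1).
#' @return A single FDR estimate in (0, 1].
#' @examples
#' nonlocal_fdr(c(0.001, 0.01, 0.2, 0.9), alpha = 0.05) # 0.1
#' @export
nonlocal_fdr <- function(p, alpha) {
  check_pvalues(p)
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single value in (0, 1)", call. = FALSE)
  }
  d <- sum(p <= alpha)
  if (d == 0) return(1)
  min(length(p) * alpha / d, 1)
}

#' Binomial-based LFDR estimator (BBE)
#'
#' A conservative rank-doubling modification of the nonlocal-FDR estimate:
#' the category whose p-value has rank r (rank 1 = smallest) receives
#' `min(m * p_(2r) / (2r), 1)` when r is at most m/2, where `p_(k)` is the
#' k-th smallest p-value, and 1 otherwise. Ties are ranked in stable input order,
#' so results are deterministic. The estimator tends to overestimate the LFDR,
#' which is what makes it safe for small numbers of categories.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of LFDR estimates in \[0, 1\], aligned with `p`.
#' @examples
#' lfdr_bbe(c(0.001, 0.01, 0.2, 0.9)) # 0.02 0.90 1.00 1.00
#' @export
lfdr_bbe <- function(p) {
  check_pvalues(p)
  m <- length(p)
  r <- rank(p, ties.method = "first")
  ps <- sort(p)
  out <- rep(1, m)
  use <- r <= m / 2
  out[use] <- pmin(m * ps[2 * r[use]] / (2 * r[use]), 1)
  out
}
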