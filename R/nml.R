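# Normalized maximum likelihood for a single 2x2 enrichment table.
# The NML predictive pmf under a hypothesis set H is
#   f_dagger(t|s; H) = max_{theta in H} f_theta(t|s) / K(H),
#   K(H) = sum_y max_{theta in H} f_theta(y|s),
# the unique minimax-regret predictive distribution over the support.
# H is {0} (null), R \ {0} (alternative) or R (full); the supremum over the
# alternative set equals the maximum over its closure R by continuity.

check_hypothesis <- function(hypothesis) {
  match.arg(hypothesis, c("full", "alternative", "null"))
}

#' Conditional MLE of the log odds ratio for one outcome
#'
#' Maximizer of `f_theta(y|s)` over a hypothesis set: `0` for the null set;
#' for the full or alternative set, the solution of the score equation for
#' interior outcomes and `-Inf` / `+Inf` sentinels at the support endpoints,
#' where the supremum is a limit with pmf value 1.
#'
#' @param y Outcome (count in the support of T given S = s).
#' @param s,n,N Table margins.
#' @param hypothesis `"full"`, `"alternative"` or `"null"`.
#' @return The maximizing log odds ratio (possibly `-Inf` or `Inf`).
#' @export
mle_theta_conditional <- function(y, s, n, N,
                                  hypothesis = c("full", "alternative", "null")) {
  hypothesis <- check_hypothesis(hypothesis)
  if (hypothesis == "null") return(0)
  r <- support_range(s, n, N)
  if (y < r[1] || y > r[2] || y != round(y)) {
    stop("`y` must lie in the support of T given S = s", call. = FALSE)
  }
  if (r[1] == r[2]) return(0)       # degenerate support: pmf is 1 for all theta
  if (y == r[1]) return(-Inf)
  if (y == r[2]) return(Inf)
  sw <- support_log_weights(s, n, N)
  pos <- match(y, sw$y)
  obj <- function(theta) sw$lw[pos] + y * theta - log_sum_exp(sw$lw + sw$y * theta)
  stats::optimize(obj, c(-50, 50), maximum = TRUE, tol = 1e-10)$maximum
}

# per-outcome maximized pmf values over the support (sup = 1 at endpoints)
nml_profile <- function(s, n, N, hypothesis = "full") {
  hypothesis <- check_hypothesis(hypothesis)
  r <- support_range(s, n, N)
  y <- seq.int(r[1], r[2])
  if (hypothesis == "null") {
    return(tibble::tibble(y = y, theta_hat = 0,
                          f_max = cond_pmf(y, s, n, N, 0)))
  }
  th <- vapply(y, function(yy) mle_theta_conditional(yy, s, n, N, hypothesis),
               numeric(1))
  f <- numeric(length(y))
  for (i in seq_along(y)) {
    f[i] <- if (is.finite(th[i])) cond_pmf(y[i], s, n, N, th[i]) else 1
  }
  tibble::tibble(y = y, theta_hat = th, f_max = f)
}

#' NML normalizing constant
#'
#' `K(H) = sum_y max_{theta in H} f_theta(y|s)` over the support of T given
#' S = s, using the limiting supremum value 1 at the support endpoints. For
#' the null set `K = 1` exactly.
#'
#' @inheritParams mle_theta_conditional
#' @return The normalizer (>= 1 for the full and alternative sets).
#' @examples
#' nml_constant(s = 2, n = 3, N = 6, hypothesis = "alternative") # 2.6
#' @export
nml_constant <- function(s, n, N, hypothesis = c("full", "alternative", "null")) {
  hypothesis <- check_hypothesis(hypothesis)
  if (hypothesis == "null") return(1)
  sum(nml_profile(s, n, N, hypothesis)$f_max)
}

#' NML predictive pmf value
#'
#' @inheritParams mle_theta_conditional
#' @param t Observed count.
#' @return `f_dagger(t|s; H)`, the minimax-regret predictive probability.
#' @export
nml_pmf <- function(t, s, n, N, hypothesis = c("full", "alternative", "null")) {
  hypothesis <- check_hypothesis(hypothesis)
  prof <- nml_profile(s, n, N, hypothesis)
  pos <- match(t, prof$y)
  if (anyNA(pos)) stop("`t` must lie in the support", call. = FALSE)
  prof$f_max[pos] / sum(prof$f_max)
}

#' Regret of a predictive pmf at an observed outcome
#'
#' Log-loss excess of the predictive value `fbar` relative to the best
#' hindsight member of the family: `log(f_thetahat(t)(t|s) / fbar)`. The NML
#' pmf equalizes the regret at `log K(H)` over the whole support; every other
#' predictive pmf has a larger maximum regret.
#'
#' @param fbar Predictive probability assigned to the observed `t` (> 0).
#' @inheritParams nml_pmf
#' @return Regret in nats (`Inf` if `fbar` is 0).
#' @export
nml_regret <- function(fbar, t, s, n, N,
                       hypothesis = c("full", "alternative", "null")) {
  hypothesis <- check_hypothesis(hypothesis)
  if (fbar < 0) stop("`fbar` must be nonnegative", call. = FALSE)
  if (fbar == 0) return(Inf)
  prof <- nml_profile(s, n, N, hypothesis)
  pos <- match(t, prof$y)
  if (anyNA(pos)) stop("`t` must lie in the support", call. = FALSE)
  log(prof$f_max[pos] / fbar)
}

#' NML ratio: minimax-regret approximation of the Bayes factor
#'
#' Ratio of the NML predictive pmf under the alternative hypothesis set to
#' that under the null: `[max_theta f_theta(t|s) / K(alt)] / f_0(t|s)`.
#' Computed per table, so it works with data for a single category.
#'
#' @param t,s Observed count and category size (vectorized, recycled).
#' @param n,N Study totals.
#' @return Vector of Bayes-factor approximations.
#' @examples
#' nml_ratio(1, s = 2, n = 3, N = 6) # 1 / 2.6
#' @export
nml_ratio <- function(t, s, n, N) {
  check_totals(n, N)
  len <- max(length(t), length(s))
  t <- rep_len(t, len); s <- rep_len(s, len)
  out <- numeric(len)
  for (si in unique(s)) {
    idx <- which(s == si)
    prof <- nml_profile(si, n, N, "alternative")
    K <- sum(prof$f_max)
    pos <- match(t[idx], prof$y)
    if (anyNA(pos)) stop("`t` outside the support of its table", call. = FALSE)
    f0 <- cond_pmf(t[idx], si, n, N, 0)
    out[idx] <- (prof$f_max[pos] / K) / f0
  }
  out
}

#' LFDR from a Bayes factor and a specified null proportion (NMLE)
#'
#' `LFDR = [1 + BF (1 - pi0)/pi0]^-1`: increasing in `pi0`, decreasing in the
#' Bayes factor. Unlike the mixture estimators this needs `pi0` supplied by
#' the analyst, which is the price of working with a single category; in the
#' absence of prior information 0.5 is the conventional default.
#'
#' @param bf Bayes-factor values (>= 0), e.g. from [nml_ratio()].
#' @param pi0 Prior null probability in \[0, 1\].
#' @return LFDR estimates in \[0, 1\].
#' @examples
#' lfdr_nmle(nml_ratio(1, 2, 3, 6), pi0 = 0.5) # about 0.722
#' @export
lfdr_nmle <- function(bf, pi0) {
  if (any(bf < 0)) stop("`bf` must be nonnegative", call. = FALSE)
  if (length(pi0) != 1L || pi0 < 0 || pi0 > 1) {
    stop("`pi0` must be a single probability", call. = FALSE)
  }
  if (pi0 == 1) return(rep(1, length(bf)))
  if (pi0 == 0) return(rep(0, length(bf)))
  1 / (1 + (1 - pi0) / pi0 * bf)
}
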