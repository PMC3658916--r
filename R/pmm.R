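# k-component parametric mixture of symmetrized conditional pmfs:
#   g(t|s) = sum_j Pi_j g_theta_j(t|s),  theta_0 = 0,
# fitted by type-II (marginal) maximum likelihood. The per-dataset
# precomputation groups categories by size s and stores, for each group, the
# log binomial-coefficient weights over the full support as one padded matrix,
# so a likelihood evaluation is a handful of vectorized matrix operations.

pmm_precompute <- function(data) {
  tot <- dataset_totals(data)
  n <- tot$n; N <- tot$N
  us <- sort(unique(data$s))
  sup <- lapply(us, support_log_weights, n = n, N = N)
  wdt <- vapply(sup, function(x) length(x$y), integer(1))
  W <- max(wdt)
  G <- length(us)
  LCH <- matrix(-Inf, G, W)
  Y <- matrix(0, G, W)
  for (g in seq_len(G)) {
    LCH[g, seq_len(wdt[g])] <- sup[[g]]$lw
    Y[g, seq_len(wdt[g])] <- sup[[g]]$y
  }
  gidx <- match(data$s, us)
  obs_lw <- lchoose(n, data$t) + lchoose(N - n, data$s - data$t)
  pc <- list(n = n, N = N, us = us, LCH = LCH, Y = Y, gidx = gidx,
             t = as.numeric(data$t), obs_lw = obs_lw, m = nrow(data))
  pc$logZ0 <- group_log_normalizer(pc, 0)
  pc
}

# log normalizer log sum_y exp(lch + y * theta), one value per size group
group_log_normalizer <- function(pc, theta) {
  V <- pc$LCH + pc$Y * theta
  M <- V[cbind(seq_len(nrow(V)), max.col(V, ties.method = "first"))]
  M + log(rowSums(exp(V - M)))
}

# log f_theta(t_i | s_i) for every observation
obs_log_pmf <- function(pc, theta) {
  logZ <- if (theta == 0) pc$logZ0 else group_log_normalizer(pc, theta)
  pc$obs_lw + pc$t * theta - logZ[pc$gidx]
}

# log g_theta(t_i | s_i), the symmetrized family
obs_log_sym_pmf <- function(pc, theta) {
  if (theta == 0) return(obs_log_pmf(pc, 0))
  a <- obs_log_pmf(pc, theta)
  b <- obs_log_pmf(pc, -theta)
  m <- pmax(a, b)
  m + log((exp(a - m) + exp(b - m)) / 2)
}

# m x k matrix of log g_theta_j(t_i | s_i), theta_0 = 0 first column
component_log_matrix <- function(pc, theta) {
  vapply(c(0, theta), function(th) obs_log_sym_pmf(pc, th), numeric(pc$m))
}

mixture_loglik <- function(pc, theta, pi) {
  L <- component_log_matrix(pc, theta)
  L <- sweep(L, 2, log(pi), "+")
  M <- do.call(pmax, as.data.frame(L))
  sum(M + log(rowSums(exp(L - M))))
}

#' Mixture log-likelihood of an enrichment dataset
#'
#' Log-likelihood of the k-component mixture whose null component has log
#' odds ratio 0 and whose non-null components have log odds magnitudes
#' `theta`, with mixing weights `pi` (first element is the null weight):
#' `sum_i log sum_j pi_j g_theta_j(t_i | s_i)`.
#'
#' @param data An `enrich_df` from [enrichment_data()].
#' @param theta Non-null log odds magnitudes (length k - 1, natural log).
#' @param pi Mixture weights (length k, nonnegative, summing to 1).
#' @return The log-likelihood (scalar).
#' @export
pmm_loglik <- function(data, theta, pi) {
  if (length(pi) != length(theta) + 1L) {
    stop("`pi` must have one more element than `theta`", call. = FALSE)
  }
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-9) {
    stop("`pi` must be a probability vector summing to 1", call. = FALSE)
  }
  if (any(theta < 0)) stop("`theta` magnitudes must be nonnegative", call. = FALSE)
  pc <- pmm_precompute(data)
  mixture_loglik(pc, theta, pi)
}

softmax <- function(b) {
  e <- exp(c(0, b) - max(0, b))
  e / sum(e)
}

#' Fit the k-component mixture by type-II maximum likelihood
#'
#' Maximizes the marginal likelihood over the non-null log odds magnitudes
#' (constrained to `[0, theta_max]`) and the mixture weights (on the
#' simplex), by multi-start quasi-Newton optimization on transformed
#' parameters: a scaled logit maps each magnitude onto its box and a softmax
#' maps free weights onto the simplex. The likelihood surface is multimodal,
#' hence the restarts; the fit is deterministic given `seed`.
#'
#' Requires at least 2 categories: with a single category the weights are not
#' identifiable and the only honest LFDR estimate is 1 (use the NML-based
#' estimator instead).
#'
#' @param data An `enrich_df` with at least 2 categories.
#' @param k Number of mixture components (>= 2); 2 and 3 give the MLE2 and
#'   MLE3 estimators.
#' @param restarts Number of optimizer starts (the first is deterministic).
#' @param seed Integer seed for the random starts.
#' @param theta_max Upper bound of the log odds magnitude box.
#' @return A `pmm_fit` object: estimates `theta` (sorted increasing), `pi`
#'   (null weight first), the maximized `loglik`, a `boundary` flag marking
#'   degenerate weight fits, and the data needed to score new LFDRs.
#' @examples
#' d <- enrichment_data(t = c(1, 2, 0, 3), s = c(2, 2, 3, 4), n = 3, N = 6)
#' fit <- fit_pmm(d, k = 2, restarts = 3)
#' tidy(fit)
#' @export
fit_pmm <- function(data, k = 2, restarts = 10, seed = 0, theta_max = 10) {
  if (nrow(data) < 2L) {
    stop("mixture estimators need data for at least 2 categories; ",
         "with 1 category use the NML-based estimator (lfdr_nmle)",
         call. = FALSE)
  }
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  pc <- pmm_precompute(data)
  kk <- as.integer(k)
  nth <- kk - 1L

  negll <- function(par) {
    theta <- theta_max * stats::plogis(par[seq_len(nth)])
    pi <- softmax(par[-seq_len(nth)])
    -mixture_loglik(pc, theta, pi)
  }

  # deterministic first start: magnitudes spread over the box, equal weights
  starts <- list(c(stats::qlogis(seq_len(nth) / kk), rep(0, nth)))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  for (r in seq_len(max(restarts - 1L, 0L))) {
    starts[[r + 1L]] <- c(stats::rnorm(nth, 0, 1.5), stats::rnorm(nth, 0, 1.5))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  best <- NULL
  conv <- FALSE
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      conv <- opt$convergence == 0
    }
  }
  if (is.null(best)) {
    stop("mixture optimization failed on every start", call. = FALSE)
  }

  theta <- theta_max * stats::plogis(best$par[seq_len(nth)])
  pi <- softmax(best$par[-seq_len(nth)])
  ord <- order(theta)
  theta <- theta[ord]
  pi <- c(pi[1], pi[-1][ord])
  boundary <- pi[1] < 1e-4 || pi[1] > 1 - 1e-4

  structure(
    list(k = kk, theta = theta, pi = pi, loglik = -best$value,
         restarts = restarts, seed = seed, theta_max = theta_max,
         converged = conv, boundary = boundary, m = pc$m,
         n = pc$n, N = pc$N, precomp = pc,
         category_id = data$category_id),
    class = "pmm_fit"
  )
}

#' Per-category LFDR from a fitted mixture (MLEk estimator)
#'
#' Posterior null probability of each category under the fitted mixture:
#' `pi0_hat g_0(t_i|s_i) / sum_j pi_hat_j g_theta_hat_j(t_i|s_i)`.
#'
#' @param fit A `pmm_fit` from [fit_pmm()].
#' @param data Optional `enrich_df`; defaults to the dataset the fit was
#'   produced on.
#' @return Vector of LFDR estimates in \[0, 1\].
#' @export
lfdr_mle <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "pmm_fit"))
  pc <- if (is.null(data)) fit$precomp else pmm_precompute(data)
  L <- component_log_matrix(pc, fit$theta)
  L <- sweep(L, 2, log(fit$pi), "+")
  M <- do.call(pmax, as.data.frame(L))
  logmix <- M + log(rowSums(exp(L - M)))
  pmin(exp(L[, 1] - logmix), 1)
}

#' Empirical-Bayes Bayes factor from an LFDR estimate
#'
#' Converts a posterior null probability back to a Bayes factor given the
#' estimated prior null proportion: `BF = [(1 - LFDR)/LFDR] * [pi0/(1 - pi0)]`,
#' the algebraic inverse of `LFDR = 1 / (1 + BF (1 - pi0)/pi0)`.
#'
#' @param lfdr LFDR estimates in (0, 1].
#' @param pi0 Estimated null proportion in (0, 1).
#' @return Bayes-factor estimates; `Inf` (with a warning) where `lfdr` is 0.
#' @export
eb_bayes_factor <- function(lfdr, pi0) {
  if (any(lfdr < 0 | lfdr > 1)) stop("`lfdr` must lie in [0, 1]", call. = FALSE)
  if (pi0 <= 0 || pi0 >= 1) stop("`pi0` must lie strictly in (0, 1)", call. = FALSE)
  if (any(lfdr == 0)) warning("LFDR of 0 maps to an infinite Bayes factor")
  (1 - lfdr) / lfdr * pi0 / (1 - pi0)
}

# ---- methods ----------------------------------------------------------------

#' @export
print.pmm_fit <- function(x, ...) {
  cat(sprintf("%d-component conditional-pmf mixture fit (m = %d categories, n = %d, N = %d)\n",
              x$k, x$m, x$n, x$N))
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  cat(sprintf("  null weight pi0: %.4f%s\n", x$pi[1],
              if (x$boundary) "  [boundary fit]" else ""))
  cat("  non-null components:\n")
  for (j in seq_along(x$theta)) {
    cat(sprintf("    theta_%d = %.4f   weight = %.4f\n", j, x$theta[j], x$pi[j + 1]))
  }
  invisible(x)
}

#' Tidy a fitted mixture
#'
#' @param x A `pmm_fit`.
#' @param ... Unused.
#' @return One row per mixture component: `component`, `theta` (log odds
#'   magnitude, 0 for the null) and `weight`.
#' @export
tidy.pmm_fit <- function(x, ...) {
  tibble::tibble(component = seq_len(x$k) - 1L,
                 theta = c(0, x$theta),
                 weight = x$pi)
}

#' One-row summary of a fitted mixture
#'
#' @param x A `pmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `m`, `loglik`, `pi0`, `boundary`,
#'   `converged`.
#' @export
glance.pmm_fit <- function(x, ...) {
  tibble::tibble(k = x$k, m = x$m, loglik = x$loglik, pi0 = x$pi[1],
                 boundary = x$boundary, converged = x$converged)
}

#' Plot a fitted mixture at a chosen category size
#'
#' Displays the null mass `pi0 f_0(t|s)` against the weighted alternative
#' mass `sum_j pi_j g_theta_j(t|s)` over the full support, for one category
#' size — the graphical check of whether the null or the alternative carries
#' an observed count.
#'
#' @param object A `pmm_fit`.
#' @param s Category size; defaults to the median size in the fitted data.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmm_fit <- function(object, s = NULL, ...) {
  if (is.null(s)) s <- stats::median(object$precomp$us)
  r <- support_range(s, object$n, object$N)
  y <- seq.int(r[1], r[2])
  null_mass <- object$pi[1] * cond_pmf(y, s, object$n, object$N, 0)
  alt_mass <- rowSums(vapply(seq_along(object$theta), function(j) {
    object$pi[j + 1] * sym_pmf(y, s, object$n, object$N, object$theta[j])
  }, numeric(length(y))))
  df <- tibble::tibble(
    t = rep(y, 2),
    mass = c(null_mass, alt_mass),
    hypothesis = rep(c("null (weighted)", "alternative (weighted)"),
                     each = length(y))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$mass,
                                   colour = .data$hypothesis)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "selected genes in category (t)",
                  y = "probability mass",
                  title = sprintf("Mixture components at category size s = %d", s))
}
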