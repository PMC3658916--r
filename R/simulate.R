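# Synthetic enrichment data: per category i a log2 odds ratio phi_i, a
# uniform draw pi1, the matched pi2 solving the odds-ratio equation, and
# binomial counts x1 ~ Bin(n, pi1), x2 ~ Bin(N - n, pi2). The log2 odds
# configurations reproduce the standard study designs: an asymmetric ladder,
# a symmetric (signed) ladder, and a set of fixed small-m configurations.

# fixed small-m configurations: list keyed by "m|pi0"
table_configs <- local({
  cfg <- list()
  put <- function(m, pi0, phi) cfg[[paste(m, pi0, sep = "|")]] <<- phi
  put(2, 0.5, c(0.5, 0))
  put(2, 1, c(0, 0))
  put(4, 0.5, c(3, -3, 0, 0))
  put(4, 0.75, c(0.5, 0, 0, 0))
  put(4, 1, rep(0, 4))
  put(8, 0.5, c(0.5 + 1.5 * (1:2 - 1), -(0.5 + 1.5 * (3:4 - 3)), rep(0, 4)))
  put(8, 0.625, c(0.5 + 1.5 * (1:2 - 1), -(0.5 + 1.5 * (3 - 2)), rep(0, 5)))
  put(8, 0.75, c(2, -2, rep(0, 6)))
  put(8, 0.875, c(2, rep(0, 7)))
  put(8, 1, rep(0, 8))
  put(32, 0.5, c(0.32 + 0.64 * (1:8 - 1), -(0.32 + 0.64 * (9:16 - 9)), rep(0, 16)))
  put(32, 0.625, c(0.8 + 0.8 * (1:3 - 1), -(0.8 + 0.8 * (4:6 - 4)), rep(0, 26)))
  put(32, 0.75, c(0.2 + 1.6 * (1:2 - 1), -(0.2 + 1.6 * (3:4 - 1)), rep(0, 28)))
  put(32, 0.875, c(1.8, -1.8, rep(0, 30)))
  put(32, 1, rep(0, 32))
  cfg
})

#' Log2 odds ratio configuration for a simulation study
#'
#' Returns the vector of per-category log2 odds ratios `phi_i` for a study
#' with `m` categories of which a proportion `pi0` is non-enriched.
#' Three schemes are available:
#' * `"asymmetric"`: `phi_i = 5 i / J` for the `J = round(m (1 - pi0))`
#'   enriched categories (all positive, an increasing ladder to 5), 0 after.
#' * `"symmetric"`: `phi_i = 10 i / J` for `i <= J/2` and `5 - 10 i / J`
#'   for `J/2 < i <= J` (balanced positive and negative ratios), 0 after.
#' * `"fixed"`: the tabulated small-study configurations for
#'   `m` in 2, 4, 8, 32 at their listed `pi0` values.
#'
#' @param m Number of categories.
#' @param pi0 Proportion of non-enriched categories in \[0, 1\].
#' @param scheme `"asymmetric"`, `"symmetric"` or `"fixed"`.
#' @return Numeric vector of `m` log2 odds ratios.
#' @examples
#' odds_ratio_config(100, 0.5, "asymmetric")[c(1, 50, 51)] # 0.1, 5, 0
#' odds_ratio_config(8, 0.75, "fixed") # 2, -2, 0 x 6
#' @export
odds_ratio_config <- function(m, pi0, scheme = c("asymmetric", "symmetric", "fixed")) {
  scheme <- match.arg(scheme)
  if (pi0 < 0 || pi0 > 1) stop("`pi0` must lie in [0, 1]", call. = FALSE)
  if (m < 1) stop("`m` must be at least 1", call. = FALSE)
  if (scheme == "fixed") {
    phi <- table_configs[[paste(m, pi0, sep = "|")]]
    if (is.null(phi)) {
      stop("no fixed configuration for m = ", m, ", pi0 = ", pi0,
           "; use the asymmetric or symmetric scheme", call. = FALSE)
    }
    return(phi)
  }
  J <- round(m * (1 - pi0))
  phi <- rep(0, m)
  if (J == 0) return(phi)
  i <- seq_len(J)
  if (scheme == "asymmetric") {
    phi[i] <- 5 * i / J
  } else {
    lower <- i <= J / 2
    phi[i[lower]] <- 10 * i[lower] / J
    phi[i[!lower]] <- 5 - 10 * i[!lower] / J
  }
  phi
}

# deterministic substream seed per (category, replicate); doubles avoid
# 32-bit overflow, result stays below 2^31
substream_seed <- function(seed, rep, i) {
  ((as.double(seed) %% 2147483647) * 1000003 + rep * 10007 + i * 101) %% 2147483647
}

#' Simulate an enrichment dataset
#'
#' For each category `i`: draw `pi1 ~ Uniform(0, 1)`, set
#' `pi2 = pi1 / (pi1 + (1 - pi1) 2^phi_i)` so the log2 odds ratio between
#' the selected and unselected pools is `phi_i`, then draw
#' `x1 ~ Binomial(n, pi1)` and `x2 ~ Binomial(N - n, pi2)`. The returned
#' dataset records `t = x1` and `s = x1 + x2` per category, plus the true
#' `phi`. Draws come from per-(category, replicate) substreams of the master
#' seed, so results are reproducible and stable when `m` changes.
#'
#' @param m Number of categories (ignored when `phi` is supplied).
#' @param pi0 Proportion of non-enriched categories.
#' @param scheme Configuration scheme passed to [odds_ratio_config()].
#' @param n Total selected genes (default 200).
#' @param N Total reference genes (default 10000).
#' @param rep Replicate index (>= 1).
#' @param seed Master seed.
#' @param phi Optional explicit vector of log2 odds ratios.
#' @return An `enrich_df` with extra columns `phi`, `pi1`, `pi2`.
#' @export
simulate_enrichment <- function(m = 100, pi0 = 0.5, scheme = "asymmetric",
                                n = 200, N = 10000, rep = 1, seed = 0,
                                phi = NULL) {
  if (is.null(phi)) phi <- odds_ratio_config(m, pi0, scheme)
  m <- length(phi)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  t <- integer(m); s <- integer(m)
  pi1 <- numeric(m); pi2 <- numeric(m)
  for (i in seq_len(m)) {
    set.seed(substream_seed(seed, rep, i))
    pi1[i] <- stats::runif(1)
    pi2[i] <- pi2_from_pi1(pi1[i], phi[i])
    x1 <- stats::rbinom(1, n, pi1[i])
    x2 <- stats::rbinom(1, N - n, pi2[i])
    t[i] <- x1
    s[i] <- x1 + x2
  }
  out <- enrichment_data(t, s, n, N)
  out$phi <- phi
  out$pi1 <- pi1
  out$pi2 <- pi2
  out
}

#' Exact true LFDR under a known generating mixture
#'
#' Posterior null probability of each table when the generating model is
#' known: the null density is the central hypergeometric pmf, the
#' alternative density is the equal-weight average of the conditional pmfs
#' at the signed non-null log odds ratios, and
#' `LFDR = [1 + (f1/f0) (1 - pi0)/pi0]^-1`.
#'
#' @param t,s Observed counts and category sizes (vectorized).
#' @param n,N Study totals.
#' @param theta Vector of the non-zero natural-log odds ratios of the
#'   enriched categories (signed, as generated).
#' @param pi0 Prior null proportion in \[0, 1\].
#' @return Vector of true LFDR values in \[0, 1\].
#' @examples
#' true_lfdr(2, s = 2, n = 3, N = 6, theta = log(2), pi0 = 0.5) # about 0.3548
#' @export
true_lfdr <- function(t, s, n, N, theta, pi0) {
  if (pi0 < 0 || pi0 > 1) stop("`pi0` must lie in [0, 1]", call. = FALSE)
  len <- max(length(t), length(s))
  if (pi0 == 1) return(rep(1, len))
  if (pi0 == 0) return(rep(0, len))
  if (length(theta) == 0) {
    stop("`theta` must be non-empty when pi0 < 1", call. = FALSE)
  }
  f0 <- cond_pmf(t, s, n, N, 0)
  fmat <- matrix(vapply(theta, function(th) cond_pmf(t, s, n, N, th),
                        numeric(len)), nrow = len)
  f1 <- rowMeans(fmat)
  bf <- f1 / f0
  1 / (1 + bf * (1 - pi0) / pi0)
}

#' Append the true LFDR to a simulated dataset
#'
#' @param data An `enrich_df` carrying a `phi` column (from
#'   [simulate_enrichment()]).
#' @param pi0 Prior null proportion of the generating configuration.
#' @return The input with a `true_lfdr` column added.
#' @export
add_true_lfdr <- function(data, pi0) {
  if (!"phi" %in% names(data)) {
    stop("`data` must carry a `phi` column", call. = FALSE)
  }
  tot <- dataset_totals(data)
  theta <- data$phi[data$phi != 0] * log(2)
  data$true_lfdr <- true_lfdr(data$t, data$s, tot$n, tot$N, theta, pi0)
  data
}

# run one estimator on one replicate; NULL on failure
run_estimator <- function(est, data, p, restarts, seed) {
  switch(
    est,
    bbe = lfdr_bbe(p),
    mle2 = lfdr_mle(fit_pmm(data, k = 2, restarts = restarts, seed = seed)),
    mle3 = lfdr_mle(fit_pmm(data, k = 3, restarts = restarts, seed = seed)),
    hbe = lfdr_hbe(p, null = "theoretical"),
    hbe_en = lfdr_hbe(p, null = "empirical"),
    stop("unknown estimator: ", est, call. = FALSE)
  )
}

#' Benchmark estimator bias against the true LFDR
#'
#' Simulates `reps` datasets from one configuration, runs each estimator,
#' and aggregates the error against the exact true LFDR. The default
#' aggregation averages the signed errors over categories and replicates
#' first and takes the absolute value last (bias in the term-of-art sense);
#' `aggregate = "mae"` instead averages absolute per-category errors.
#' Estimator failures on a replicate are recorded and excluded from the
#' averages.
#'
#' @param m,pi0,scheme,n,N Configuration passed to [simulate_enrichment()].
#' @param estimators Subset of `"bbe"`, `"mle2"`, `"mle3"`, `"hbe"`,
#'   `"hbe_en"`.
#' @param reps Number of replicate datasets.
#' @param seed Master seed.
#' @param restarts Optimizer restarts for the mixture fits.
#' @param aggregate `"bias"` (signed mean, absolute value last) or `"mae"`.
#' @return A tibble with one row per estimator: `estimator`, `m`, `pi0`,
#'   `scheme`, `reps`, `bias` (signed), `abs_bias`, `n_failed`.
#' @export
bias_experiment <- function(m, pi0, scheme = "asymmetric",
                            estimators = c("bbe", "mle2", "mle3", "hbe", "hbe_en"),
                            reps = 20, seed = 0, n = 200, N = 10000,
                            restarts = 10, aggregate = c("bias", "mae")) {
  aggregate <- match.arg(aggregate)
  if (length(estimators) == 0) stop("no estimators requested", call. = FALSE)
  errs <- stats::setNames(vector("list", length(estimators)), estimators)
  failed <- stats::setNames(integer(length(estimators)), estimators)
  for (r in seq_len(reps)) {
    data <- simulate_enrichment(m = m, pi0 = pi0, scheme = scheme, n = n,
                                N = N, rep = r, seed = seed)
    data <- add_true_lfdr(data, pi0)
    tot <- dataset_totals(data)
    p <- fisher_pvalue(data$t, data$s, tot$n, tot$N)
    for (est in estimators) {
      hat <- tryCatch(
        run_estimator(est, data, p, restarts, seed = seed + r),
        error = function(e) NULL
      )
      if (is.null(hat)) {
        failed[est] <- failed[est] + 1L
        next
      }
      e <- hat - data$true_lfdr
      errs[[est]] <- c(errs[[est]], if (aggregate == "bias") e else abs(e))
    }
  }
  if (any(failed > 0)) {
    warning("estimator failures excluded from averages: ",
            paste(sprintf("%s (%d)", names(failed)[failed > 0],
                          failed[failed > 0]), collapse = ", "))
  }
  agg <- vapply(estimators, function(est) {
    if (is.null(errs[[est]])) NA_real_ else mean(errs[[est]])
  }, numeric(1))
  tibble::tibble(
    estimator = estimators,
    m = m, pi0 = pi0, scheme = scheme, reps = reps,
    bias = if (aggregate == "bias") agg else NA_real_,
    abs_bias = abs(agg),
    n_failed = as.integer(failed)
  )
}

#' Plot absolute bias across configurations
#'
#' @param bias_table Row-bound output of [bias_experiment()] runs.
#' @return A ggplot object: absolute bias against `pi0`, one line per
#'   estimator, faceted by `m` and scheme.
#' @export
plot_bias <- function(bias_table) {
  ggplot2::ggplot(bias_table,
                  ggplot2::aes(x = .data$pi0, y = .data$abs_bias,
                               colour = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(m ~ scheme, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "proportion of non-enriched categories (pi0)",
                  y = "absolute estimated LFDR bias")
}
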