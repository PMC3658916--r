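test_that("odds-ratio ladders follow the configuration formulas", {
  phi <- odds_ratio_config(100, 0.5, "asymmetric")
  expect_equal(phi[1], 0.1)
  expect_equal(phi[50], 5)
  expect_true(all(phi[51:100] == 0))
  sym <- odds_ratio_config(100, 0.5, "symmetric")
  expect_equal(sym[1], 0.2)
  expect_equal(sym[25], 5)
  expect_equal(sym[26], 5 - 10 * 26 / 50)
  expect_equal(sym[50], -5)
  expect_true(all(sym[51:100] == 0))
  # half positive, half negative among the enriched terms
  expect_equal(sum(sym > 0), 25)
  expect_equal(sum(sym < 0), 25)
})

test_that("fixed small-study configurations return the tabulated vectors", {
  expect_equal(odds_ratio_config(8, 0.75, "fixed"), c(2, -2, rep(0, 6)))
  expect_equal(odds_ratio_config(2, 1, "fixed"), c(0, 0))
  expect_equal(odds_ratio_config(4, 0.5, "fixed"), c(3, -3, 0, 0))
  expect_equal(odds_ratio_config(8, 0.625, "fixed"), c(0.5, 2, -2, rep(0, 5)))
  expect_equal(odds_ratio_config(32, 0.875, "fixed"), c(1.8, -1.8, rep(0, 30)))
  expect_error(odds_ratio_config(8, 0.33, "fixed"), "no fixed configuration")
  expect_error(odds_ratio_config(3, 1.2), "pi0")
})

test_that("the generator is deterministic and stable under m changes", {
  d1 <- simulate_enrichment(m = 10, pi0 = 0.5, rep = 3, seed = 42)
  d2 <- simulate_enrichment(m = 10, pi0 = 0.5, rep = 3, seed = 42)
  expect_identical(d1, d2)
  d3 <- simulate_enrichment(m = 10, pi0 = 0.5, rep = 4, seed = 42)
  expect_false(identical(d1$t, d3$t))
  # category substreams do not shift when later categories are added
  big <- simulate_enrichment(phi = rep(0, 20), rep = 3, seed = 42,
                             n = 200, N = 10000)
  small <- simulate_enrichment(phi = rep(0, 10), rep = 3, seed = 42,
                               n = 200, N = 10000)
  expect_identical(big$t[1:10], small$t)
})

test_that("generator marginals match the sampling model", {
  d <- simulate_enrichment(phi = rep(0, 2000), n = 200, N = 10000, seed = 8)
  expect_equal(mean(d$t) / 200, 0.5, tolerance = 0.05)     # E[pi1] = 1/2
  expect_equal(mean(d$pi2), mean(d$pi1), tolerance = 0.05) # phi = 0 ties them
})

test_that("null draws of t given s are hypergeometric", {
  # randomized PIT: u = F(t-1|s) + V f(t|s) is uniform iff t|s follows f
  set.seed(9)
  d <- do.call(rbind, lapply(1:10, function(r) {
    simulate_enrichment(phi = rep(0, 100), n = 50, N = 1000, rep = r, seed = 9)
  }))
  u <- vapply(seq_len(nrow(d)), function(i) {
    phyper(d$t[i] - 1, 50, 950, d$s[i]) +
      runif(1) * dhyper(d$t[i], 50, 950, d$s[i])
  }, numeric(1))
  expect_gt(ks.test(u, "punif")$p.value, 0.01)
})

test_that("true LFDR matches the closed-form posterior", {
  expect_equal(true_lfdr(2, 2, 3, 6, theta = log(2), pi0 = 0.5), 0.354839,
               tolerance = 1e-6)
  expect_equal(true_lfdr(0:2, 2, 3, 6, theta = 1, pi0 = 1), rep(1, 3))
  expect_equal(true_lfdr(1, 2, 3, 6, theta = 1, pi0 = 0), 0)
  # vanishing odds ratios drive the posterior to the prior
  expect_equal(true_lfdr(1, 2, 3, 6, theta = 1e-10, pi0 = 0.3), 0.3,
               tolerance = 1e-6)
  expect_error(true_lfdr(1, 2, 3, 6, theta = numeric(0), pi0 = 0.5),
               "non-empty")
})

test_that("true LFDR lies in [0,1] and increases with pi0", {
  set.seed(58)
  for (rep in 1:20) {
    mg <- random_margins(40)
    t <- random_support_point(mg$s, mg$n, mg$N)
    th <- runif(2, 0.2, 3)
    vals <- vapply(seq(0.05, 0.95, by = 0.1), function(p0) {
      true_lfdr(t, mg$s, mg$n, mg$N, th, p0)
    }, numeric(1))
    expect_true(all(vals >= 0 & vals <= 1))
    expect_true(all(diff(vals) > -1e-12))
  }
})

test_that("add_true_lfdr uses the signed generating log odds ratios", {
  d <- simulate_enrichment(m = 8, pi0 = 0.75, scheme = "fixed", n = 20,
                           N = 200, seed = 3)
  d <- add_true_lfdr(d, 0.75)
  tot <- dataset_totals(d)
  manual <- true_lfdr(d$t, d$s, tot$n, tot$N,
                      theta = c(2, -2) * log(2), pi0 = 0.75)
  expect_equal(d$true_lfdr, manual)
  expect_error(add_true_lfdr(enrichment_data(1, 2, 3, 6), 0.5), "phi")
})

test_that("bias_experiment aggregates signed error then takes |.|", {
  res <- bias_experiment(m = 4, pi0 = 1, scheme = "fixed",
                         estimators = c("bbe", "mle2"), reps = 3, seed = 1,
                         n = 50, N = 1000, restarts = 3)
  expect_s3_class(res, "tbl_df")
  expect_equal(res$estimator, c("bbe", "mle2"))
  expect_equal(res$abs_bias, abs(res$bias))
  # truth is identically 1 at pi0 = 1 and BBE is conservative: tiny bias
  expect_lt(res$abs_bias[res$estimator == "bbe"], 0.2)
  res2 <- bias_experiment(m = 4, pi0 = 1, scheme = "fixed",
                          estimators = c("bbe", "mle2"), reps = 3, seed = 1,
                          n = 50, N = 1000, restarts = 3)
  expect_identical(res, res2)
  mae <- bias_experiment(m = 4, pi0 = 1, scheme = "fixed",
                         estimators = "bbe", reps = 3, seed = 1,
                         n = 50, N = 1000, aggregate = "mae")
  expect_true(is.na(mae$bias))
  expect_gte(mae$abs_bias, res$abs_bias[1] - 1e-12)
  expect_s3_class(plot_bias(res), "ggplot")
})
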