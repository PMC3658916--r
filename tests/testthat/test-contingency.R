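test_that("conditional pmf reduces to the hypergeometric at theta = 0", {
  expect_equal(cond_pmf(1, 2, 3, 6, 0), 0.6)
  expect_equal(cond_pmf(0:2, 2, 3, 6, 0), dhyper(0:2, 3, 3, 2))
  set.seed(11)
  for (rep in 1:200) {
    mg <- random_margins(40)
    t <- random_support_point(mg$s, mg$n, mg$N)
    expect_equal(cond_pmf(t, mg$s, mg$n, mg$N, 0),
                 dhyper(t, mg$n, mg$N - mg$n, mg$s),
                 tolerance = 1e-12)
  }
})

test_that("conditional pmf matches brute-force arithmetic at non-zero theta", {
  expect_equal(cond_pmf(2, 2, 3, 6, 2), exp(4) / (1 + 3 * exp(2) + exp(4)),
               tolerance = 1e-12)
  set.seed(12)
  for (rep in 1:100) {
    mg <- random_margins(40)
    t <- random_support_point(mg$s, mg$n, mg$N)
    th <- runif(1, -3, 3)
    expect_equal(cond_pmf(t, mg$s, mg$n, mg$N, th),
                 oracle_cond_pmf(t, mg$s, mg$n, mg$N, th),
                 tolerance = 1e-10)
  }
})

test_that("conditional pmf normalizes and vanishes off support", {
  expect_equal(sum(cond_pmf(0:2, 2, 3, 6, 1.7)), 1, tolerance = 1e-12)
  set.seed(13)
  for (rep in 1:50) {
    mg <- random_margins(40)
    y <- max(0, mg$s + mg$n - mg$N):min(mg$s, mg$n)
    th <- runif(1, -4, 4)
    expect_equal(sum(cond_pmf(y, mg$s, mg$n, mg$N, th)), 1, tolerance = 1e-12)
  }
  expect_equal(cond_pmf(3, 2, 3, 6, 0), 0)   # t > s
  expect_equal(cond_pmf(0, 5, 3, 6, 0), 0)   # below support floor
})

test_that("invalid margins error, off-support counts do not", {
  expect_error(cond_pmf(1, 2, 7, 6, 0), "n <= N")
  expect_error(cond_pmf(1, 8, 3, 6, 0), "category sizes")
  expect_error(cond_pmf(1, 2, 3, 6, Inf), "finite")
  expect_silent(cond_pmf(-1, 2, 3, 6, 0))
})

test_that("pmf at the upper support endpoint increases with theta", {
  ths <- seq(-2, 3, by = 0.5)
  vals <- cond_pmf(rep(2, length(ths)), 2, 3, 6, ths)
  expect_true(all(diff(vals) > 0))
  vals2 <- vapply(ths, function(th) cond_pmf(5, 9, 5, 30, th), numeric(1))
  expect_true(all(diff(vals2) > 0))
})

test_that("symmetrized pmf averages the two signed families", {
  expect_equal(sym_pmf(1, 2, 3, 6, 0), 0.6)
  expect_equal(sym_pmf(2, 2, 3, 6, 2),
               (exp(4) / (1 + 3 * exp(2) + exp(4)) +
                exp(-4) / (1 + 3 * exp(-2) + exp(-4))) / 2,
               tolerance = 1e-12)
  set.seed(14)
  for (rep in 1:30) {
    mg <- random_margins(40)
    t <- random_support_point(mg$s, mg$n, mg$N)
    th <- runif(1, 0, 3)
    expect_equal(sym_pmf(t, mg$s, mg$n, mg$N, th),
                 sym_pmf(t, mg$s, mg$n, mg$N, -th))
    expect_equal(sym_pmf(t, mg$s, mg$n, mg$N, th),
                 oracle_sym_pmf(t, mg$s, mg$n, mg$N, th), tolerance = 1e-10)
  }
})

test_that("two-sided Fisher p-values follow the minimum-likelihood rule", {
  expect_equal(fisher_pvalue(2, 2, 3, 6), 0.4)
  expect_equal(fisher_pvalue(1, 2, 3, 6), 1)
  expect_equal(fisher_pvalue(0, 0, 3, 6), 1)  # singleton support
})

test_that("Fisher p-values agree with stats::fisher.test", {
  set.seed(15)
  for (rep in 1:100) {
    mg <- random_margins(40)
    t <- random_support_point(mg$s, mg$n, mg$N)
    tab <- matrix(c(t, mg$s - t, mg$n - t, mg$N - mg$n - (mg$s - t)), 2)
    expect_equal(fisher_pvalue(t, mg$s, mg$n, mg$N),
                 fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("endpoint outcomes are never less significant than the mode", {
  set.seed(16)
  for (rep in 1:50) {
    mg <- random_margins(40)
    lo <- max(0, mg$s + mg$n - mg$N); hi <- min(mg$s, mg$n)
    y <- lo:hi
    p0 <- cond_pmf(y, mg$s, mg$n, mg$N, 0)
    tmode <- y[which.max(p0)]
    expect_lte(fisher_pvalue(lo, mg$s, mg$n, mg$N),
               fisher_pvalue(tmode, mg$s, mg$n, mg$N) + 1e-12)
    expect_lte(fisher_pvalue(hi, mg$s, mg$n, mg$N),
               fisher_pvalue(tmode, mg$s, mg$n, mg$N) + 1e-12)
  }
})

test_that("pi2 solves the log2 odds-ratio equation", {
  expect_equal(pi2_from_pi1(0.3, 0), 0.3)
  expect_equal(pi2_from_pi1(0.5, 1), 1 / 3)
  set.seed(17)
  p1 <- runif(50, 0.01, 0.99)
  phi <- runif(50, -6, 6)
  p2 <- pi2_from_pi1(p1, phi)
  expect_equal(log2(p1 / (1 - p1)) - log2(p2 / (1 - p2)), phi,
               tolerance = 1e-12)
  expect_error(pi2_from_pi1(0, 1), "strictly")
  expect_error(pi2_from_pi1(1, 1), "strictly")
})

test_that("enrichment_data validates counts against the support", {
  d <- enrichment_data(t = c(1, 2), s = c(2, 2), n = 3, N = 6)
  expect_s3_class(d, "enrich_df")
  expect_equal(dataset_totals(d), list(n = 3L, N = 6L))
  expect_error(enrichment_data(t = 4, s = 4, n = 3, N = 6), "support")
  expect_error(enrichment_data(t = 0, s = 5, n = 3, N = 6), "support")
  expect_error(enrichment_data(t = 1, s = 2, n = 7, N = 6), "n <= N")
  expect_error(enrichment_data(t = integer(0), s = integer(0), n = 3, N = 6),
               "at least one")
})

test_that("TSV reader round-trips datasets with header totals", {
  d <- enrichment_data(t = c(1, 2, 0), s = c(2, 2, 3), n = 3, N = 6,
                       category_id = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# n = 3", "# N = 6",
               "category_id\tt\ts",
               "a\t1\t2", "b\t2\t2", "c\t0\t3"), path)
  d2 <- read_enrichment_tsv(path)
  expect_equal(d2$t, d$t)
  expect_equal(d2$s, d$s)
  expect_equal(d2$category_id, d$category_id)
  expect_equal(dataset_totals(d2), dataset_totals(d))
  d3 <- read_enrichment_tsv(path, n = 3, N = 6)
  expect_identical(d2, d3)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("category_id\tt\ts", "a\t1\t2"), path2)
  expect_error(read_enrichment_tsv(path2), "totals")
})

test_that("report TSV writes metadata and re-parses losslessly", {
  rep1 <- tibble::tibble(category_id = c("a", "b"), t = 1:2,
                         p_value = c(0.4, 1), bbe = c(1, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(rep1, path, metadata = list(n = 3, N = 6), digits = NULL)
  lines <- readLines(path)
  expect_true(any(grepl("^# n = 3", lines)))
  back <- utils::read.delim(path, comment.char = "#")
  expect_equal(back$p_value, rep1$p_value)
  expect_equal(back$category_id, rep1$category_id)
})
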