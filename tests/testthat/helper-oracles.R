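# Independent brute-force oracles, kept free of the package's log-space path.

# conditional pmf by direct binomial-coefficient arithmetic (small N only)
oracle_cond_pmf <- function(t, s, n, N, theta = 0) {
  y <- seq.int(max(0, s + n - N), min(s, n))
  w <- choose(n, y) * choose(N - n, s - y) * exp(y * theta)
  if (!(t %in% y)) return(0)
  (choose(n, t) * choose(N - n, s - t) * exp(t * theta)) / sum(w)
}

# symmetrized family, brute force
oracle_sym_pmf <- function(t, s, n, N, theta) {
  (oracle_cond_pmf(t, s, n, N, theta) + oracle_cond_pmf(t, s, n, N, -theta)) / 2
}

# mixture log-likelihood by direct summation
oracle_pmm_loglik <- function(t, s, n, N, theta, pi) {
  sum(vapply(seq_along(t), function(i) {
    comps <- c(oracle_cond_pmf(t[i], s[i], n, N, 0),
               vapply(theta, function(th) oracle_sym_pmf(t[i], s[i], n, N, th),
                      numeric(1)))
    log(sum(pi * comps))
  }, numeric(1)))
}

# max of the conditional pmf over theta by dense grid search
oracle_max_pmf <- function(y, s, n, N, grid = seq(-30, 30, by = 0.01)) {
  max(vapply(grid, function(th) oracle_cond_pmf(y, s, n, N, th), numeric(1)))
}

# random valid table margins with N <= Nmax
random_margins <- function(Nmax) {
  N <- sample(4:Nmax, 1)
  n <- sample(1:(N - 1), 1)
  s <- sample(0:N, 1)
  list(N = N, n = n, s = s)
}

safe_sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1)

random_support_point <- function(s, n, N) {
  lo <- max(0, s + n - N)
  hi <- min(s, n)
  safe_sample1(lo:hi)
}
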