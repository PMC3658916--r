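#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @import ggplot2
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# ---- validation helpers -----------------------------------------------------

check_totals <- function(n, N) {
  if (length(n) != 1L || length(N) != 1L || !is.finite(n) || !is.finite(N)) {
    stop("`n` and `N` must be single finite numbers", call. = FALSE)
  }
  if (n < 0 || N < 0 || n > N || n != round(n) || N != round(N)) {
    stop("need integer totals with 0 <= n <= N", call. = FALSE)
  }
  invisible(TRUE)
}

check_category_size <- function(s, n, N) {
  bad <- s < 0 | s > N | s != round(s)
  if (any(bad)) {
    stop("category sizes `s` must be integers in [0, N]", call. = FALSE)
  }
  invisible(TRUE)
}

# Support of T | S = s: the integer interval [max(0, s + n - N), min(s, n)].
support_range <- function(s, n, N) {
  c(max(0, s + n - N), min(s, n))
}

# log binomial-coefficient weights lchoose(n, y) + lchoose(N - n, s - y)
# over the full support of T given S = s.
support_log_weights <- function(s, n, N) {
  r <- support_range(s, n, N)
  y <- seq.int(r[1], r[2])
  list(y = y, lw = lchoose(n, y) + lchoose(N - n, s - y))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# ---- conditional pmf --------------------------------------------------------

#' Conditional probability mass function of the enrichment count
#'
#' Probability of observing `t` selected (DE) genes in a category of size `s`,
#' conditional on `s`, when the log odds ratio of category membership between
#' selected and unselected genes is `theta`. Conditioning on the category size
#' eliminates the nuisance parameter of the two-binomial sampling model and
#' leaves Fisher's noncentral hypergeometric family: at `theta = 0` this is the
#' central hypergeometric pmf underlying Fisher's exact test.
#'
#' All evaluation is in log space (log-gamma binomial coefficients, log-sum-exp
#' normalizer) so that genome-scale tables (`N` in the tens of thousands) do
#' not overflow.
#'
#' @param t Number of selected genes in the category. Vectorized; values
#'   outside the support return probability 0.
#' @param s Category size (selected + unselected genes in the category).
#'   Vectorized, recycled against `t`.
#' @param n Total number of selected genes (scalar).
#' @param N Total number of reference genes (scalar).
#' @param theta Natural-log odds ratio (scalar or recycled vector).
#' @param log If `TRUE`, return log probabilities.
#' @return Numeric vector of probabilities (or log probabilities).
#' @examples
#' cond_pmf(1, s = 2, n = 3, N = 6, theta = 0) # hypergeometric: 9/15
#' sum(cond_pmf(0:2, s = 2, n = 3, N = 6, theta = 1.7)) # normalized
#' @export
cond_pmf <- function(t, s, n, N, theta = 0, log = FALSE) {
  check_totals(n, N)
  len <- max(length(t), length(s), length(theta))
  t <- rep_len(t, len); s <- rep_len(s, len); theta <- rep_len(theta, len)
  check_category_size(s, n, N)
  if (any(!is.finite(theta))) stop("`theta` must be finite", call. = FALSE)
  out <- numeric(len)
  key <- paste(s, theta)
  for (k in unique(key)) {
    idx <- which(key == k)
    si <- s[idx[1]]; th <- theta[idx[1]]
    sw <- support_log_weights(si, n, N)
    lognum <- sw$lw + sw$y * th
    logZ <- log_sum_exp(lognum)
    ti <- t[idx]
    pos <- match(ti, sw$y)
    lp <- rep(-Inf, length(idx))
    ok <- !is.na(pos) & ti == round(ti)
    lp[ok] <- lognum[pos[ok]] - logZ
    out[idx] <- lp
  }
  if (log) out else exp(out)
}

#' Symmetrized conditional pmf
#'
#' Two-sided mixture `g_theta(t|s) = (f_theta(t|s) + f_(-theta)(t|s)) / 2`,
#' the parametric family used by the mixture-model LFDR estimators: a non-null
#' component with log odds magnitude `theta` places equal weight on enrichment
#' and depletion. At `theta = 0` it reduces to the central hypergeometric pmf.
#'
#' @inheritParams cond_pmf
#' @param theta Non-negative log odds magnitude.
#' @return Numeric vector of probabilities (or log probabilities).
#' @export
sym_pmf <- function(t, s, n, N, theta, log = FALSE) {
  lp1 <- cond_pmf(t, s, n, N, theta, log = TRUE)
  lp2 <- cond_pmf(t, s, n, N, -theta, log = TRUE)
  m <- pmax(lp1, lp2)
  lg <- ifelse(is.finite(m),
               m + log((exp(lp1 - m) + exp(lp2 - m)) / 2),
               -Inf)
  if (log) lg else exp(lg)
}

#' Two-sided Fisher exact p-value for enrichment tables
#'
#' For each category the p-value is the total null (hypergeometric)
#' probability of all outcomes at most as probable as the observed count —
#' the usual two-sided convention for Fisher's exact test. Ties in the null
#' pmf are admitted with a fixed relative tolerance of 1e-7 so results are
#' reproducible across platforms.
#'
#' @inheritParams cond_pmf
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_pvalue(2, s = 2, n = 3, N = 6) # 0.4
#' @export
fisher_pvalue <- function(t, s, n, N) {
  check_totals(n, N)
  len <- max(length(t), length(s))
  t <- rep_len(t, len); s <- rep_len(s, len)
  check_category_size(s, n, N)
  out <- numeric(len)
  for (si in unique(s)) {
    idx <- which(s == si)
    sw <- support_log_weights(si, n, N)
    logp <- sw$lw - log_sum_exp(sw$lw)
    p <- exp(logp)
    ti <- t[idx]
    pos <- match(ti, sw$y)
    if (anyNA(pos)) stop("observed count outside the support of its table", call. = FALSE)
    out[idx] <- vapply(pos, function(j) sum(p[p <= p[j] * (1 + 1e-7)]), numeric(1))
  }
  pmin(out, 1)
}

#' Solve for the unselected-pool probability given an odds ratio
#'
#' Given the probability `pi1` governing counts in the selected pool and a
#' log2 odds ratio `phi`, returns the probability `pi2` for the unselected
#' pool such that `log2 odds(pi1) - log2 odds(pi2) = phi`:
#' `pi2 = pi1 / (pi1 + (1 - pi1) * 2^phi)`.
#'
#' @param pi1 Probability in (0, 1). Vectorized.
#' @param phi Log2 odds ratio (finite). Vectorized, recycled.
#' @return Probability vector `pi2`.
#' @export
pi2_from_pi1 <- function(pi1, phi) {
  if (any(pi1 <= 0 | pi1 >= 1)) stop("`pi1` must lie strictly in (0, 1)", call. = FALSE)
  if (any(!is.finite(phi))) stop("`phi` must be finite", call. = FALSE)
  pi1 / (pi1 + (1 - pi1) * 2^phi)
}

# ---- dataset container ------------------------------------------------------

#' Assemble an enrichment dataset
#'
#' Bundles per-category counts with the study-wide totals into a tibble with
#' one row per category: `category_id`, `t` (selected genes in the category)
#' and `s` (category size). The totals `n` (selected genes) and `N` (reference
#' genes) are carried as attributes and recovered with [dataset_totals()].
#'
#' @param t Integer vector of selected-gene counts per category.
#' @param s Integer vector of category sizes.
#' @param n Total selected genes.
#' @param N Total reference genes.
#' @param category_id Optional identifiers; defaults to `cat_1 ... cat_m`.
#' @return A tibble of class `enrich_df`.
#' @examples
#' enrichment_data(t = c(1, 2), s = c(2, 2), n = 3, N = 6)
#' @export
enrichment_data <- function(t, s, n, N, category_id = NULL) {
  check_totals(n, N)
  if (length(t) != length(s)) stop("`t` and `s` must have equal length", call. = FALSE)
  if (length(t) < 1L) stop("need at least one category", call. = FALSE)
  check_category_size(s, n, N)
  lo <- pmax(0, s + n - N)
  hi <- pmin(s, n)
  if (any(t != round(t) | t < lo | t > hi)) {
    stop("each `t` must lie in the support [max(0, s + n - N), min(s, n)]",
         call. = FALSE)
  }
  if (is.null(category_id)) category_id <- paste0("cat_", seq_along(t))
  out <- tibble::tibble(category_id = as.character(category_id),
                        t = as.integer(t), s = as.integer(s))
  attr(out, "n") <- as.integer(n)
  attr(out, "N") <- as.integer(N)
  class(out) <- c("enrich_df", class(out))
  out
}

#' Totals attached to an enrichment dataset
#'
#' @param data An `enrich_df` created by [enrichment_data()].
#' @return Named list with elements `n` and `N`.
#' @export
dataset_totals <- function(data) {
  n <- attr(data, "n"); N <- attr(data, "N")
  if (is.null(n) || is.null(N)) {
    stop("`data` lacks n/N totals; build it with enrichment_data()", call. = FALSE)
  }
  list(n = n, N = N)
}

#' Append two-sided Fisher exact p-values to an enrichment dataset
#'
#' @param data An `enrich_df`.
#' @return The input with a `p_value` column added.
#' @export
add_fisher_pvalues <- function(data) {
  tot <- dataset_totals(data)
  data$p_value <- fisher_pvalue(data$t, data$s, tot$n, tot$N)
  data
}

# ---- TSV input / output -----------------------------------------------------

#' Read an enrichment dataset from TSV
#'
#' Expects columns `category_id`, `t`, `s` (tab-separated, header row). The
#' totals may be given either as arguments or as comment lines of the form
#' `# n = 200` and `# N = 10000` preceding the header.
#'
#' @param path Path to the TSV file.
#' @param n,N Study-wide totals; if `NULL`, read from `#` header lines.
#' @return An `enrich_df` tibble.
#' @export
read_enrichment_tsv <- function(path, n = NULL, N = NULL) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), meta, value = TRUE)
    if (length(hit) == 0) return(NULL)
    as.numeric(sub(".*=\\s*", "", hit[1]))
  }
  if (is.null(n)) n <- get_meta("n")
  if (is.null(N)) N <- get_meta("N")
  if (is.null(n) || is.null(N)) {
    stop("totals n and N must be supplied as arguments or '# n = ...' header lines",
         call. = FALSE)
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  need <- c("category_id", "t", "s")
  if (!all(need %in% names(df))) {
    stop("TSV must have columns category_id, t, s", call. = FALSE)
  }
  enrichment_data(df$t, df$s, n, N, category_id = df$category_id)
}

#' Write an estimation report as TSV
#'
#' Writes a tab-separated table preceded by `#`-prefixed metadata lines
#' (totals, options, seed), with missing values as `NA`. The body re-parses
#' losslessly with [utils::read.delim()].
#'
#' @param report A data frame (typically from [estimate_lfdr()]).
#' @param path Output path or an open connection (e.g. `stdout()`).
#' @param metadata Named list written as `# key = value` lines.
#' @param digits Significant digits for numeric columns; `NULL` keeps full
#'   precision.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path, metadata = list(), digits = 6) {
  if (inherits(path, "connection")) {
    con <- path
  } else {
    con <- file(path, "w")
    on.exit(close(con))
  }
  for (key in names(metadata)) {
    writeLines(sprintf("# %s = %s", key, format(metadata[[key]])), con)
  }
  out <- as.data.frame(report)
  if (!is.null(digits)) {
    num <- vapply(out, is.double, logical(1))
    out[num] <- lapply(out[num], signif, digits = digits)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
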