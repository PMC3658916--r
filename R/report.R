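# Unified per-category estimation report tying all estimators to one dataset.

#' Run LFDR estimators on an enrichment dataset
#'
#' Computes two-sided Fisher exact p-values and the requested per-category
#' LFDR columns, returning one tidy row per category. Bayes-factor columns
#' accompany the NML and mixture estimators (`bf_nml`, `bf_eb`), with
#' evidence flags at the conventional Bayes-factor thresholds of 10 (strong)
#' and 100 (overwhelming).
#'
#' The mixture and histogram estimators pool information across categories
#' and therefore need at least 2 of them; with a single category only the
#' NML estimator (with a supplied `pi0`) is available.
#'
#' @param data An `enrich_df` from [enrichment_data()] or
#'   [read_enrichment_tsv()].
#' @param methods Any of `"bbe"`, `"mle2"`, `"mle3"`, `"hbe"`, `"hbe_en"`,
#'   `"nmle"`.
#' @param pi0 Prior null proportion, required by `"nmle"`.
#' @param restarts,seed Optimizer settings for the mixture fits.
#' @param theta_max Upper bound of the mixture log odds magnitude box.
#' @param bins,df,central_fraction Histogram-estimator settings.
#' @return A tibble with columns `category_id`, `t`, `s`, `p_value`, one
#'   LFDR column per requested method, Bayes-factor and flag columns where
#'   applicable. Mixture fits are attached as attribute `"fits"`.
#' @examples
#' d <- enrichment_data(t = c(1, 2), s = c(2, 2), n = 3, N = 6)
#' estimate_lfdr(d, methods = c("bbe", "nmle"), pi0 = 0.5)
#' @export
estimate_lfdr <- function(data,
                          methods = c("bbe", "mle2", "mle3", "hbe", "hbe_en"),
                          pi0 = NULL, restarts = 10, seed = 0, theta_max = 10,
                          bins = 120, df = 7, central_fraction = 0.5) {
  known <- c("bbe", "mle2", "mle3", "hbe", "hbe_en", "nmle")
  if (length(methods) == 0) stop("no methods requested", call. = FALSE)
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown methods: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  tot <- dataset_totals(data)
  m <- nrow(data)
  pooled <- setdiff(methods, "nmle")
  if (m == 1L && length(pooled)) {
    stop("with a single category only the NML estimator can do better than ",
         "the trivial estimate of 1; request method \"nmle\" with a pi0",
         call. = FALSE)
  }
  if ("nmle" %in% methods && is.null(pi0)) {
    stop("method \"nmle\" needs a `pi0` value", call. = FALSE)
  }

  out <- tibble::tibble(category_id = data$category_id, t = data$t, s = data$s)
  out$p_value <- fisher_pvalue(data$t, data$s, tot$n, tot$N)
  fits <- list()

  if ("bbe" %in% methods) out$bbe <- lfdr_bbe(out$p_value)
  for (mk in intersect(methods, c("mle2", "mle3"))) {
    k <- if (mk == "mle2") 2L else 3L
    fit <- fit_pmm(data, k = k, restarts = restarts, seed = seed,
                   theta_max = theta_max)
    fits[[mk]] <- fit
    out[[mk]] <- lfdr_mle(fit)
    out[[paste0("boundary_", mk)]] <- fit$boundary
  }
  if ("hbe" %in% methods) {
    out$hbe <- lfdr_hbe(out$p_value, null = "theoretical", bins = bins, df = df)
  }
  if ("hbe_en" %in% methods) {
    out$hbe_en <- lfdr_hbe(out$p_value, null = "empirical", bins = bins,
                           df = df, central_fraction = central_fraction)
  }
  if ("nmle" %in% methods) {
    out$bf_nml <- nml_ratio(data$t, data$s, tot$n, tot$N)
    out$log_bf_nml <- log(out$bf_nml)
    out$nmle <- lfdr_nmle(out$bf_nml, pi0)
    out$evidence_nml <- evidence_flag(out$bf_nml)
  }
  ebk <- intersect(c("mle2", "mle3"), names(fits))
  if (length(ebk)) {
    fit <- fits[[ebk[1]]]
    p0 <- min(max(fit$pi[1], 1e-12), 1 - 1e-12)
    out$bf_eb <- suppressWarnings(eb_bayes_factor(out[[ebk[1]]], p0))
    out$evidence_eb <- evidence_flag(out$bf_eb)
  }
  attr(out, "fits") <- fits
  attr(out, "n") <- tot$n
  attr(out, "N") <- tot$N
  attr(out, "pi0") <- pi0
  out
}

evidence_flag <- function(bf) {
  dplyr::case_when(
    bf >= 100 ~ "overwhelming",
    bf >= 10 ~ "strong",
    TRUE ~ "none"
  )
}
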