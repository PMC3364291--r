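#' Observed versus chance-expected overlap of two gene sets
#'
#' Under independent sampling from a universe of `universe_size` genes, two
#' sets of sizes `|A|` and `|B|` share `|A||B|/N` genes in expectation; the
#' observed intersection is compared with that.
#'
#' @param setA,setB character vectors of gene ids.
#' @param universe_size number of genes both platforms could have reported.
#' @return list: `observed`, `expected`, `fold` (observed/expected).
#' @export
expected_overlap <- function(setA, setB, universe_size) {
  if (universe_size <= 0) stop("universe_size must be positive", call. = FALSE)
  setA <- unique(setA); setB <- unique(setB)
  if (length(setA) > universe_size || length(setB) > universe_size) {
    stop("set sizes cannot exceed the universe size", call. = FALSE)
  }
  observed <- length(intersect(setA, setB))
  expected <- length(setA) * length(setB) / universe_size
  list(observed = observed, expected = expected,
       fold = if (expected > 0) observed / expected else NA_real_)
}

#' Fisher exact test for a 2x2 contingency table
#'
#' Exact conditional test on the hypergeometric distribution of the top-left
#' cell given fixed margins. The two-sided p-value sums the probabilities of
#' all tables no more likely than the observed one (the point-probability
#' rule). The odds ratio reported is the sample cross-product `ad/bc`;
#' degenerate tables are flagged.
#'
#' @param a,b,c,d non-negative integer cell counts; rows index the focal set
#'   (in/out), columns the property (with/without).
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"` — the
#'   direction of association for cell `a`.
#' @return list: `p`, `odds_ratio` (may be `Inf` or `NaN`, see
#'   `odds_ratio_defined`), `alternative`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("empty table", call. = FALSE)
  or <- (a * d) / (b * c)
  or_defined <- is.finite(or)
  m <- a + b      # row-1 margin
  n2 <- c + d     # row-2 margin
  kk <- a + c     # column-1 margin
  if (m == 0 || n2 == 0 || kk == 0 || b + d == 0) {
    return(list(p = 1, odds_ratio = NA_real_, odds_ratio_defined = FALSE,
                alternative = alternative))
  }
  support <- max(0, kk - n2):min(kk, m)
  dens <- stats::dhyper(support, m, n2, kk)
  p <- switch(alternative,
    greater = sum(dens[support >= a]),
    less = sum(dens[support <= a]),
    two_sided = {
      p_obs <- stats::dhyper(a, m, n2, kk)
      sum(dens[dens <= p_obs * (1 + 1e-7)])
    })
  list(p = min(1, p), odds_ratio = or, odds_ratio_defined = or_defined,
       alternative = alternative)
}

#' Cross-platform correlation of per-sample measurements
#'
#' Correlates measurements of one gene across the same samples on two
#' platforms (e.g. log2 microarray intensity versus qPCR minus-delta-Ct).
#' Spearman rank correlation is the default; Pearson is available.
#'
#' @param values_a,values_b paired numeric vectors, `n >= 4`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha significance threshold for the flag; default 0.05.
#' @return list: `rho`, `p`, `significant`, `method`, `n`.
#' @export
correlate_platforms <- function(values_a, values_b,
                                method = c("spearman", "pearson"),
                                alpha = 0.05) {
  method <- match.arg(method)
  if (length(values_a) != length(values_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (length(values_a) < 4) stop("need at least 4 paired samples",
                                 call. = FALSE)
  if (stats::sd(values_a) == 0 || stats::sd(values_b) == 0) {
    stop("zero variance in one of the platforms", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(values_a, values_b, method = method, exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value,
       significant = ct$p.value < alpha, method = method,
       n = length(values_a))
}

#' Run the variability screen on an external replication dataset
#'
#' Applies the same screen semantics to an already-preprocessed external
#' matrix: top-variance selection, one-sided variance-ratio F-test, signed
#' rank and proportion statistics. The sex-adjustment step is disabled (and
#' logged), the usual situation for public replication datasets lacking sex
#' metadata.
#'
#' @param external_matrix log2-scale subject-level [expression_matrix()].
#' @param external_samples matching [sample_table()] with ages.
#' @param top_fraction,top_k,q_method,q_cutoff passed to [dv_screen()].
#' @return list: the `"dv_screen"` fit, `proportion_greater`,
#'   `signed_rank_p`, `n_significant`, and `significant_probes` (the
#'   intersection hook for cross-study overlap).
#' @export
replicate_screen <- function(external_matrix, external_samples,
                             top_fraction = 0.05, top_k = NULL,
                             q_method = "storey", q_cutoff = 0.25) {
  if (anyNA(external_samples$age_years)) {
    stop("age missing for some samples in the replication dataset",
         call. = FALSE)
  }
  fit <- dv_screen(external_matrix, external_samples,
                   top_fraction = top_fraction, top_k = top_k,
                   adjust_sex = FALSE, q_method = q_method,
                   q_cutoff = q_cutoff)
  list(screen = fit,
       proportion_greater = fit$proportion_greater,
       signed_rank_p = as.numeric(fit$signed_rank_p),
       n_significant = fit$n_significant,
       significant_probes = fit$table$probe_id[fit$table$significant])
}
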