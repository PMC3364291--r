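# internal: unbiased per-row variances of a matrix, fast and base-R
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) stop("variance needs >= 2 columns", call. = FALSE)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

#' Select the most variable probes
#'
#' Ranks probes by unbiased sample variance across all samples (regardless of
#' group) and keeps the top fraction: `k = round(fraction * n_probes)` probes,
#' or an explicit `k` when given. Ties at the selection boundary are broken by
#' probe-id lexicographic order so the result is deterministic.
#'
#' @param matrix log2-scale [expression_matrix()] with >= 2 samples.
#' @param fraction fraction of probes to keep, in (0, 1]; default 0.05.
#' @param k explicit number of probes, overriding `fraction` (useful when
#'   replicating a published probe count that is not an exact percentage).
#' @return Character vector of selected probe ids, in ranking order.
#' @export
top_variance_subset <- function(matrix, fraction = 0.05, k = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (is.null(k)) {
    if (fraction <= 0 || fraction > 1) {
      stop("fraction must lie in (0, 1]", call. = FALSE)
    }
    k <- round(fraction * nrow(matrix$values))
  }
  k <- min(k, nrow(matrix$values))
  v <- row_vars(matrix$values)
  if (all(v == 0)) {
    stop("all probes are constant: no variance ranking possible",
         call. = FALSE)
  }
  ids <- probe_ids(matrix)
  ord <- order(-v, ids)
  ids[ord][seq_len(k)]
}

#' Variance-ratio F-test of greater variability in the young group
#'
#' The core screen. For each probe it computes the group standard deviations
#' and tests `H0: var_young / var_old <= 1` with the one-sided F-test:
#' `F = s2_young / s2_old` on `(n_young - 1, n_old - 1)` degrees of freedom,
#' upper-tail p-value. Both BH FDR and Storey pFDR q-values are attached,
#' along with the paired signed-rank test of the per-probe SD differences and
#' the fraction of probes with strictly greater SD in the young group.
#'
#' Degenerate probes are handled by convention: `s2_old = 0` with
#' `s2_young > 0` gives p = 0, both variances zero gives p = 1; such probes
#' are flagged in the `degenerate` column.
#'
#' @param matrix log2-scale [expression_matrix()], one column per subject.
#' @param samples matching [sample_table()]; both age groups need >= 2
#'   subjects.
#' @param probes probe ids to test (e.g. from [top_variance_subset()]);
#'   default all probes in the matrix.
#' @param q_method FDR flavour used for the `significant` call: `"storey"`
#'   (default, positive FDR) or `"bh"`.
#' @param q_cutoff q-value threshold for the `significant` flag; default 0.25.
#' @return An object of class `"dv_screen"`: list with the per-probe results
#'   `table`, group sizes, the summary statistics, and the probe universe the
#'   matrix supplied (used downstream as the enrichment reference).
#' @export
variance_ratio_ftest <- function(matrix, samples, probes = NULL,
                                 q_method = c("storey", "bh"),
                                 q_cutoff = 0.25) {
  stopifnot(inherits(matrix, "expr_matrix"))
  q_method <- match.arg(q_method)
  samples <- align_samples(matrix, samples)
  if (anyDuplicated(samples$subject_id)) {
    stop("replicate arrays present: average technical replicates before ",
         "the variance screen", call. = FALSE)
  }
  if (is.null(probes)) probes <- probe_ids(matrix)
  miss <- setdiff(probes, probe_ids(matrix))
  if (length(miss)) {
    stop("probe(s) not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  young <- samples$age_group == "young"
  n_young <- sum(young); n_old <- sum(!young)
  if (n_young < 2 || n_old < 2) {
    stop("both age groups need >= 2 subjects for a variance ratio",
         call. = FALSE)
  }
  x <- matrix$values[probes, , drop = FALSE]
  v_young <- row_vars(x[, young, drop = FALSE])
  v_old <- row_vars(x[, !young, drop = FALSE])
  df1 <- n_young - 1L; df2 <- n_old - 1L
  f <- v_young / v_old
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  degenerate <- v_old == 0
  p[degenerate & v_young > 0] <- 0
  p[degenerate & v_young == 0] <- 1
  q_bh <- adjust_fdr(p, "bh")
  q_pfdr <- adjust_fdr(p, "storey")
  q <- if (q_method == "storey") q_pfdr else q_bh
  tab <- data.frame(
    probe_id = probes,
    sd_young = sqrt(v_young), sd_old = sqrt(v_old),
    var_ratio = f, F = f, df_num = df1, df_den = df2,
    p_one_sided = p, q_bh = q_bh, q_pfdr = as.numeric(q_pfdr),
    degenerate = degenerate,
    selected_top_variance = TRUE,
    significant = q < q_cutoff,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(
    table = tab,
    n_young = n_young, n_old = n_old,
    q_method = q_method, q_cutoff = q_cutoff,
    pi0 = attr(q_pfdr, "pi0"),
    proportion_greater = proportion_sd_greater(tab$sd_young, tab$sd_old),
    signed_rank_p = signed_rank_paired_sd(tab$sd_young, tab$sd_old),
    n_significant = sum(tab$significant),
    probe_universe = probe_ids(matrix)
  ), class = "dv_screen")
}

#' Fit the full differential-variability screen
#'
#' Convenience fitting function chaining the stages of the variance analysis
#' on a preprocessed subject-level matrix: optional covariate centering,
#' selection of the most variable probes, and the one-sided variance-ratio
#' F-test with FDR control.
#'
#' @inheritParams variance_ratio_ftest
#' @param top_fraction fraction of probes kept by the variance pre-filter
#'   (default 0.05); use `1` to screen every probe.
#' @param top_k explicit pre-filter probe count overriding `top_fraction`.
#' @param adjust_sex centre expression within sex before computing variances
#'   (default `TRUE`; replication datasets without sex information set this
#'   to `FALSE`).
#' @return A `"dv_screen"` object; see [variance_ratio_ftest()].
#' @seealso [summary.dv_screen()], [plot.dv_screen()]
#' @export
#' @examples
#' study <- simulate_expression_study(sim_config(n_probes = 500, seed = 7))
#' prep <- preprocess_study(study$matrix, study$samples)
#' fit <- dv_screen(prep$matrix, prep$samples, top_fraction = 0.2)
#' summary(fit)
dv_screen <- function(matrix, samples, top_fraction = 0.05, top_k = NULL,
                      adjust_sex = TRUE, q_method = "storey",
                      q_cutoff = 0.25) {
  samples <- align_samples(matrix, samples)
  if (adjust_sex) {
    matrix <- adjust_group_means(matrix, samples, "sex")
  } else {
    message("sex adjustment skipped")
  }
  probes <- if (is.null(top_k) && top_fraction >= 1) {
    probe_ids(matrix)
  } else {
    top_variance_subset(matrix, fraction = top_fraction, k = top_k)
  }
  fit <- variance_ratio_ftest(matrix, samples, probes,
                              q_method = q_method, q_cutoff = q_cutoff)
  fit$top_fraction <- top_fraction
  fit$top_k <- length(probes)
  fit$adjust_sex <- adjust_sex
  fit
}

#' Paired signed-rank test on group standard deviations
#'
#' Wilcoxon signed-rank test of whether the young-group SDs exceed the
#' old-group SDs across the selected probes. Zero differences are dropped;
#' tied absolute differences receive average ranks. The exact null
#' distribution is used for up to 25 untied nonzero pairs, otherwise a normal
#' approximation with continuity and tie corrections.
#'
#' @param sd_young,sd_old equal-length paired SD vectors.
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @return p-value; when every difference is zero, 1 with a `"note"`
#'   attribute.
#' @export
signed_rank_paired_sd <- function(sd_young, sd_old,
                                  alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (length(sd_young) != length(sd_old)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  d <- sd_young - sd_old
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(1, note = "all paired differences are zero"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    p_greater <- stats::psignrank(w - 1, n, lower.tail = FALSE)
    p_less <- stats::psignrank(w, n)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z_g <- (w - mu - 0.5) / sqrt(sigma2)
    z_l <- (w - mu + 0.5) / sqrt(sigma2)
    p_greater <- stats::pnorm(z_g, lower.tail = FALSE)
    p_less <- stats::pnorm(z_l)
  }
  if (alternative == "greater") p_greater else min(1, 2 * min(p_greater, p_less))
}

#' Fraction of probes with strictly greater SD in the young group
#'
#' The headline proportion statistic: how many of the screened probes have a
#' larger expression SD among young subjects than old ones. Ties count as not
#' greater.
#'
#' @inheritParams signed_rank_paired_sd
#' @return fraction in `[0, 1]`.
#' @export
proportion_sd_greater <- function(sd_young, sd_old) {
  if (length(sd_young) != length(sd_old) || length(sd_young) == 0) {
    stop("paired nonempty vectors of equal length required", call. = FALSE)
  }
  mean(sd_young > sd_old)
}

#' Permutation null of the proportion-greater statistic
#'
#' A diagnostic for the selection bias the variance pre-filter induces:
#' pre-filtering on pooled variance before comparing group variances shifts
#' the null of the proportion-greater statistic above 0.5 when group sizes
#' are unbalanced. Age-group labels are permuted across subjects; each
#' permutation reruns the top-variance selection and recomputes the fraction
#' of probes with greater SD in the (permuted) young group.
#'
#' @param matrix log2-scale subject-level [expression_matrix()].
#' @param samples matching [sample_table()].
#' @param fraction variance pre-filter fraction (1 disables filtering).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @return list with `null` (vector of permuted proportions), `observed`,
#'   and `p_empirical` (share of permutations at or above the observed
#'   value, add-one corrected).
#' @export
permutation_null_proportion <- function(matrix, samples, fraction = 0.05,
                                        n_perm = 200, seed = 1L) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  samples <- align_samples(matrix, samples)
  set.seed(seed)
  young <- samples$age_group == "young"
  n <- length(young)
  probes <- if (fraction >= 1) probe_ids(matrix) else
    top_variance_subset(matrix, fraction)
  x <- matrix$values[probes, , drop = FALSE]
  prop_for <- function(is_young) {
    sdy <- sqrt(row_vars(x[, is_young, drop = FALSE]))
    sdo <- sqrt(row_vars(x[, !is_young, drop = FALSE]))
    mean(sdy > sdo)
  }
  observed <- prop_for(young)
  null <- vapply(seq_len(n_perm), function(i) {
    prop_for(sample(young))
  }, numeric(1))
  list(null = null, observed = observed,
       p_empirical = (1 + sum(null >= observed)) / (n_perm + 1))
}
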