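#' Hypergeometric over-representation test
#'
#' For each gene set, tests whether the study genes contain more members of
#' the set than expected under random sampling from the universe. With
#' universe size `N`, `K` set members in the universe, and `n` study genes of
#' which `k` are members: `expected = n K / N` and the upper-tail p-value is
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Genes outside the universe
#' are dropped from sets (with a message); study genes must lie inside the
#' universe.
#'
#' @param study character vector of study gene ids (subset of `universe`).
#' @param universe character vector: the reference gene list.
#' @param sets `"gene_sets"` collection (named list of gene-id vectors).
#' @param min_term_size smallest in-universe term size tested; default 2.
#' @param q_method FDR flavour for the `q` column (default `"storey"`).
#' @return data.frame of class `"dv_enrichment"`: `term_id`, `term_size_K`,
#'   `observed`, `expected`, `p_hyper`, `q`.
#' @export
hypergeometric_overrepresentation <- function(study, universe, sets,
                                              min_term_size = 2,
                                              q_method = "storey") {
  study <- unique(study); universe <- unique(universe)
  outside <- setdiff(study, universe)
  if (length(outside)) {
    stop("study gene(s) outside the universe: ",
         paste(utils::head(outside, 10), collapse = ", "),
         if (length(outside) > 10) ", ..." else "", call. = FALSE)
  }
  N <- length(universe); n <- length(study)
  if (n == 0) stop("empty study set", call. = FALSE)
  trimmed <- lapply(sets, intersect, universe)
  n_dropped <- sum(lengths(sets) - lengths(trimmed))
  if (n_dropped > 0) {
    message(n_dropped, " set member(s) outside the universe dropped")
  }
  keep <- lengths(trimmed) >= min_term_size
  trimmed <- trimmed[keep]
  K <- lengths(trimmed)
  k <- vapply(trimmed, function(g) length(intersect(g, study)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- as.numeric(adjust_fdr(p, q_method))
  out <- data.frame(term_id = names(trimmed), term_size_K = as.integer(K),
                    observed = as.integer(k), expected = n * K / N,
                    p_hyper = p, q = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_hyper, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dv_enrichment", "data.frame")
  out
}

#' Dual-reference enrichment report for a variability screen
#'
#' Collapses the screen's probes to unique gene ids and runs the
#' over-representation test twice: once against all genes present on the
#' (filtered) array, and once against the genes of the top-variance subset —
#' the two reference lists variability studies report side by side. Rows at
#' or below `q_report_cutoff` form the report; the full tables and
#' expected-versus-observed plot data are returned as well.
#'
#' @param screen a `"dv_screen"` fit (its significant probes form the study
#'   set; its probe universe and tested subset form the two references).
#' @param sets `"gene_sets"` collection.
#' @param probe_gene_map data.frame with columns `probe_id`, `gene_id`.
#' @param q_report_cutoff report threshold on the q-value; default 0.1.
#' @param min_term_size passed to [hypergeometric_overrepresentation()].
#' @return list of class `"dv_enrichment_report"`: `all_present` and
#'   `top_variance` (full `dv_enrichment` tables, each with a `report`
#'   attribute of rows passing the cutoff), `plot_data` (term, universe,
#'   expected, observed, q) and the study gene set.
#' @export
enrichment_report <- function(screen, sets, probe_gene_map,
                              q_report_cutoff = 0.1, min_term_size = 2) {
  stopifnot(inherits(screen, "dv_screen"))
  if (!all(c("probe_id", "gene_id") %in% names(probe_gene_map))) {
    stop("probe_gene_map needs columns probe_id and gene_id", call. = FALSE)
  }
  map_genes <- function(probes) {
    g <- probe_gene_map$gene_id[match(probes, probe_gene_map$probe_id)]
    lost <- sum(is.na(g))
    if (lost > 0) message(lost, " probe(s) without gene mapping dropped")
    unique(g[!is.na(g)])
  }
  study <- map_genes(screen$table$probe_id[screen$table$significant])
  if (length(study) == 0) {
    stop("no study genes left after mapping significant probes",
         call. = FALSE)
  }
  uni_all <- map_genes(screen$probe_universe)
  uni_top <- map_genes(screen$table$probe_id)
  res_all <- hypergeometric_overrepresentation(study, uni_all, sets,
                                               min_term_size)
  res_top <- hypergeometric_overrepresentation(study, uni_top, sets,
                                               min_term_size)
  attr(res_all, "report") <- res_all[res_all$q <= q_report_cutoff, ]
  attr(res_top, "report") <- res_top[res_top$q <= q_report_cutoff, ]
  plot_data <- rbind(
    cbind(universe = "all_present",
          res_all[, c("term_id", "expected", "observed", "q")]),
    cbind(universe = "top_variance",
          res_top[, c("term_id", "expected", "observed", "q")])
  )
  structure(list(all_present = res_all, top_variance = res_top,
                 plot_data = plot_data, study_genes = study,
                 q_report_cutoff = q_report_cutoff),
            class = "dv_enrichment_report")
}

#' @export
print.dv_enrichment_report <- function(x, ...) {
  cat("Over-representation report (", length(x$study_genes),
      " study genes)\n", sep = "")
  for (u in c("all_present", "top_variance")) {
    rep <- attr(x[[u]], "report")
    cat(sprintf("  universe %-12s: %d/%d terms at q <= %g\n", u,
                nrow(rep), nrow(x[[u]]), x$q_report_cutoff))
  }
  invisible(x)
}
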