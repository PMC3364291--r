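#' @export
print.dv_screen <- function(x, ...) {
  cat("Differential-variability screen\n")
  cat(sprintf("  %d probes tested (%d young vs %d old subjects)\n",
              nrow(x$table), x$n_young, x$n_old))
  cat(sprintf("  SD greater in young: %.1f%% of probes\n",
              100 * x$proportion_greater))
  cat(sprintf("  signed-rank p (young > old): %.3g\n",
              as.numeric(x$signed_rank_p)))
  cat(sprintf("  significant at %s q < %g: %d probes\n",
              x$q_method, x$q_cutoff, x$n_significant))
  invisible(x)
}

#' Summarize a differential-variability screen
#'
#' @param object a `"dv_screen"` fit.
#' @param ... unused.
#' @return list of class `"summary.dv_screen"` with the headline statistics
#'   and counts at several q-value thresholds.
#' @export
summary.dv_screen <- function(object, ...) {
  tab <- object$table
  thresholds <- c(0.05, 0.1, 0.25)
  counts <- data.frame(
    q_cutoff = thresholds,
    n_bh = vapply(thresholds, function(a) sum(tab$q_bh < a), integer(1)),
    n_pfdr = vapply(thresholds, function(a) sum(tab$q_pfdr < a), integer(1))
  )
  structure(list(
    n_tested = nrow(tab), n_young = object$n_young, n_old = object$n_old,
    proportion_greater = object$proportion_greater,
    signed_rank_p = as.numeric(object$signed_rank_p),
    pi0 = object$pi0, counts = counts,
    n_significant = object$n_significant,
    q_method = object$q_method, q_cutoff = object$q_cutoff
  ), class = "summary.dv_screen")
}

#' @export
print.summary.dv_screen <- function(x, ...) {
  cat("Differential-variability screen summary\n")
  cat(sprintf("  probes tested:        %d\n", x$n_tested))
  cat(sprintf("  group sizes:          %d young / %d old\n",
              x$n_young, x$n_old))
  cat(sprintf("  SD greater in young:  %.1f%%\n", 100 * x$proportion_greater))
  cat(sprintf("  signed-rank p:        %.3g\n", x$signed_rank_p))
  cat(sprintf("  estimated pi0:        %.3f\n", x$pi0))
  cat("  probes below q threshold:\n")
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("    q < %-5g BH: %-6d pFDR: %d\n", x$counts$q_cutoff[i],
                x$counts$n_bh[i], x$counts$n_pfdr[i]))
  }
  invisible(x)
}

#' @export
as.data.frame.dv_screen <- function(x, ...) x$table

#' Boxplot of paired SD differences
#'
#' Plots the distribution of `sd_young - sd_old` over the screened probes;
#' values above zero indicate greater inter-individual variability in the
#' young group.
#'
#' @param x a `"dv_screen"` fit.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.dv_screen <- function(x, ...) {
  d <- x$table$sd_young - x$table$sd_old
  graphics::boxplot(d, ylab = "SD(young) - SD(old), log2 scale",
                    main = "Paired SD differences", ...)
  graphics::abline(h = 0, lty = 2, col = "grey40")
  invisible(x)
}
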