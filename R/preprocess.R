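#' Filter probes by detection call
#'
#' Keeps probes whose detection p-value is at or below `p_threshold` in at
#' least `min_individuals` unique subjects. Detection is counted at the
#' subject level: by default a subject counts as detected if any of its
#' replicate arrays is detected (configurable to require all replicates).
#'
#' @param matrix raw-scale [expression_matrix()] carrying detection p-values.
#' @param samples [sample_table()] (supplies the array-to-subject grouping).
#' @param p_threshold detection p-value cutoff; default 0.1.
#' @param min_individuals minimum number of detected unique subjects;
#'   defaults to half the subjects, rounded down. Studies replicating a
#'   specific published configuration can override it explicitly.
#' @param replicate_rule `"any"` (default) or `"all"`: how replicate arrays
#'   of one subject vote.
#' @return The filtered `expr_matrix` with updated provenance.
#' @export
filter_by_detection <- function(matrix, samples, p_threshold = 0.1,
                                min_individuals = NULL,
                                replicate_rule = c("any", "all")) {
  stopifnot(inherits(matrix, "expr_matrix"))
  replicate_rule <- match.arg(replicate_rule)
  if (is.null(matrix$detection_p)) {
    stop("no detection p-values in this matrix; skip the detection filter",
         call. = FALSE)
  }
  samples <- align_samples(matrix, samples)
  subjects <- unique(samples$subject_id)
  if (is.null(min_individuals)) min_individuals <- floor(length(subjects) / 2)
  if (min_individuals > length(subjects)) {
    stop("min_individuals exceeds the number of unique subjects",
         call. = FALSE)
  }
  detected <- matrix$detection_p <= p_threshold
  vote <- if (replicate_rule == "any") any else all
  per_subject <- vapply(subjects, function(s) {
    cols <- which(samples$subject_id == s)
    apply(detected[, cols, drop = FALSE], 1, vote)
  }, logical(nrow(detected)))
  keep <- rowSums(per_subject) >= min_individuals
  out <- matrix
  out$values <- matrix$values[keep, , drop = FALSE]
  out$detection_p <- matrix$detection_p[keep, , drop = FALSE]
  add_provenance(out, sprintf(
    "detection_filter(p<=%g, >=%d/%d subjects, %s-replicate): %d -> %d probes",
    p_threshold, min_individuals, length(subjects), replicate_rule,
    nrow(matrix$values), sum(keep)))
}

#' Offset to a minimum of one, then log2-transform
#'
#' Adds a single global constant `c = 1 - min(values)` to every cell so the
#' smallest intensity equals exactly 1 (the constant may be negative when the
#' minimum exceeds 1), then takes log2. The minimum of the output is exactly
#' 0 by construction.
#'
#' @param matrix raw-scale [expression_matrix()].
#' @return log2-scale `expr_matrix`.
#' @export
offset_and_log2 <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$scale != "raw") stop("matrix is already on the log2 scale",
                                  call. = FALSE)
  if (length(matrix$values) == 0) stop("empty expression matrix",
                                       call. = FALSE)
  offset <- 1 - min(matrix$values)
  out <- matrix
  out$values <- log2(matrix$values + offset)
  out$scale <- "log2"
  add_provenance(out, sprintf("offset(%+.6g) + log2", offset))
}

#' Quantile normalization
#'
#' Forces every sample to share the reference distribution given by the
#' row means of the column-sorted matrix. Ties within a column all receive
#' the mean of the reference values at their tied ranks, so tied inputs stay
#' tied in the output.
#'
#' @param matrix log2-scale [expression_matrix()] with at least two samples
#'   and no missing values.
#' @return Quantile-normalized `expr_matrix`.
#' @export
quantile_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  x <- matrix$values
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples",
                        call. = FALSE)
  if (anyNA(x)) stop("missing values present; imputation is out of scope",
                     call. = FALSE)
  ref <- rowMeans(apply(x, 2, sort))
  out <- matrix
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    q <- numeric(length(v))
    q[order(v)] <- ref
    # tie groups share the mean of their assigned reference values
    q <- stats::ave(q, match(v, v), FUN = mean)
    out$values[, j] <- q
  }
  add_provenance(out, "quantile_normalize")
}

#' Average technical replicate arrays
#'
#' Collapses arrays of the same subject to one column by arithmetic mean of
#' the expression values (and, when present, the minimum of the detection
#' p-values, preserving any-replicate detection semantics). Covariates must
#' agree across a subject's replicates. Output columns are keyed by
#' `subject_id`.
#'
#' @param matrix an [expression_matrix()].
#' @param samples matching [sample_table()].
#' @return list with the collapsed `matrix` (one column per subject) and the
#'   collapsed `samples` table (one row per subject, `sample_id` equal to
#'   `subject_id`).
#' @export
average_technical_replicates <- function(matrix, samples) {
  stopifnot(inherits(matrix, "expr_matrix"))
  samples <- align_samples(matrix, samples)
  covars <- c("age_years", "sex", "dev_delay", "region")
  for (s in unique(samples$subject_id)) {
    rows <- samples[samples$subject_id == s, covars, drop = FALSE]
    if (nrow(unique(rows)) > 1) {
      stop("conflicting covariates across replicates of subject ", s,
           call. = FALSE)
    }
  }
  subjects <- unique(samples$subject_id)
  collapse <- function(m, fun) {
    out <- vapply(subjects, function(s) {
      cols <- which(samples$subject_id == s)
      apply(m[, cols, drop = FALSE], 1, fun)
    }, numeric(nrow(m)))
    dimnames(out) <- list(rownames(m), subjects)
    out
  }
  out <- matrix
  out$values <- collapse(matrix$values, mean)
  if (!is.null(matrix$detection_p)) {
    out$detection_p <- collapse(matrix$detection_p, min)
  }
  first <- samples[match(subjects, samples$subject_id), , drop = FALSE]
  first$sample_id <- first$subject_id
  rownames(first) <- NULL
  attr(first, "age_cutoff") <- attr(samples, "age_cutoff")
  class(first) <- c("sample_table", "data.frame")
  out <- add_provenance(out, sprintf("replicate_average: %d -> %d columns",
                                     ncol(matrix$values), length(subjects)))
  list(matrix = out, samples = first)
}

#' Center expression within levels of a covariate
#'
#' Per probe, subtracts each factor level's mean from that level's samples,
#' leaving every level with mean exactly zero. With `factor = "sex"` this is
#' the standard removal of additive sex effects before a variance analysis;
#' an `"unknown"` code is treated as its own level, so a study with no sex
#' information degrades to overall-mean centering.
#'
#' @param matrix log2-scale [expression_matrix()].
#' @param samples matching [sample_table()].
#' @param factor name of the covariate column to adjust for (default
#'   `"sex"`).
#' @return Adjusted `expr_matrix`.
#' @export
adjust_group_means <- function(matrix, samples, factor = "sex") {
  stopifnot(inherits(matrix, "expr_matrix"))
  samples <- align_samples(matrix, samples)
  if (!factor %in% names(samples)) {
    stop("covariate '", factor, "' not present in the sample table",
         call. = FALSE)
  }
  lev <- as.character(samples[[factor]])
  out <- matrix
  for (l in unique(lev)) {
    cols <- which(lev == l)
    mu <- rowMeans(matrix$values[, cols, drop = FALSE])
    out$values[, cols] <- matrix$values[, cols, drop = FALSE] - mu
  }
  add_provenance(out, sprintf("adjust_group_means(%s: %s)", factor,
                              paste(unique(lev), collapse = "/")))
}

#' Run the full preprocessing chain in canonical order
#'
#' Detection filter, offset + log2, quantile normalization, technical
#' replicate averaging, then covariate centering — the order every stage's
#' assumptions require. Each step is recorded in the provenance.
#'
#' @param matrix raw-scale [expression_matrix()].
#' @param samples [sample_table()].
#' @param p_threshold,min_individuals,replicate_rule passed to
#'   [filter_by_detection()]; the filter is skipped (with a provenance note)
#'   when the matrix carries no detection p-values.
#' @param adjust_factor covariate for [adjust_group_means()], or `NULL` to
#'   skip the adjustment.
#' @return list with the preprocessed subject-level `matrix` and collapsed
#'   `samples`.
#' @export
preprocess_study <- function(matrix, samples, p_threshold = 0.1,
                             min_individuals = NULL,
                             replicate_rule = "any",
                             adjust_factor = "sex") {
  if (!is.null(matrix$detection_p)) {
    matrix <- filter_by_detection(matrix, samples, p_threshold,
                                  min_individuals, replicate_rule)
  } else {
    matrix <- add_provenance(matrix, "detection_filter skipped (no p-values)")
  }
  matrix <- offset_and_log2(matrix)
  matrix <- quantile_normalize(matrix)
  avg <- average_technical_replicates(matrix, samples)
  if (!is.null(adjust_factor)) {
    avg$matrix <- adjust_group_means(avg$matrix, avg$samples, adjust_factor)
  } else {
    avg$matrix <- add_provenance(avg$matrix, "covariate adjustment skipped")
  }
  avg
}
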