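#' Expression matrix container
#'
#' A probe-by-sample numeric matrix with a scale flag (`"raw"` intensities or
#' `"log2"` values), optional per-cell detection p-values, and a provenance
#' record of the transforms applied so far. This is the object every
#' preprocessing stage consumes and returns.
#'
#' @param values numeric matrix, probes in rows, samples in columns. Row and
#'   column names are required and must be unique; they serve as probe and
#'   sample identifiers.
#' @param scale either `"raw"` or `"log2"`.
#' @param detection_p optional numeric matrix of detection p-values in
#'   `[0, 1]`, same dimensions and dimnames as `values`. A small value means
#'   the probe's signal is distinguishable from background in that sample.
#' @param provenance character vector of transform labels already applied,
#'   in order.
#'
#' @return An object of class `"expr_matrix"`.
#' @export
expression_matrix <- function(values, scale = c("raw", "log2"),
                              detection_p = NULL, provenance = character()) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have probe row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate probe ids in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  }
  if (scale == "raw" && any(!is.finite(values))) {
    stop("raw-scale expression values must be finite", call. = FALSE)
  }
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !all(dim(detection_p) == dim(values))) {
      stop("'detection_p' must be a matrix with the same shape as 'values'",
           call. = FALSE)
    }
    if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE)) {
      stop("detection p-values must lie in [0, 1]", call. = FALSE)
    }
    dimnames(detection_p) <- dimnames(values)
  }
  structure(
    list(values = values, detection_p = detection_p, scale = scale,
         provenance = as.character(provenance)),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d probes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$detection_p)) cat("  with detection p-values\n")
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Probe and sample identifiers of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector of ids.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$values)

# internal: append a provenance entry, preserving everything else
add_provenance <- function(x, label) {
  x$provenance <- c(x$provenance, label)
  x
}

#' Sample metadata table
#'
#' Per-sample covariates for an expression study. Technical replicates share a
#' `subject_id`; the `age_group` column is derived from `age_years` at the
#' given cutoff (young strictly below the cutoff, old at or above it).
#'
#' @param df data.frame with columns `sample_id`, `subject_id`, `age_years`,
#'   and optionally `sex` (`"male"`, `"female"` or `"unknown"`), `dev_delay`
#'   (logical) and `region`. Missing optional columns are filled with
#'   `"unknown"` / `FALSE` / `NA`.
#' @param age_cutoff age in years splitting young from old; default 15.
#'
#' @return A data.frame of class `"sample_table"` with a derived `age_group`
#'   factor (`young`/`old`) and the cutoff stored as an attribute.
#' @export
sample_table <- function(df, age_cutoff = 15) {
  stopifnot(is.data.frame(df))
  required <- c("sample_id", "subject_id", "age_years")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("sample table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in sample table", call. = FALSE)
  }
  if (any(!is.finite(df$age_years)) || any(df$age_years < 0)) {
    stop("age_years must be non-negative and finite", call. = FALSE)
  }
  if (!is.numeric(age_cutoff) || age_cutoff <= 0) {
    stop("age_cutoff must be positive", call. = FALSE)
  }
  if (is.null(df$sex)) df$sex <- "unknown"
  df$sex <- as.character(df$sex)
  bad_sex <- setdiff(unique(df$sex), c("male", "female", "unknown"))
  if (length(bad_sex)) {
    stop("unknown sex code(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$dev_delay)) df$dev_delay <- FALSE
  df$dev_delay <- as.logical(df$dev_delay)
  if (is.null(df$region)) df$region <- NA_character_
  df$age_group <- factor(ifelse(df$age_years < age_cutoff, "young", "old"),
                         levels = c("young", "old"))
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  attr(df, "age_cutoff") <- age_cutoff
  class(df) <- c("sample_table", "data.frame")
  df
}

# internal: check that every matrix sample has metadata, and return the
# metadata rows in matrix column order
align_samples <- function(matrix, samples) {
  miss <- setdiff(sample_ids(matrix), samples$sample_id)
  if (length(miss)) {
    stop("sample(s) present in matrix but missing from metadata: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  samples[match(sample_ids(matrix), samples$sample_id), , drop = FALSE]
}
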