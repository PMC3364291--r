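# Plain-text study formats: tab-separated probe x sample matrices with a
# header row of sample ids and a leading probe-id column; metadata TSV; GMT
# gene sets; 2-column probe -> gene TSV.

#' Read / write an expression (or detection-p) matrix as TSV
#'
#' @param path file path.
#' @param scale scale flag to attach on read (`"raw"` or `"log2"`).
#' @param detection_path optional path of a same-shape detection-p TSV.
#' @return [expression_matrix()] on read; invisibly `path` on write.
#' @export
read_expression_tsv <- function(path, scale = "raw", detection_path = NULL) {
  read_mat <- function(f) {
    df <- utils::read.delim(f, check.names = FALSE, stringsAsFactors = FALSE)
    if (anyDuplicated(df[[1]])) {
      stop("duplicate probe ids in ", f, call. = FALSE)
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric cells in ", f, call. = FALSE)
    rownames(m) <- df[[1]]
    m
  }
  values <- read_mat(path)
  det <- NULL
  if (!is.null(detection_path)) {
    det <- read_mat(detection_path)
    if (!identical(dim(det), dim(values)) ||
        !identical(dimnames(det), dimnames(values))) {
      stop("detection-p matrix does not align with the expression matrix",
           call. = FALSE)
    }
  }
  expression_matrix(values, scale = scale, detection_p = det)
}

#' @rdname read_expression_tsv
#' @param matrix an [expression_matrix()] to write (its detection p-values,
#'   when present, go to `detection_path`).
#' @export
write_expression_tsv <- function(matrix, path, detection_path = NULL) {
  write_mat <- function(m, f) {
    # %.17g keeps doubles bit-exact across a write/read cycle
    chr <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
    df <- data.frame(probe_id = rownames(m), chr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(matrix$values, path)
  if (!is.null(detection_path) && !is.null(matrix$detection_p)) {
    write_mat(matrix$detection_p, detection_path)
  }
  invisible(path)
}

#' Read / write the sample metadata TSV
#'
#' Columns: `sample_id`, `subject_id`, `age_years`, `sex`, `dev_delay`,
#' `region`.
#'
#' @param path file path.
#' @param age_cutoff passed to [sample_table()].
#' @export
read_sample_table <- function(path, age_cutoff = 15) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_table(df, age_cutoff = age_cutoff)
}

#' @rdname read_sample_table
#' @param samples a [sample_table()] to write.
#' @export
write_sample_table <- function(samples, path) {
  cols <- intersect(c("sample_id", "subject_id", "age_years", "sex",
                      "dev_delay", "region"), names(samples))
  utils::write.table(samples[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT: one term per line, tab-separated `term_id`, description,
#' then member gene ids (so at least 3 fields).
#'
#' @param path file path.
#' @return `"gene_sets"` collection (named list of gene-id vectors with a
#'   `descriptions` attribute).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descr <- character(length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT parse error at line ", i, ": fewer than 3 tab-separated ",
           "fields", call. = FALSE)
    }
    ids[i] <- fields[1]
    descr[i] <- fields[2]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(ids)) stop("duplicate term ids in GMT", call. = FALSE)
  structure(setNames(sets, ids), descriptions = setNames(descr, ids),
            class = "gene_sets")
}

#' @rdname read_gmt
#' @param sets a `"gene_sets"` collection to write.
#' @export
write_gmt <- function(sets, path) {
  descr <- attr(sets, "descriptions")
  if (is.null(descr)) descr <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descr[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 2-column probe-to-gene map TSV
#'
#' @param path file with header columns `probe_id` and `gene_id`.
#' @export
read_probe_gene_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(df))) {
    stop("probe-gene map needs columns probe_id and gene_id", call. = FALSE)
  }
  df
}

#' Write a simulated study bundle to disk
#'
#' Writes the standard plain-text bundle: `expression.tsv`, `detection_p.tsv`,
#' `metadata.tsv`, `truth.csv`, and `gene_sets.gmt` (plus `probe_gene_map.tsv`)
#' when gene sets are supplied.
#'
#' @param study result of [simulate_expression_study()].
#' @param dir output directory (created if needed).
#' @param sets optional `"gene_sets"` collection.
#' @return invisibly, the named vector of file paths written.
#' @export
write_study_bundle <- function(study, dir, sets = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             detection = file.path(dir, "detection_p.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.csv"))
  write_expression_tsv(study$matrix, paths["expression"], paths["detection"])
  write_sample_table(study$samples, paths["metadata"])
  utils::write.csv(study$truth, paths["truth"], row.names = FALSE)
  if (!is.null(sets)) {
    paths <- c(paths, gmt = file.path(dir, "gene_sets.gmt"),
               map = file.path(dir, "probe_gene_map.tsv"))
    write_gmt(sets, paths["gmt"])
    utils::write.table(study$truth[, c("probe_id", "gene_id")], paths["map"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
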