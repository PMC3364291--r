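#' Study configuration
#'
#' Bundles everything one analysis run needs: either the paths of an on-disk
#' study bundle or a simulation block (exactly one of the two), the stage
#' parameters, an output directory and a seed. Defaults carry the screen's
#' canonical constants: detection p <= 0.1, top 5% variance pre-filter,
#' age cutoff 15 years, significance at pFDR < 0.25, enrichment report at
#' q <= 0.1.
#'
#' @param expression,detection,metadata,gmt,probe_gene_map input file paths
#'   (`gmt`/`probe_gene_map`/`detection` optional).
#' @param simulation a [sim_config()] instead of input paths.
#' @param detection_threshold detection p-value cutoff (default 0.1).
#' @param min_individuals detected-subject minimum for the filter; `NULL` for
#'   half the subjects. Published re-analyses can pin the exact value (e.g.
#'   16).
#' @param top_fraction variance pre-filter fraction (default 0.05).
#' @param top_k explicit pre-filter count overriding `top_fraction` (e.g.
#'   1095 to match a published probe count).
#' @param age_cutoff young/old split in years (default 15).
#' @param q_cutoff significance threshold on the screen q-values
#'   (default 0.25).
#' @param q_report_cutoff enrichment report threshold (default 0.1).
#' @param fdr_method `"storey"` or `"bh"`.
#' @param adjust_sex centre within sex before the screen (default `TRUE`).
#' @param correlation_method `"spearman"` or `"pearson"`.
#' @param out_dir output directory for [run_pipeline()].
#' @param seed integer seed governing any randomness in the run.
#' @return validated list of class `"study_config"`.
#' @export
study_config <- function(expression = NULL, detection = NULL, metadata = NULL,
                         gmt = NULL, probe_gene_map = NULL, simulation = NULL,
                         detection_threshold = 0.1, min_individuals = NULL,
                         top_fraction = 0.05, top_k = NULL, age_cutoff = 15,
                         q_cutoff = 0.25, q_report_cutoff = 0.1,
                         fdr_method = c("storey", "bh"), adjust_sex = TRUE,
                         correlation_method = c("spearman", "pearson"),
                         out_dir = tempfile("devvar_run_"), seed = 1L) {
  fdr_method <- match.arg(fdr_method)
  correlation_method <- match.arg(correlation_method)
  has_paths <- !is.null(expression) || !is.null(metadata)
  has_sim <- !is.null(simulation)
  if (has_paths == has_sim) {
    stop("exactly one of input paths or a simulation block must be given",
         call. = FALSE)
  }
  if (has_paths && (is.null(expression) || is.null(metadata))) {
    stop("file input requires both expression and metadata paths",
         call. = FALSE)
  }
  if (has_sim && !inherits(simulation, "sim_config")) {
    stop("simulation block must be a sim_config()", call. = FALSE)
  }
  if (age_cutoff <= 0) stop("age_cutoff must be positive", call. = FALSE)
  for (thr in c(detection_threshold, top_fraction, q_cutoff,
                q_report_cutoff)) {
    if (thr <= 0 || thr > 1) {
      stop("thresholds must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(list(
    expression = expression, detection = detection, metadata = metadata,
    gmt = gmt, probe_gene_map = probe_gene_map, simulation = simulation,
    detection_threshold = detection_threshold,
    min_individuals = min_individuals, top_fraction = top_fraction,
    top_k = top_k, age_cutoff = age_cutoff, q_cutoff = q_cutoff,
    q_report_cutoff = q_report_cutoff, fdr_method = fdr_method,
    adjust_sex = adjust_sex, correlation_method = correlation_method,
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [study_config()]; a `simulation`
#' mapping is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return `"study_config"`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) y$simulation <- do.call(sim_config, y$simulation)
  do.call(study_config, y)
}

#' Load and align the study inputs named by a configuration
#'
#' @param config a [study_config()].
#' @return list: `matrix`, `samples`, and (when configured) `sets`,
#'   `probe_gene_map`, `truth`.
#' @export
load_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(config$simulation)) {
    study <- simulate_expression_study(config$simulation)
    out <- list(matrix = study$matrix, samples = study$samples,
                truth = study$truth)
  } else {
    out <- list(
      matrix = read_expression_tsv(config$expression,
                                   detection_path = config$detection),
      samples = read_sample_table(config$metadata,
                                  age_cutoff = config$age_cutoff),
      truth = NULL
    )
  }
  align_samples(out$matrix, out$samples)   # fails early with the sample name
  if (!is.null(config$gmt)) out$sets <- read_gmt(config$gmt)
  if (!is.null(config$probe_gene_map)) {
    out$probe_gene_map <- read_probe_gene_map(config$probe_gene_map)
  }
  out
}

#' Run the full differential-variability pipeline
#'
#' Orchestrates preprocessing, the variance screen, the age-trajectory
#' exclusion and (when annotations are configured) the enrichment analysis,
#' writing every result table plus a machine-readable manifest to
#' `config$out_dir`. A rerun with the same configuration and seed reproduces
#' all numeric outputs.
#'
#' @param config a [study_config()].
#' @return invisibly, a list of class `"dv_study"` with the in-memory
#'   results (`preprocessed`, `screen`, `trajectory`, `enrichment`,
#'   `summary`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_study(config)
  n0 <- nrow(inputs$matrix$values)
  message("loaded ", n0, " probes x ", ncol(inputs$matrix$values), " arrays")

  prep <- preprocess_study(inputs$matrix, inputs$samples,
                           p_threshold = config$detection_threshold,
                           min_individuals = config$min_individuals,
                           adjust_factor = NULL)
  message("preprocessed: ", nrow(prep$matrix$values), " probes x ",
          ncol(prep$matrix$values), " subjects")

  screen <- dv_screen(prep$matrix, prep$samples,
                      top_fraction = config$top_fraction,
                      top_k = config$top_k,
                      adjust_sex = config$adjust_sex,
                      q_method = config$fdr_method,
                      q_cutoff = config$q_cutoff)
  message("screen: ", nrow(screen$table), " probes tested, ",
          screen$n_significant, " significant at q < ", config$q_cutoff)

  sig <- screen$table$probe_id[screen$table$significant]
  trajectory <- screen_age_regulated(prep$matrix, prep$samples, probes = sig,
                                     q_cutoff = config$q_cutoff)

  enrichment <- NULL
  if (!is.null(inputs$sets) && !is.null(inputs$probe_gene_map) &&
      length(sig) > 0) {
    enrichment <- enrichment_report(screen, inputs$sets,
                                    inputs$probe_gene_map,
                                    q_report_cutoff = config$q_report_cutoff)
  }

  files <- c(
    preprocessed = file.path(config$out_dir, "expression_preprocessed.tsv"),
    screen = file.path(config$out_dir, "screen_results.csv"),
    trajectory = file.path(config$out_dir, "trajectory_results.csv"),
    summary = file.path(config$out_dir, "summary.json"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  write_expression_tsv(prep$matrix, files["preprocessed"])
  utils::write.csv(screen$table, files["screen"], row.names = FALSE)
  utils::write.csv(as.data.frame(trajectory), files["trajectory"],
                   row.names = FALSE)
  if (!is.null(enrichment)) {
    files <- c(files,
               enrichment_all = file.path(config$out_dir,
                                          "enrichment_all_present.csv"),
               enrichment_top = file.path(config$out_dir,
                                          "enrichment_top_variance.csv"),
               plot_data = file.path(config$out_dir,
                                     "enrichment_plot_data.csv"))
    utils::write.csv(enrichment$all_present, files["enrichment_all"],
                     row.names = FALSE)
    utils::write.csv(enrichment$top_variance, files["enrichment_top"],
                     row.names = FALSE)
    utils::write.csv(enrichment$plot_data, files["plot_data"],
                     row.names = FALSE)
  }

  summary_list <- list(
    n_probes_input = n0,
    n_probes_after_filter = nrow(prep$matrix$values),
    n_subjects = ncol(prep$matrix$values),
    n_young = screen$n_young, n_old = screen$n_old,
    n_tested = nrow(screen$table),
    proportion_sd_greater = screen$proportion_greater,
    signed_rank_p = as.numeric(screen$signed_rank_p),
    pi0 = screen$pi0,
    n_significant = screen$n_significant,
    n_developmentally_regulated = sum(trajectory$developmentally_regulated),
    n_enriched_terms = if (is.null(enrichment)) NA_integer_ else
      nrow(attr(enrichment$all_present, "report"))
  )
  jsonlite::write_json(summary_list, files["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("devvar")),
    r_version = R.version.string,
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("out_dir", "simulation"))],
    simulation = if (is.null(config$simulation)) NULL else
      unclass(config$simulation),
    provenance = prep$matrix$provenance,
    files = as.list(files)
  )
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(structure(list(
    config = config, preprocessed = prep, screen = screen,
    trajectory = trajectory, enrichment = enrichment,
    truth = inputs$truth, summary = summary_list, files = files
  ), class = "dv_study"))
}

#' @export
print.dv_study <- function(x, ...) {
  cat("Differential-variability study run\n")
  cat(sprintf("  funnel: %d probes -> %d after filter -> %d tested -> %d significant\n",
              x$summary$n_probes_input, x$summary$n_probes_after_filter,
              x$summary$n_tested, x$summary$n_significant))
  cat(sprintf("  SD greater in young: %.1f%%; signed-rank p = %.3g\n",
              100 * x$summary$proportion_sd_greater,
              x$summary$signed_rank_p))
  cat(sprintf("  developmentally regulated among significant: %d\n",
              x$summary$n_developmentally_regulated))
  cat("  outputs in: ", x$config$out_dir, "\n", sep = "")
  invisible(x)
}
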