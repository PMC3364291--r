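#' Simulation configuration
#'
#' Parameters of the synthetic expression-study generator. The defaults
#' emulate the study design the screen targets: 29 young (<15 y) and 8 old
#' (>=15 y) subjects, 3 subjects arrayed in duplicate (so 40 arrays for 37
#' unique samples), and a probe population mixing null genes with classes
#' carrying group-specific variance ratios, sex effects and quadratic age
#' trajectories.
#'
#' @param n_probes number of probes to simulate.
#' @param n_young,n_old subjects below / at-or-above the age cutoff.
#' @param n_duplicated_subjects subjects assayed on two arrays each.
#' @param age_range_young,age_range_old uniform sampling intervals for ages,
#'   in years.
#' @param frac_dv fraction of probes with differential variability (larger
#'   SD in the young group).
#' @param variance_ratio sigma_young / sigma_old for DV probes: a scalar, or
#'   a length-2 interval to sample ratios from uniformly. Must be >= 1.
#' @param frac_dev fraction of probes with a quadratic age trajectory.
#' @param frac_sex fraction of probes with an additive sex effect.
#' @param frac_mixed fraction of probes combining all three effects.
#' @param base_sd biological log2-scale SD in the adult group.
#' @param technical_sd SD of replicate-array noise on the log2 scale.
#' @param background_scale scale of the half-normal background added to the
#'   raw intensities.
#' @param frac_undetected fraction of probes simulated as unexpressed
#'   (near-background intensity, uniform detection p-values).
#' @param detection_p_max upper bound of detection p-values for expressed
#'   probes.
#' @param seed integer RNG seed; the generator is deterministic given it.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_probes = 2000,
                       n_young = 29, n_old = 8,
                       n_duplicated_subjects = 3,
                       age_range_young = c(0.5, 14.5),
                       age_range_old = c(15, 53),
                       frac_dv = 0.10,
                       variance_ratio = 3,
                       frac_dev = 0.05,
                       frac_sex = 0.05,
                       frac_mixed = 0,
                       base_sd = 0.30,
                       technical_sd = 0.10,
                       background_scale = 1,
                       frac_undetected = 0.05,
                       detection_p_max = 0.05,
                       seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), n_young = as.integer(n_young),
              n_old = as.integer(n_old),
              n_duplicated_subjects = as.integer(n_duplicated_subjects),
              age_range_young = age_range_young, age_range_old = age_range_old,
              frac_dv = frac_dv, variance_ratio = variance_ratio,
              frac_dev = frac_dev, frac_sex = frac_sex, frac_mixed = frac_mixed,
              base_sd = base_sd, technical_sd = technical_sd,
              background_scale = background_scale,
              frac_undetected = frac_undetected,
              detection_p_max = detection_p_max, seed = as.integer(seed))
  fr <- c(cfg$frac_dv, cfg$frac_dev, cfg$frac_sex, cfg$frac_mixed)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("class fractions must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  }
  if (cfg$n_probes < 1) stop("n_probes must be positive", call. = FALSE)
  if (cfg$n_young < 1 || cfg$n_old < 1) {
    stop("both age groups need at least one subject (group variances are ",
         "undefined otherwise)", call. = FALSE)
  }
  if (cfg$n_duplicated_subjects > cfg$n_young + cfg$n_old) {
    stop("cannot duplicate more subjects than exist", call. = FALSE)
  }
  if (any(variance_ratio < 1)) {
    stop("variance_ratio (sigma_young/sigma_old) must be >= 1", call. = FALSE)
  }
  if (base_sd < 0 || technical_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a complete expression study with ground truth
#'
#' Generates a raw-intensity probe-by-array matrix plus detection p-values,
#' the matching sample table, and a truth table holding every generative
#' parameter. The log2 signal for probe g in subject i is
#' `mu_g + beta_sex * male_i + gamma1 * age_i + gamma2 * age_i^2 + eps`,
#' with `eps ~ Normal(0, sigma_{g, group(i)})`; raw intensity is `2^signal`
#' plus a half-normal background. Duplicated subjects appear as two arrays
#' differing by `Normal(0, technical_sd)` on the log2 scale.
#'
#' The single RNG stream is consumed in a fixed documented order — probe
#' parameters, then sample covariates, then noise, then detection p-values —
#' so a seed pins down the whole study.
#'
#' @param config a [sim_config()].
#' @return A list with components `matrix` (raw-scale [expression_matrix()]
#'   with detection p-values), `samples` ([sample_table()]), `truth`
#'   (data.frame: probe_id, gene_id, class, mu, sd_young, sd_old, beta_sex,
#'   gamma1, gamma2, expressed), and `degenerate` (`TRUE` when the
#'   configuration leaves every probe constant across samples).
#' @export
simulate_expression_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_probes
  width <- max(5, nchar(m))
  probe_id <- sprintf("P%0*d", width, seq_len(m))
  gene_id <- sprintf("G%0*d", width, seq_len(m))

  ## 1. probe parameters -----------------------------------------------------
  n_dv <- round(config$frac_dv * m)
  n_dev <- round(config$frac_dev * m)
  n_sex <- round(config$frac_sex * m)
  n_mixed <- round(config$frac_mixed * m)
  cls <- rep("null", m)
  idx <- seq_len(m)
  pick <- function(k, pool) if (k > 0) pool[seq_len(k)] else integer(0)
  pool <- sample(idx)                       # random class placement
  i_dv <- pick(n_dv, pool);          pool <- setdiff(pool, i_dv)
  i_dev <- pick(n_dev, pool);        pool <- setdiff(pool, i_dev)
  i_sex <- pick(n_sex, pool);        pool <- setdiff(pool, i_sex)
  i_mix <- pick(n_mixed, pool)
  cls[i_dv] <- "dv"; cls[i_dev] <- "dev"; cls[i_sex] <- "sex"
  cls[i_mix] <- "mixed"

  expressed <- rep(TRUE, m)
  n_undet <- round(config$frac_undetected * m)
  if (n_undet > 0) {
    i_undet <- sample(which(cls == "null"), min(n_undet, sum(cls == "null")))
    expressed[i_undet] <- FALSE
  }
  mu <- ifelse(expressed, runif(m, 6, 12), runif(m, -1, 1))

  vr <- rep(1, m)
  has_dv <- cls %in% c("dv", "mixed")
  if (any(has_dv)) {
    vr[has_dv] <- if (length(config$variance_ratio) == 2) {
      runif(sum(has_dv), config$variance_ratio[1], config$variance_ratio[2])
    } else config$variance_ratio
  }
  sd_old <- rep(config$base_sd, m)
  sd_young <- sd_old * vr

  beta_sex <- numeric(m)
  has_sex <- cls %in% c("sex", "mixed")
  beta_sex[has_sex] <- sample(c(-1, 1), sum(has_sex), replace = TRUE) *
    runif(sum(has_sex), 0.5, 1.5)

  gamma1 <- gamma2 <- numeric(m)
  has_dev <- cls %in% c("dev", "mixed")
  if (any(has_dev)) {
    # concave-down quadratic peaking in childhood: amplitude ~1 log2 unit
    amp <- runif(sum(has_dev), 0.75, 1.5)
    peak <- runif(sum(has_dev), 3, 10)
    scl <- 25
    gamma2[has_dev] <- -amp / scl^2
    gamma1[has_dev] <- 2 * amp * peak / scl^2
  }

  ## 2. sample covariates ----------------------------------------------------
  n_sub <- config$n_young + config$n_old
  ages <- c(runif(config$n_young, config$age_range_young[1],
                  config$age_range_young[2]),
            runif(config$n_old, config$age_range_old[1],
                  config$age_range_old[2]))
  sex <- sample(c("male", "female"), n_sub, replace = TRUE)
  delay <- runif(n_sub) < 0.2
  subject_id <- sprintf("S%02d", seq_len(n_sub))
  dup <- sample(seq_len(n_sub), config$n_duplicated_subjects)
  array_subject <- c(seq_len(n_sub), dup)    # one array each + duplicates
  n_arr <- length(array_subject)
  array_id <- sprintf("A%02d", seq_len(n_arr))

  samples <- sample_table(data.frame(
    sample_id = array_id,
    subject_id = subject_id[array_subject],
    age_years = ages[array_subject],
    sex = sex[array_subject],
    dev_delay = delay[array_subject],
    region = "temporal cortex",
    stringsAsFactors = FALSE
  ))

  ## 3. noise ----------------------------------------------------------------
  young <- ages < 15
  sd_mat <- outer(sd_young, as.numeric(young)) +
    outer(sd_old, as.numeric(!young))        # m x n_sub group SDs
  eps <- matrix(rnorm(m * n_sub), m, n_sub) * sd_mat
  male <- as.numeric(sex == "male")
  signal <- mu + outer(beta_sex, male) + outer(gamma1, ages) +
    outer(gamma2, ages^2) + eps
  x <- signal[, array_subject, drop = FALSE]
  if (config$n_duplicated_subjects > 0 && config$technical_sd > 0) {
    tech <- matrix(rnorm(m * n_arr, sd = config$technical_sd), m, n_arr)
    x <- x + tech
  }
  raw <- 2^x + abs(matrix(rnorm(m * n_arr, sd = config$background_scale),
                          m, n_arr))
  dimnames(raw) <- list(probe_id, array_id)

  ## 4. detection p-values ---------------------------------------------------
  det <- matrix(runif(m * n_arr), m, n_arr)
  det[expressed, ] <- det[expressed, ] * config$detection_p_max
  dimnames(det) <- dimnames(raw)

  degenerate <- config$base_sd == 0 && config$technical_sd == 0 &&
    all(!has_dv & !has_sex & !has_dev)
  if (degenerate) {
    warning("degenerate configuration: every probe is constant across ",
            "samples (zero-noise limit)", call. = FALSE)
  }

  truth <- data.frame(probe_id = probe_id, gene_id = gene_id, class = cls,
                      mu = mu, sd_young = sd_young, sd_old = sd_old,
                      beta_sex = beta_sex, gamma1 = gamma1, gamma2 = gamma2,
                      expressed = expressed, stringsAsFactors = FALSE)
  list(matrix = expression_matrix(raw, scale = "raw", detection_p = det,
                                  provenance = "simulated"),
       samples = samples, truth = truth, degenerate = degenerate)
}

#' Simulate gene-set annotations with one planted enriched term
#'
#' Builds a collection of flat gene sets over the simulated genes. One
#' designated term (`TERM_PLANTED`) samples differential-variability genes
#' with elevated odds; all remaining terms sample genes independently of
#' class, so enrichment analyses have a known positive and known nulls.
#'
#' @param truth truth table from [simulate_expression_study()].
#' @param n_terms number of terms (0 gives an empty collection).
#' @param planted_odds_ratio sampling-weight ratio for DV genes in the
#'   planted term; 1 makes membership independent of class.
#' @param term_size length-2 integer interval of term sizes.
#' @param seed integer RNG seed.
#' @return A named list of gene-id vectors, class `"gene_sets"`, with a
#'   `descriptions` attribute.
#' @export
simulate_gene_sets <- function(truth, n_terms = 50, planted_odds_ratio = 1,
                               term_size = c(10, 100), seed = 1L) {
  if (!nrow(truth)) stop("truth table is empty", call. = FALSE)
  if (term_size[1] > nrow(truth)) {
    stop("term_size lower bound exceeds the number of genes", call. = FALSE)
  }
  if (planted_odds_ratio <= 0) {
    stop("planted_odds_ratio must be positive", call. = FALSE)
  }
  set.seed(seed)
  genes <- truth$gene_id
  term_size[2] <- min(term_size[2], length(genes))
  if (n_terms == 0) {
    return(structure(setNames(list(), character(0)),
                     descriptions = character(0), class = "gene_sets"))
  }
  is_dv <- truth$class %in% c("dv", "mixed")
  sets <- vector("list", n_terms)
  sizes <- sample(seq(term_size[1], term_size[2]), n_terms, replace = TRUE)
  w <- ifelse(is_dv, planted_odds_ratio, 1)
  sets[[1]] <- sample(genes, sizes[1], prob = w)
  for (t in seq_len(n_terms)[-1]) sets[[t]] <- sample(genes, sizes[t])
  names(sets) <- c("TERM_PLANTED",
                   sprintf("TERM_%04d", seq_len(n_terms)[-1]))
  structure(sets,
            descriptions = setNames(
              c("planted differential-variability term",
                rep("random term", n_terms - 1)), names(sets)),
            class = "gene_sets")
}

#' Simulate a qPCR validation panel
#'
#' Emulates quantitative PCR re-measurement of selected genes on the same
#' samples. Values are reported as minus delta-Ct, defined as
#' `Ct_reference - Ct_target`, which increases with target expression and is
#' a surrogate for log2 expression: `-dCt = intercept + slope * log2expr +
#' Normal(0, noise_sd)` with `slope > 0`.
#'
#' @param matrix log2-scale [expression_matrix()] (one column per sample).
#' @param genes probe/gene ids to assay; must exist in `matrix`.
#' @param noise_sd SD of the qPCR measurement noise (Ct units).
#' @param seed integer RNG seed.
#' @param intercept,slope affine map from log2 expression to -dCt;
#'   `slope` must be positive.
#' @return Long-format data.frame: `sample_id`, `gene_id`, `neg_delta_ct`.
#' @export
simulate_qpcr_panel <- function(matrix, genes, noise_sd = 0.5, seed = 1L,
                                intercept = -10, slope = 1) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$scale != "log2") {
    stop("qPCR panel is simulated from log2 expression", call. = FALSE)
  }
  if (slope <= 0) stop("slope must be positive (-dCt increases with ",
                       "expression)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  miss <- setdiff(genes, probe_ids(matrix))
  if (length(miss)) {
    stop("gene(s) absent from the expression matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  expr <- matrix$values[genes, , drop = FALSE]
  noise <- matrix(rnorm(length(expr), sd = noise_sd), nrow(expr))
  ct <- intercept + slope * expr + noise
  data.frame(
    sample_id = rep(colnames(expr), each = length(genes)),
    gene_id = rep(genes, times = ncol(expr)),
    neg_delta_ct = as.vector(ct),
    stringsAsFactors = FALSE
  )
}
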