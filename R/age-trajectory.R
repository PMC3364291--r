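# internal: build the full and reduced design matrices for the quadratic
# age model. Age is centered before squaring (numerically kinder; the
# nested-model F is invariant to it).
trajectory_designs <- function(samples) {
  n <- nrow(samples)
  if (n < 6) stop("quadratic age model needs >= 6 subjects", call. = FALSE)
  age <- samples$age_years - mean(samples$age_years)
  sex <- as.numeric(samples$sex == "male")
  delay <- samples$dev_delay
  if (anyNA(delay)) {
    warning("missing dev_delay values imputed as FALSE", call. = FALSE)
    delay[is.na(delay)] <- FALSE
  }
  full <- cbind(intercept = 1, age = age, age2 = age^2, sex = sex,
                delay = as.numeric(delay))
  # constant nuisance covariates carry no information; drop them rather
  # than fail (a study with no delayed subjects is perfectly regular)
  const <- colnames(full)[-1][apply(full[, -1, drop = FALSE], 2, stats::var) == 0]
  nuisance_const <- intersect(const, c("sex", "delay"))
  if (length(nuisance_const)) {
    message("constant covariate(s) dropped from the age model: ",
            paste(nuisance_const, collapse = ", "))
    full <- full[, setdiff(colnames(full), nuisance_const), drop = FALSE]
  }
  reduced <- full[, setdiff(colnames(full), c("age", "age2")), drop = FALSE]
  qr_full <- qr(full)
  if (qr_full$rank < ncol(full)) {
    dropped <- colnames(full)[qr_full$pivot[(qr_full$rank + 1):ncol(full)]]
    stop("rank-deficient design: collinear column(s) ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  list(full = full, reduced = reduced, qr_full = qr_full,
       qr_reduced = qr(reduced), n = n)
}

# internal: vectorized nested-model F-test over the columns of Y (n x p)
trajectory_ftest <- function(Y, des) {
  n <- des$n
  res_f <- qr.resid(des$qr_full, Y)
  res_r <- qr.resid(des$qr_reduced, Y)
  sse_f <- colSums(res_f^2)
  sse_r <- colSums(res_r^2)
  df2 <- n - ncol(des$full)
  f <- ((sse_r - sse_f) / 2) / (sse_f / df2)
  p <- stats::pf(f, 2, df2, lower.tail = FALSE)
  # constant expression: both SSEs ~ 0, no age signal by convention
  flat <- sse_r < 1e-12 * pmax(colSums(Y^2), 1)
  p[flat] <- 1; f[flat] <- 0
  coefs <- qr.coef(des$qr_full, Y)
  list(F = f, p = p, df = c(2, df2), coef = coefs,
       sse_full = sse_f, sse_reduced = sse_r)
}

#' Quadratic age-trajectory F-test for one probe
#'
#' Fits the full linear model `expr ~ 1 + age + age^2 + sex + delay` and the
#' reduced model without the age terms, and tests the joint contribution of
#' age with the nested-model F-statistic
#' `F = ((SSE_red - SSE_full)/2) / (SSE_full/(n-5))` on `(2, n-5)` degrees of
#' freedom. Used to ask whether a variable gene is merely developmentally
#' regulated (a smooth function of age) rather than more variable in
#' childhood.
#'
#' @param expression numeric vector, one value per subject.
#' @param samples [sample_table()] in the same order.
#' @return list with `coefficients` (intercept, age, age2, sex, delay),
#'   `F`, `df`, and `p`.
#' @export
quadratic_age_ftest <- function(expression, samples) {
  if (length(expression) != nrow(samples)) {
    stop("expression length must match the sample table", call. = FALSE)
  }
  des <- trajectory_designs(samples)
  fit <- trajectory_ftest(cbind(expression), des)
  list(coefficients = setNames(as.numeric(fit$coef), colnames(des$full)),
       F = as.numeric(fit$F), df = fit$df, p = as.numeric(fit$p))
}

#' Screen probes for developmental (age-trajectory) regulation
#'
#' Applies the quadratic age F-test to each requested probe, adjusts the
#' p-values (Storey pFDR for the flag, BH alongside), and flags probes whose
#' expression tracks age at the given q cutoff. Probes failing to fit are
#' recorded with `NA` statistics rather than aborting the screen.
#'
#' @param matrix log2-scale subject-level [expression_matrix()].
#' @param samples matching [sample_table()].
#' @param probes probe ids to test; default all.
#' @param q_cutoff pFDR threshold for `developmentally_regulated`
#'   (default 0.25).
#' @return data.frame of class `"dv_trajectory"`: coefficients, `F_age`,
#'   `df_num`, `df_den`, `p_age`, `q_bh`, `q_pfdr`,
#'   `developmentally_regulated`.
#' @export
screen_age_regulated <- function(matrix, samples, probes = NULL,
                                 q_cutoff = 0.25) {
  stopifnot(inherits(matrix, "expr_matrix"))
  samples <- align_samples(matrix, samples)
  if (is.null(probes)) probes <- probe_ids(matrix)
  if (length(probes) == 0) {
    out <- data.frame(probe_id = character(0), intercept = numeric(0),
                      age = numeric(0), age2 = numeric(0), sex = numeric(0),
                      delay = numeric(0), F_age = numeric(0),
                      df_num = integer(0), df_den = integer(0),
                      p_age = numeric(0), q_bh = numeric(0),
                      q_pfdr = numeric(0),
                      developmentally_regulated = logical(0))
    class(out) <- c("dv_trajectory", "data.frame")
    return(out)
  }
  miss <- setdiff(probes, probe_ids(matrix))
  if (length(miss)) {
    stop("probe(s) not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  des <- trajectory_designs(samples)
  Y <- t(matrix$values[probes, , drop = FALSE])
  fit <- trajectory_ftest(Y, des)
  q_bh <- adjust_fdr(fit$p, "bh")
  q_pfdr <- as.numeric(adjust_fdr(fit$p, "storey"))
  cf <- matrix(NA_real_, length(probes), 5,
               dimnames = list(NULL, c("intercept", "age", "age2", "sex",
                                       "delay")))
  cf[, colnames(des$full)] <- t(fit$coef)
  out <- data.frame(
    probe_id = probes,
    intercept = cf[, 1], age = cf[, 2], age2 = cf[, 3], sex = cf[, 4],
    delay = cf[, 5],
    F_age = fit$F, df_num = fit$df[1], df_den = fit$df[2],
    p_age = fit$p, q_bh = q_bh, q_pfdr = q_pfdr,
    developmentally_regulated = q_pfdr < q_cutoff,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("dv_trajectory", "data.frame")
  attr(out, "q_cutoff") <- q_cutoff
  out
}
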