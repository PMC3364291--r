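# tiny in-code fixtures shared across tests

# probe x sample matrix with auto ids
make_mat <- function(values, nrow, scale = "log2", detection_p = NULL) {
  m <- matrix(values, nrow = nrow)
  rownames(m) <- sprintf("P%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("A%02d", seq_len(ncol(m)))
  if (!is.null(detection_p)) {
    detection_p <- matrix(detection_p, nrow = nrow,
                          dimnames = dimnames(m))
  }
  expression_matrix(m, scale = scale, detection_p = detection_p)
}

# one subject per sample unless subject_id given
make_samples <- function(ages, sex = NULL, subject_id = NULL,
                         dev_delay = FALSE) {
  n <- length(ages)
  sample_table(data.frame(
    sample_id = sprintf("A%02d", seq_len(n)),
    subject_id = if (is.null(subject_id)) sprintf("S%02d", seq_len(n))
                 else subject_id,
    age_years = ages,
    sex = if (is.null(sex)) rep("unknown", n) else sex,
    dev_delay = dev_delay,
    stringsAsFactors = FALSE
  ))
}

# ages giving n_young subjects < 15 and n_old >= 15
mixed_ages <- function(n_young, n_old) {
  c(seq(2, 14, length.out = n_young), seq(16, 50, length.out = n_old))
}

# brute-force one-sided signed-rank p over all 2^n sign patterns
# (average ranks on |d|, zeros removed by the caller)
enumerate_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mean(w_all >= w_obs)
}
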