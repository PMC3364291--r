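test_that("detection filter keeps probes detected in enough unique subjects", {
  det <- rbind(c(0.05, 0.05, 0.5, 0.5),
               c(0.2, 0.2, 0.2, 0.05),
               c(0.09, 0.10, 0.11, 0.12))
  m <- make_mat(seq_len(12), nrow = 3, scale = "raw", detection_p = det)
  s <- make_samples(c(5, 10, 20, 30))
  out <- filter_by_detection(m, s, p_threshold = 0.1, min_individuals = 2)
  expect_identical(rownames(out$values), c("P001", "P003"))

  all_zero <- make_mat(seq_len(12), nrow = 3, scale = "raw",
                       detection_p = rep(0, 12))
  expect_equal(nrow(filter_by_detection(all_zero, s, 0.1, 2)$values), 3)
})

test_that("detection counts subjects, not arrays, with any-replicate voting", {
  # subject S01 has two arrays; probe 1 detected on only one of them
  det <- rbind(c(0.05, 0.9, 0.9), c(0.05, 0.05, 0.9))
  m <- make_mat(seq_len(6), nrow = 2, scale = "raw", detection_p = det)
  s <- make_samples(c(5, 5, 20), subject_id = c("S01", "S01", "S02"))
  any_rule <- filter_by_detection(m, s, 0.1, min_individuals = 1)
  expect_identical(rownames(any_rule$values), c("P001", "P002"))
  # under all-replicate voting S01 no longer counts for probe 1,
  # leaving it with zero detected subjects
  all_rule <- filter_by_detection(m, s, 0.1, min_individuals = 1,
                                  replicate_rule = "all")
  expect_identical(rownames(all_rule$values), "P002")
  strict <- filter_by_detection(m, s, 0.1, min_individuals = 2,
                                replicate_rule = "all")
  expect_identical(nrow(strict$values), 0L)

  no_det <- make_mat(seq_len(6), nrow = 2, scale = "raw")
  expect_error(filter_by_detection(no_det, s, 0.1, 1), "skip")
})

test_that("offset-and-log2 shifts the global minimum to one", {
  m <- make_mat(c(-3, 1, 7, -3, 1, 7), nrow = 3, scale = "raw")
  out <- offset_and_log2(m)
  expect_equal(out$values[, 1], c(P001 = 0, P002 = log2(5), P003 = log2(11)))
  expect_equal(unname(out$values[, 1]), c(0, 2.321928, 3.459432),
               tolerance = 1e-6)
  expect_identical(out$scale, "log2")

  # minimum already 1: pure log2 (offset constant is 0)
  m1 <- make_mat(c(1, 2, 8, 16), nrow = 2, scale = "raw")
  expect_equal(offset_and_log2(m1)$values, log2(m1$values))

  # minimum above 1: the constant is negative, output min still exactly 0
  set.seed(42)
  m2 <- make_mat(runif(40, 5, 100), nrow = 10, scale = "raw")
  expect_identical(min(offset_and_log2(m2)$values), 0)
  expect_error(offset_and_log2(offset_and_log2(m2)), "log2")
})

test_that("quantile normalization matches the rank/mean construction", {
  m <- make_mat(c(2, 4, 6, 5, 3, 1), nrow = 3)
  out <- quantile_normalize(m)
  expect_equal(unname(out$values),
               cbind(c(1.5, 3.5, 5.5), c(5.5, 3.5, 1.5)))

  # tie rule: tied pair shares the mean of the reference values at its ranks
  mt <- make_mat(c(1, 1, 3, 2, 4, 6), nrow = 3)
  outt <- quantile_normalize(mt)
  expect_equal(unname(outt$values),
               cbind(c(2, 2, 4.5), c(1.5, 2.5, 4.5)))

  # identical columns are a fixed point
  mi <- make_mat(rep(c(1, 5, 9), 3), nrow = 3)
  expect_equal(quantile_normalize(mi)$values, mi$values)
})

test_that("quantile normalization is idempotent and equalizes column sums", {
  set.seed(7)
  m <- make_mat(rnorm(200), nrow = 50)
  once <- quantile_normalize(m)
  twice <- quantile_normalize(once)
  expect_equal(twice$values, once$values)
  sums <- colSums(once$values)
  expect_lt(diff(range(sums)), 1e-10)
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(8)
  m <- make_mat(rnorm(300), nrow = 60)
  ours <- quantile_normalize(m)$values
  ref <- limma::normalizeQuantiles(m$values)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("technical replicate averaging collapses arrays to subjects", {
  m <- make_mat(c(2, 4, 4, 6), nrow = 2)
  s <- make_samples(c(5, 5), subject_id = c("S01", "S01"))
  out <- average_technical_replicates(m, s)
  expect_equal(unname(out$matrix$values), cbind(c(3, 5)))
  expect_identical(colnames(out$matrix$values), "S01")
  expect_equal(nrow(out$samples), 1L)

  # no duplicated subjects: identity up to column keying
  m2 <- make_mat(seq_len(6), nrow = 2)
  s2 <- make_samples(c(5, 10, 20))
  out2 <- average_technical_replicates(m2, s2)
  expect_equal(unname(out2$matrix$values), unname(m2$values))

  # conflicting covariates are named
  s_bad <- make_samples(c(5, 9), subject_id = c("S01", "S01"))
  expect_error(average_technical_replicates(m, s_bad), "S01")
})

test_that("40 simulated arrays collapse to 37 unique subjects", {
  study <- simulate_expression_study(sim_config(n_probes = 50, seed = 4))
  expect_identical(ncol(study$matrix$values), 40L)
  out <- average_technical_replicates(study$matrix, study$samples)
  expect_identical(ncol(out$matrix$values), 37L)
})

test_that("group-mean adjustment zeroes every level mean", {
  m <- make_mat(c(1, 3, 2, 6), nrow = 1)
  s <- make_samples(c(5, 8, 10, 12), sex = c("male", "male", "female",
                                             "female"))
  out <- adjust_group_means(m, s, "sex")
  expect_equal(unname(out$values[1, ]), c(-1, 1, -2, 2))

  # all one level: row centering
  s_m <- make_samples(c(5, 8, 10, 12), sex = rep("male", 4))
  out_m <- adjust_group_means(m, s_m, "sex")
  expect_equal(unname(out_m$values[1, ]), unname(m$values[1, ] - 3))

  # defining property on random input, and within-level variances unchanged
  set.seed(9)
  mr <- make_mat(rnorm(80), nrow = 10)
  sr <- make_samples(mixed_ages(4, 4),
                     sex = rep(c("male", "female"), 4))
  outr <- adjust_group_means(mr, sr, "sex")
  for (l in c("male", "female")) {
    cols <- which(sr$sex == l)
    expect_lt(max(abs(rowMeans(outr$values[, cols]))), 1e-12)
    expect_equal(apply(outr$values[, cols], 1, var),
                 apply(mr$values[, cols], 1, var))
  }
})

test_that("preprocess_study runs the stages in order and records provenance", {
  study <- simulate_expression_study(sim_config(n_probes = 120, seed = 5))
  prep <- preprocess_study(study$matrix, study$samples)
  prov <- prep$matrix$provenance
  stages <- c("detection_filter", "offset", "quantile_normalize",
              "replicate_average", "adjust_group_means")
  idx <- vapply(stages, function(s) grep(s, prov)[1], numeric(1))
  expect_false(anyNA(idx))
  expect_true(all(diff(idx) > 0))
  expect_identical(prep$matrix$scale, "log2")
  expect_identical(ncol(prep$matrix$values), 37L)
})
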