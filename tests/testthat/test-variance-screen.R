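test_that("top-variance selection ranks by variance with lexicographic ties", {
  # per-row variances 10, 5, 5, 1 (up to a common factor)
  base <- c(-1, 0, 1)
  vals <- rbind(base * sqrt(10), base * sqrt(5), base * sqrt(5), base)
  dimnames(vals) <- list(sprintf("P%03d", 1:4), sprintf("A%02d", 1:3))
  m <- expression_matrix(vals, scale = "log2")
  expect_equal(unname(apply(vals, 1, var)), c(10, 5, 5, 1))
  got <- top_variance_subset(m, fraction = 0.5)
  expect_identical(got, c("P001", "P002"))  # P002 beats tied P003 by id

  expect_identical(top_variance_subset(m, fraction = 1),
                   c("P001", "P002", "P003", "P004"))

  const <- make_mat(rep(1, 12), nrow = 4)
  expect_error(top_variance_subset(const, 0.5), "constant")
})

test_that("explicit k overrides the fraction", {
  set.seed(1)
  m <- make_mat(rnorm(60), nrow = 20)
  expect_length(top_variance_subset(m, fraction = 0.05), 1L)
  expect_length(top_variance_subset(m, k = 7), 7L)
})

test_that("variance-ratio F-test matches closed forms", {
  # young {0,2,4} (var 4), old {0,1,2} (var 1): F = 4 on (2,2) df,
  # upper tail of F(2,2) at x is 1/(1+x) -> p = 0.2
  m <- make_mat(c(0, 2, 4, 0, 1, 2), nrow = 1)
  s <- make_samples(c(3, 7, 11, 20, 30, 40))
  fit <- variance_ratio_ftest(m, s)
  expect_equal(fit$table$F, 4)
  expect_identical(c(fit$table$df_num, fit$table$df_den), c(2L, 2L))
  expect_equal(fit$table$p_one_sided, 0.2)
  expect_equal(fit$table$var_ratio, fit$table$F)

  # identical data in both groups, equal sizes: F = 1, p = 0.5 exactly
  m2 <- make_mat(rep(c(1, 2, 3), 2), nrow = 1)
  fit2 <- variance_ratio_ftest(m2, s)
  expect_equal(fit2$table$F, 1)
  expect_equal(fit2$table$p_one_sided, 0.5)
})

test_that("degenerate variances follow the stated conventions", {
  s <- make_samples(c(3, 7, 11, 20, 30, 40))
  m <- expression_matrix(
    matrix(c(0, 2, 4, 1, 1, 1,   # old constant, young varying -> p = 0
             5, 5, 5, 5, 5, 5),  # both constant -> p = 1
           nrow = 2, byrow = TRUE,
           dimnames = list(c("P001", "P002"), sprintf("A%02d", 1:6))),
    scale = "log2")
  fit <- variance_ratio_ftest(m, s)
  expect_true(all(fit$table$degenerate))
  expect_equal(fit$table$p_one_sided, c(0, 1))
})

test_that("one-sided p matches the Monte-Carlo tail of the null ratio", {
  # shared-normal null with (29, 8) subjects: the variance ratio is
  # (chi2_28/28)/(chi2_7/7); compare tail frequencies with pf()
  set.seed(123)
  n_draws <- 2e5
  ratio <- (rchisq(n_draws, 28) / 28) / (rchisq(n_draws, 7) / 7)
  for (x in c(1.5, 3, 6)) {
    emp <- mean(ratio >= x)
    se <- sqrt(emp * (1 - emp) / n_draws)
    expect_lt(abs(emp - pf(x, 28, 7, lower.tail = FALSE)), 3 * se + 1e-12)
  }
})

test_that("swapped group labels satisfy the reciprocal-F relation", {
  set.seed(11)
  for (i in 1:5) {
    ny <- sample(3:10, 1); no <- sample(3:10, 1)
    m <- make_mat(rnorm(6 * (ny + no)), nrow = 6)
    ages <- mixed_ages(ny, no)
    fit <- variance_ratio_ftest(m, make_samples(ages))
    # swap: young become old and vice versa
    fit_sw <- variance_ratio_ftest(m, make_samples(ifelse(ages < 15, 20, 5)))
    # P(F_{a,b} >= x) = P(F_{b,a} <= 1/x)
    expect_equal(fit$table$p_one_sided, 1 - fit_sw$table$p_one_sided,
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04), "bh"), rep(0.04, 4))
  expect_equal(adjust_fdr(0.37, "bh"), 0.37)
  set.seed(2)
  p <- runif(50)^2
  q <- adjust_fdr(p, "bh")
  expect_true(all(q >= p))
  # thresholding q reproduces the step-up rejection set
  for (alpha in c(0.05, 0.2)) {
    ps <- sort(p)
    k <- which(ps <= alpha * seq_along(ps) / length(ps))
    rejected_stepup <- if (length(k)) p <= ps[max(k)] else rep(FALSE, 50)
    expect_identical(q <= alpha, rejected_stepup)
  }
  # q is monotone in p
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("Storey q-values follow the pi0 x BH construction", {
  p <- c(0.01, 0.02, 0.6, 0.8)
  # fixed lambda = 0.5: pi0 = #{p > 0.5} / (m * 0.5) = 2/(4*0.5) = 1
  q <- adjust_fdr(p, "storey", lambda = 0.5)
  expect_equal(attr(q, "pi0"), 1)
  expect_equal(as.numeric(q), c(0.04, 0.04, 0.8, 0.8))

  # smoothed pi0 stays in (0, 1] and scales BH
  set.seed(3)
  p2 <- c(runif(400), runif(100, 0, 0.01))
  q2 <- adjust_fdr(p2, "storey")
  pi0 <- attr(q2, "pi0")
  expect_gt(pi0, 0); expect_lte(pi0, 1)
  expect_equal(as.numeric(q2), pmin(1, pi0 * adjust_fdr(p2, "bh")))
  expect_length(adjust_fdr(numeric(0)), 0)
})

test_that("signed-rank p has the exact small-sample distribution", {
  # differences (1,2,3): only sign pattern (+,+,+) reaches W = 6 -> p = 1/8
  expect_equal(signed_rank_paired_sd(c(2, 3, 4), c(1, 1, 1)), 1 / 8)
  expect_equal(as.numeric(signed_rank_paired_sd(c(1, 2), c(1, 2))), 1)
  expect_match(attr(signed_rank_paired_sd(c(1, 2), c(1, 2)), "note"), "zero")
})

test_that("exact signed-rank p equals full 2^n enumeration", {
  set.seed(14)
  for (i in 1:6) {
    n <- sample(4:12, 1)
    d <- round(rnorm(n), 2)
    d <- d[d != 0]
    if (length(d) < 3 || any(duplicated(abs(d)))) next
    p_pkg <- signed_rank_paired_sd(d, rep(0, length(d)))
    expect_equal(as.numeric(p_pkg), enumerate_signed_rank(d))
  }
  # and agrees with the standard implementation on untied data
  set.seed(15)
  d <- rnorm(18)
  expect_equal(
    as.numeric(signed_rank_paired_sd(d, rep(0, 18))),
    wilcox.test(d, alternative = "greater")$p.value
  )
})

test_that("large-sample signed-rank approximation tracks the reference", {
  set.seed(16)
  d <- rnorm(60, mean = 0.3)
  p_pkg <- signed_rank_paired_sd(d, rep(0, 60))
  p_ref <- wilcox.test(d, alternative = "greater", exact = FALSE,
                       correct = TRUE)$p.value
  expect_equal(as.numeric(p_pkg), p_ref, tolerance = 1e-10)
  # tied case
  dt <- sample(c(-2, -1, 1, 2, 3), 40, replace = TRUE)
  p_pkg_t <- signed_rank_paired_sd(dt, rep(0, 40))
  p_ref_t <- suppressWarnings(
    wilcox.test(dt, alternative = "greater", exact = FALSE,
                correct = TRUE)$p.value)
  expect_equal(as.numeric(p_pkg_t), p_ref_t, tolerance = 1e-10)
})

test_that("proportion-greater counts strict exceedances only", {
  expect_equal(proportion_sd_greater(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(proportion_sd_greater(c(2, 1, 3), c(1, 2, 1)), 2 / 3)
  expect_error(proportion_sd_greater(numeric(0), numeric(0)), "nonempty")
})

test_that("q_bh dominates the one-sided p in screen output", {
  set.seed(17)
  m <- make_mat(rnorm(30 * 12), nrow = 30)
  fit <- variance_ratio_ftest(m, make_samples(mixed_ages(6, 6)))
  expect_true(all(fit$table$q_bh >= fit$table$p_one_sided))
})

test_that("permutation null machinery validates inputs and is reproducible", {
  set.seed(18)
  m <- make_mat(rnorm(50 * 10), nrow = 50)
  s <- make_samples(mixed_ages(5, 5))
  expect_error(permutation_null_proportion(m, s, n_perm = 0), "n_perm")
  a <- permutation_null_proportion(m, s, fraction = 1, n_perm = 25, seed = 9)
  b <- permutation_null_proportion(m, s, fraction = 1, n_perm = 25, seed = 9)
  expect_identical(a, b)
  expect_length(a$null, 25)
  expect_true(a$p_empirical > 0 && a$p_empirical <= 1)
})

test_that("dv_screen wires pre-filter, adjustment and FDR together", {
  study <- simulate_expression_study(sim_config(n_probes = 300, seed = 21))
  prep <- preprocess_study(study$matrix, study$samples, adjust_factor = NULL)
  fit <- suppressMessages(dv_screen(prep$matrix, prep$samples,
                                    top_fraction = 0.2))
  expect_s3_class(fit, "dv_screen")
  expect_equal(nrow(fit$table), round(0.2 * nrow(prep$matrix$values)))
  expect_identical(fit$n_young, 29L)
  expect_identical(fit$n_old, 8L)
  expect_true(all(fit$table$probe_id %in% fit$probe_universe))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.dv_screen")
  expect_output(print(sm), "SD greater in young")
  expect_identical(as.data.frame(fit), fit$table)
})
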