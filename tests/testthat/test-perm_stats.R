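make_tbl <- function(y_wide, factors = list(condition = NULL)) {
  n <- nrow(y_wide)
  labels <- colnames(y_wide)
  df <- data.frame(subject = rep(seq_len(n), times = ncol(y_wide)),
                   condition = rep(labels, each = n),
                   y = as.vector(y_wide))
  subject_condition_table(df, "y", "subject", "condition")
}

test_that("subject-condition tables demand a complete crossing", {
  df <- expand.grid(subject = 1:4, A = c("a", "b"))
  df$y <- rnorm(8)
  tbl <- subject_condition_table(df, "y", "subject", "A")
  expect_equal(dim(tbl$y), c(4, 2))
  expect_error(subject_condition_table(df[-1, ], "y", "subject", "A"),
               "incomplete")
  expect_error(subject_condition_table(df, "y", "subject", "missing_col"),
               "missing column")
})

test_that("repeated-measures ANOVA matches the general-linear-model oracle", {
  set.seed(31)
  d <- expand.grid(subject = factor(1:10), A = factor(c("a1", "a2")),
                   B = factor(c("b1", "b2", "b3")))
  d$y <- rnorm(nrow(d)) + 0.6 * (d$A == "a2") + 0.3 * as.numeric(d$B)
  tbl <- subject_condition_table(d, "y", "subject", c("A", "B"))
  res <- rm_anova(tbl)
  fit <- summary(stats::aov(y ~ A * B + Error(subject / (A * B)), data = d))
  pick <- function(stratum) unlist(fit[[stratum]][[1]][1, c("F value", "Df")])
  oracle <- rbind(A = pick("Error: subject:A"), B = pick("Error: subject:B"),
                  `A:B` = pick("Error: subject:A:B"))
  expect_equal(res$F, unname(oracle[, 1]), tolerance = 1e-8)
  expect_equal(res$df1, unname(oracle[, 2]))
  expect_equal(res$df2, res$df1 * 9)
  expect_true(all(res$pes >= 0 & res$pes <= 1))
})

test_that("two-condition ANOVA F equals the squared paired t", {
  set.seed(12)
  Y <- cbind(a = rnorm(9), b = rnorm(9, 0.4))
  res <- rm_anova(make_tbl(Y))
  tt <- paired_t(Y[, 1], Y[, 2])
  expect_equal(res$F, tt$t^2, tolerance = 1e-8)
  # degenerate table: no effect, no error variance
  flat <- rm_anova(make_tbl(cbind(a = rep(2, 5), b = rep(2, 5))))
  expect_equal(flat$F, 0)
  expect_equal(flat$pes, 0)
})

test_that("paired t and d_z follow their closed forms", {
  res <- paired_t(c(1, 1, 1, 2), rep(0, 4))
  expect_equal(res$t, 5)
  expect_equal(res$d_z, 2.5)
  expect_equal(res$df, 3L)
  set.seed(8)
  a <- rnorm(12); b <- rnorm(12)
  res2 <- paired_t(a, b)
  expect_equal(res2$d_z * sqrt(12), res2$t)
  oracle <- stats::t.test(a, b, paired = TRUE)
  expect_equal(res2$t, unname(oracle$statistic))
  expect_error(paired_t(a, a), "zero variance")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("permutation engine follows the counting rule and the seed", {
  const <- make_tbl(cbind(a = rep(1, 6), b = rep(1, 6)))
  stat_range <- function(tb) max(tb$y) - min(tb$y)
  res <- permutation_p(const, stat_range, seed = 5, n_iter = 200)
  expect_equal(res$p, 1.0)  # every shuffle reproduces the observed statistic
  # observed larger than any shuffle: statistic sensitive to column order
  Y <- cbind(a = 100 + (1:20), b = 1:20)
  stat_diff <- function(tb) mean(tb$y[, 1] - tb$y[, 2])
  res2 <- permutation_p(make_tbl(Y), stat_diff, seed = 5, n_iter = 500)
  expect_equal(res2$p, 0.0)
  expect_length(res2$null, 500)
  # determinism and RNG-state hygiene
  r1 <- permutation_p(make_tbl(Y), stat_diff, seed = 9, n_iter = 100)
  r2 <- permutation_p(make_tbl(Y), stat_diff, seed = 9, n_iter = 100)
  expect_identical(r1$null, r2$null)
  set.seed(77); before <- runif(1)
  set.seed(77); invisible(permutation_p(make_tbl(Y), stat_diff, 3, 50))
  expect_identical(runif(1), before)
  # add-one variant
  r3 <- permutation_p(const, stat_range, seed = 1, n_iter = 99, plus_one = TRUE)
  expect_equal(r3$p, 1.0)
})

test_that("vectorized paired-t permutation agrees with the generic engine", {
  set.seed(21)
  a <- rnorm(10, 0.8); b <- rnorm(10)
  fast <- perm_paired_t(a, b, seed = 13, n_iter = 2000)
  tbl <- make_tbl(cbind(a = a, b = b))
  generic <- permutation_p(tbl, function(tb) abs(paired_t(tb$y[, 1],
                                                          tb$y[, 2])$t),
                           seed = 13, n_iter = 2000)
  expect_equal(fast$observed, generic$observed)
  # same null distribution (different RNG streams): compare quantiles
  expect_equal(stats::quantile(fast$null, c(.5, .9, .95)),
               stats::quantile(generic$null, c(.5, .9, .95)), tolerance = 0.1)
  expect_lt(abs(fast$p - generic$p), 0.03)
  expect_identical(perm_paired_t(a, b, seed = 13, n_iter = 100)$null,
                   perm_paired_t(a, b, seed = 13, n_iter = 100)$null)
})

test_that("permuted omnibus ANOVA detects effects and keeps the null", {
  set.seed(44)
  d <- expand.grid(subject = factor(1:12), A = factor(c("a1", "a2", "a3")))
  d$null <- rnorm(nrow(d))
  d$eff <- d$null + 1.5 * (d$A == "a2")
  f_stat <- function(tb) rm_anova(tb)$F[1]
  tbl_null <- subject_condition_table(d, "null", "subject", "A")
  tbl_eff <- subject_condition_table(d, "eff", "subject", "A")
  p_eff <- permutation_p(tbl_eff, f_stat, seed = 2, n_iter = 500)$p
  p_null <- permutation_p(tbl_null, f_stat, seed = 2, n_iter = 500)$p
  expect_lt(p_eff, 0.05)
  expect_gt(p_null, 0.05)
})

test_that("BH control adjusts and rejects per the step-up rule", {
  expect_equal(fdr_bh(0.03)$adjusted, 0.03)
  same <- fdr_bh(rep(0.2, 5))
  expect_equal(same$adjusted, rep(0.2, 5))
  hand <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(hand$reject))   # max i with p_i <= i q / m is 4
  mixed <- fdr_bh(c(0.001, 0.02, 0.8), q = 0.05)
  expect_equal(mixed$reject, c(TRUE, TRUE, FALSE))
  # BH never rejects more than raw alpha thresholding at the same level
  set.seed(3)
  for (i in 1:10) {
    p <- runif(20)^2
    expect_lte(sum(fdr_bh(p, 0.05)$reject), sum(p <= 0.05))
  }
  expect_error(fdr_bh(c(0.2, 1.4)), "0, 1")
})

test_that("within-subject SEM removes subject offsets with Morey correction", {
  # additive subject offsets only: zero within-subject spread
  Y <- rbind(c(1, 2, 3), c(5, 6, 7), c(-2, -1, 0))
  df <- data.frame(subject = rep(1:3, 3), condition = rep(letters[1:3], each = 3),
                   y = as.vector(Y))
  sem <- within_subject_sem(subject_condition_table(df, "y", "subject",
                                                    "condition"))
  expect_equal(unname(sem), rep(0, 3))
  # hand-computed 3-subject x 2-condition table
  Y2 <- cbind(a = c(1, 2, 3), b = c(3, 3, 6))
  sem2 <- within_subject_sem(make_tbl(Y2))
  expect_equal(unname(sem2), rep(0.5 / sqrt(3) * sqrt(2), 2))
  expect_error(within_subject_sem(make_tbl(cbind(a = 1:3))), "2 cells")
})

test_that("noncentral-t sample size reproduces known working points", {
  expect_identical(paired_t_min_n(1.24, 0.05, 0.80, "one.sided"), 6L)
  expect_identical(paired_t_min_n(0.5, 0.05, 0.80, "two.sided"), 34L)
  # monotone power in n
  pow <- vapply(2:40, paired_t_power, numeric(1), d_z = 0.8)
  expect_true(all(diff(pow) > 0))
  expect_error(paired_t_min_n(-1), "d_z > 0")
})
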