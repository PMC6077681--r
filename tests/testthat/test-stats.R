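test_that("repeated-measures ANOVA matches the paired t-test for two levels", {
  set.seed(31)
  for (n in c(3, 8, 30)) {
    m <- cbind(rnorm(n, 10, 2), rnorm(n, 11, 2))
    res <- rm_anova(m)
    tt <- t.test(m[, 1], m[, 2], paired = TRUE)
    expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
  }
})

test_that("repeated-measures ANOVA agrees with aov's within-subject stratum", {
  set.seed(32)
  n <- 12; k <- 4
  m <- matrix(rnorm(n * k, 20, 3), n, k) + rnorm(n, 0, 2)
  res <- rm_anova(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   cond = factor(rep(seq_len(k), each = n)))
  a <- summary(aov(y ~ cond + Error(subj / cond), data = df))
  tab <- a[["Error: subj:cond"]][[1]]
  expect_equal(res$statistic, tab["cond", "F value"], tolerance = 1e-9)
  expect_equal(res$p_value, tab["cond", "Pr(>F)"], tolerance = 1e-9)
})

test_that("degenerate repeated-measures inputs are flagged, not mangled", {
  m <- matrix(rnorm(12), 4, 3)
  same <- m[, c(1, 1, 1)]
  res <- rm_anova(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  shift <- cbind(m[, 1], m[, 1] + 1, m[, 1] + 2)  # no error variance
  res2 <- rm_anova(shift)
  expect_equal(res2$statistic, Inf)
  expect_equal(res2$p_value, 0)
  expect_true(res2$degenerate)
  expect_error(rm_anova(m[1:2, ]), ">= 3 subjects")
})

test_that("the subject effect is removed exactly", {
  set.seed(33)
  m <- matrix(rnorm(40), 10, 4)
  res1 <- rm_anova(m)
  res2 <- rm_anova(m + rnorm(10, sd = 50))  # per-subject constants
  expect_equal(res2$statistic, res1$statistic, tolerance = 1e-9)
})

test_that("Bonferroni pairwise tests cover every pair with the family-size correction", {
  set.seed(34)
  m <- matrix(rnorm(40, 30, 4), 10, 4)
  pw <- bonferroni_pairs(m)
  expect_length(pw, 6L)  # four flexion levels -> six comparisons
  expect_length(bonferroni_pairs(m[, 1:3]), 3L)  # three drill angles -> three
  for (x in pw) {
    expect_gte(x$adjusted_p, x$p_value)
    expect_equal(x$adjusted_p, min(1, x$p_value * 6), tolerance = 1e-12)
  }
  same <- m[, c(1, 1, 1)]
  expect_true(all(vapply(bonferroni_pairs(same),
                         function(x) x$adjusted_p, numeric(1)) == 1))
})

test_that("Cochran's Q reduces to McNemar's chi-square for two levels", {
  set.seed(35)
  for (rep in 1:5) {
    x <- matrix(rbinom(40, 1, 0.4), 20, 2)
    if (sum(x[, 1] != x[, 2]) == 0) next
    q <- cochran_q(x)
    mc <- mcnemar.test(table(factor(x[, 1], 0:1), factor(x[, 2], 0:1)),
                       correct = FALSE)
    expect_equal(q$statistic, unname(mc$statistic), tolerance = 1e-9)
    expect_equal(q$p_value, mc$p.value, tolerance = 1e-9)
  }
})

test_that("Cochran's Q is invariant to subject relabelling and handles degeneracy", {
  set.seed(36)
  x <- matrix(rbinom(36, 1, 0.5), 12, 3)
  q1 <- cochran_q(x)
  q2 <- cochran_q(x[sample(nrow(x)), ])
  expect_identical(q1$statistic, q2$statistic)
  expect_identical(cochran_q(x[, c(1, 1, 1)])$p_value, 1)
  allsame <- matrix(rep(c(0, 1), each = 3), 2, 3, byrow = TRUE)
  res <- cochran_q(rbind(allsame, allsame))
  expect_true(res$degenerate)
  expect_equal(res$statistic, 0)
})

test_that("all p-values are probabilities and adjusted never below raw", {
  set.seed(37)
  for (i in 1:10) {
    m <- matrix(rnorm(24, 10), 8, 3)
    res <- rm_anova(m)
    expect_true(res$p_value >= 0 && res$p_value <= 1)
    for (x in bonferroni_pairs(m)) {
      expect_true(x$p_value >= 0 && x$p_value <= 1)
      expect_true(x$adjusted_p >= x$p_value && x$adjusted_p <= 1)
    }
  }
})
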