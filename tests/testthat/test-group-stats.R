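test_that("exact Wilcoxon p agrees with full sign enumeration", {
  # all-positive differences, n = 10: p = 2/1024
  w <- wilcoxon_signed_rank(1:10, rep(0, 10))
  expect_equal(w$p_value, 2 / 1024, tolerance = 1e-12)
  expect_equal(w$statistic, 0)
  expect_identical(w$method, "exact")

  # x = y: all zero differences
  wz <- wilcoxon_signed_rank(rep(1, 5), rep(1, 5))
  expect_equal(wz$p_value, 1)
  expect_true(wz$all_zero)

  # 200 random paired samples (n <= 12, including ties and zeros)
  set.seed(55)
  for (i in seq_len(200)) {
    n <- sample(3:12, 1)
    x <- round(rnorm(n), sample(0:1, 1))   # rounding induces ties/zeros
    y <- round(rnorm(n), 1)
    mine <- wilcoxon_signed_rank(x, y)
    ora <- oracle_wilcoxon(x, y)
    expect_equal(mine$statistic, ora$W)
    expect_equal(mine$p_value, ora$p, tolerance = 1e-12)
  }

  # cross-check against stats::wilcox.test on tie-free data
  set.seed(56)
  x <- rnorm(12); y <- rnorm(12)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value, ref$p.value,
               tolerance = 1e-12)

  # large-n branch: close to the reference normal approximation
  set.seed(57)
  x <- rnorm(40); y <- rnorm(40, 0.4)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value, ref$p.value,
               tolerance = 1e-6)
})

test_that("group accuracy-vs-null tests behave at the degenerate points", {
  rec <- function(acc, null_mean) list(
    result = list(mean_accuracy = acc),
    null = list(mean_accuracy = null_mean))
  # all subjects at their null mean: p = 1
  res <- test_accuracy_vs_null(lapply(rep(50, 6), function(v) rec(v, v)))
  expect_equal(res$p_uncorrected, 1)
  # clear separation: small exact p
  res2 <- test_accuracy_vs_null(lapply(1:10, function(i)
    rec(60 + i / 10, 50)))
  expect_equal(res2$p_uncorrected, 2 / 1024, tolerance = 1e-12)
  expect_error(test_accuracy_vs_null(list(rec(1, 1))), "2 subjects")
})

test_that("session-difference group test is sign-symmetric", {
  set.seed(60)
  diffs <- lapply(1:8, function(i)
    list(accuracy_diff = rnorm(1, 3), null_mean_diff = rnorm(1, 0, 0.3)))
  p1 <- test_session_difference_group(diffs)$p_uncorrected
  flipped <- lapply(diffs, function(d)
    list(accuracy_diff = -d$accuracy_diff,
         null_mean_diff = -d$null_mean_diff))
  p2 <- test_session_difference_group(flipped)$p_uncorrected
  expect_equal(p1, p2, tolerance = 1e-12)
  # identical sessions: p = 1
  zero <- lapply(1:5, function(i)
    list(accuracy_diff = 0, null_mean_diff = 0))
  expect_equal(test_session_difference_group(zero)$p_uncorrected, 1)
})

test_that("BH-FDR matches the step-up oracle and is monotone", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06)
  out <- fdr_correct(p, q = 0.05)
  expect_equal(out$p_adjusted, oracle_bh(p), tolerance = 1e-12)
  expect_identical(out$significant, oracle_bh(p) < 0.05)
  # adjusted values respect the raw ordering
  expect_true(all(diff(out$p_adjusted[order(p)]) >= -1e-12))
  # single p unchanged; all-ones give no flags
  expect_equal(fdr_correct(0.3)$p_adjusted, 0.3)
  expect_false(any(fdr_correct(rep(1, 4))$significant))
  # random vectors against the oracle
  set.seed(61)
  for (i in 1:20) {
    pr <- runif(sample(2:15, 1))
    expect_equal(fdr_correct(pr)$p_adjusted, oracle_bh(pr),
                 tolerance = 1e-12)
  }
})

test_that("interaction F matches aov and hand decomposition", {
  # random tables vs the aov within-subject stratum
  set.seed(62)
  for (i in 1:5) {
    tab <- array(rnorm(8 * 2 * 3, sd = 2), c(8, 2, 3))
    expect_equal(rm_anova_interaction_F(tab),
                 oracle_interaction_F_aov(tab), tolerance = 1e-8)
  }
  # 3-subject hand-computable table
  tab3 <- array(c(1, 2, 3,  2, 3, 4,    # A1: B1, A1: B2 ...
                  2, 4, 3,  1, 5, 6,
                  0, 1, 2,  3, 2, 4), c(3, 2, 3))
  expect_equal(rm_anova_interaction_F(tab3),
               oracle_interaction_F_aov(tab3), tolerance = 1e-8)
  # additive table (no interaction): F collapses to ~0
  subj <- rnorm(6); aeff <- c(0, 1); beff <- c(0, 2, 5)
  tab_add <- array(0, c(6, 2, 3))
  for (i in 1:2) for (j in 1:3)
    tab_add[, i, j] <- subj + aeff[i] + beff[j]
  expect_lt(rm_anova_interaction_F(tab_add), 1e-6)
  # location invariance
  set.seed(63)
  tab <- array(rnorm(10 * 2 * 3), c(10, 2, 3))
  expect_equal(rm_anova_interaction_F(tab),
               rm_anova_interaction_F(tab + 7), tolerance = 1e-8)
  expect_error(rm_anova_interaction_F(array(c(NA, rnorm(11)), c(2, 2, 3))),
               "missing")
})

test_that("permutation interaction test is seeded and relabel-invariant", {
  set.seed(64)
  tab <- array(rnorm(10 * 2 * 3), c(10, 2, 3))
  r1 <- permutation_interaction_test(tab, n_perm = 10, seed = 5)
  r2 <- permutation_interaction_test(tab, n_perm = 10, seed = 5)
  expect_identical(r1$f_null, r2$f_null)
  expect_equal(r1$p_perm, (1 + sum(r1$f_null >= r1$f_observed)) / 11)
  # relabeling factor levels leaves p unchanged
  tab_swapA <- tab[, c(2, 1), ]
  tab_permB <- tab[, , c(3, 1, 2)]
  r3 <- permutation_interaction_test(tab_swapA, n_perm = 200, seed = 5)
  r4 <- permutation_interaction_test(tab_permB, n_perm = 200, seed = 5)
  r0 <- permutation_interaction_test(tab, n_perm = 200, seed = 5)
  expect_equal(r3$f_observed, r0$f_observed, tolerance = 1e-10)
  expect_equal(r4$f_observed, r0$f_observed, tolerance = 1e-10)
})

test_that("a strong crossover interaction is detected with high power", {
  set.seed(65)
  hits <- vapply(seq_len(60), function(i) {
    tab <- array(rnorm(10 * 2 * 3, sd = 0.5), c(10, 2, 3))
    tab[, 1, 1] <- tab[, 1, 1] + 2   # crossover: cell-specific shifts
    tab[, 2, 2] <- tab[, 2, 2] + 2
    permutation_interaction_test(tab, n_perm = 500,
                                 seed = 1000 + i)$p_perm <= 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
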