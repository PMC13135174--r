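# Rank tests and DeLong machinery: worked examples, oracle agreement,
# Monte-Carlo calibration.

test_that("Shapiro gate is powered and calibrated", {
  set.seed(31)
  rej_unif <- mean(replicate(200, shapiro_gate(stats::runif(500))$p_value < 0.05))
  expect_gte(rej_unif, 0.95)
  rej_norm <- mean(replicate(200, shapiro_gate(stats::rnorm(500))$p_value < 0.05))
  expect_lt(abs(rej_norm - 0.05), 0.03)
  expect_error(shapiro_gate(rep(1, 10)), "constant")
  expect_error(shapiro_gate(1:2), "3 <= n")
})

test_that("Mann-Whitney U: exact enumeration and approximation", {
  r <- mann_whitney_u(1:3, 4:6)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)

  same <- mann_whitney_u(1:10, 1:10)
  expect_gte(same$p_value, 0.95)

  # agreement with the vetted base implementation (normal approx, ties)
  set.seed(32)
  x <- round(stats::rnorm(40), 1); y <- round(stats::rnorm(35, 0.3), 1)
  mine <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney type-I error is calibrated at 0.05", {
  set.seed(33)
  n_rep <- 1e4
  xm <- matrix(stats::rnorm(30 * n_rep), nrow = 30)
  ym <- matrix(stats::rnorm(30 * n_rep), nrow = 30)
  p <- vapply(seq_len(n_rep), function(i) mann_whitney_u(xm[, i], ym[, i])$p_value,
              numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("Kruskal-Wallis matches its rank formula and the two-group case", {
  r <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(r$statistic, 7.2)
  expect_equal(kruskal_wallis(list(rep(2, 4), rep(2, 5)))$statistic, 0)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")

  set.seed(34)
  x <- stats::rnorm(20); y <- stats::rnorm(20, 0.5)
  kw <- kruskal_wallis(list(x, y))
  mw <- mann_whitney_u(x, y)
  expect_lt(abs(kw$p_value - mw$p_value), 0.01)

  # vetted-oracle agreement with ties
  g <- list(round(stats::rnorm(15), 1), round(stats::rnorm(12), 1),
            round(stats::rnorm(18, 0.4), 1))
  ref <- stats::kruskal.test(g)
  mine <- kruskal_wallis(g)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("rank tests are invariant to monotone transforms", {
  set.seed(35)
  x <- stats::rexp(25); y <- stats::rexp(30, 0.7)
  expect_equal(mann_whitney_u(x, y)$p_value, mann_whitney_u(log(x), log(y))$p_value)
  expect_equal(kruskal_wallis(list(x, y))$statistic,
               kruskal_wallis(list(exp(x), exp(y)))$statistic)
})

test_that("DeLong: self-comparison, U identity, and confidence interval", {
  set.seed(36)
  labels <- rep(c(TRUE, FALSE), each = 30)
  s <- stats::rnorm(60) + labels
  same <- delong_auc_test(s, s, labels)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # AUC equals U / (n1 n2)
  u <- mann_whitney_u(s[labels], s[!labels])$statistic
  expect_equal(same$auc_a, u / (30 * 30), tolerance = 1e-12)
  expect_equal(rank_auc(s, labels), u / (30 * 30), tolerance = 1e-12)

  expect_equal(rank_auc(rep(0, 20), rep(c(TRUE, FALSE), 10)), 0.5)

  ci <- delong_auc_ci(s, labels)
  expect_true(ci$lower <= ci$auc && ci$auc <= ci$upper)
  perfect <- delong_auc_ci(as.numeric(labels), labels)
  expect_equal(perfect$auc, 1)
  expect_error(delong_auc_test(s, s, rep(TRUE, 60)), "both classes")
})

test_that("DeLong type-I error is calibrated", {
  set.seed(37)
  n_sim <- 2000
  rej <- vapply(seq_len(n_sim), function(i) {
    labels <- rep(c(TRUE, FALSE), each = 50)
    base <- stats::rnorm(100) + 0.8 * labels
    a <- base + stats::rnorm(100, sd = 0.6)
    b <- base + stats::rnorm(100, sd = 0.6)
    delong_auc_test(a, b, labels)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})
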