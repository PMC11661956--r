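test_that("the test-selection gates route data to the right test", {
  set.seed(33)
  # clean normal data, equal variances -> Student t
  x <- qnorm(ppoints(30))
  y <- qnorm(ppoints(30)) + 0.2
  res <- choose_and_run_test(x, y)
  expect_equal(res$test, "student-t")
  dec <- attr(res, "decision")
  expect_gte(min(dec$shapiro_x, dec$shapiro_y), 0.05)
  # strongly skewed data -> Mann-Whitney
  xs <- rexp(40)^2
  ys <- rexp(40)^2 + 1
  res2 <- choose_and_run_test(xs, ys)
  expect_equal(res2$test, "mann-whitney")
  # normal but heteroscedastic -> Welch
  res3 <- choose_and_run_test(qnorm(ppoints(40)), 6 * qnorm(ppoints(40)))
  expect_equal(res3$test, "welch-t")
  # identical samples: zero statistic, p near 1
  res4 <- choose_and_run_test(x, x)
  expect_equal(res4$statistic, 0, tolerance = 1e-12)
  expect_equal(res4$p, 1, tolerance = 1e-10)
  expect_error(choose_and_run_test(rep(1, 5), rep(1, 5)), "constant")
  expect_error(choose_and_run_test(1:2, 1:5), "at least 3")
})

test_that("the categorical branch runs an uncorrected chi-square", {
  m <- matrix(c(58, 37, 38, 19), 2, 2)
  res <- choose_and_run_test(m)
  expect_equal(res$test, "chi-square")
  expect_equal(res$statistic,
               unname(chisq.test(m, correct = FALSE)$statistic))
  f1 <- factor(rep(c("a", "b"), c(30, 20)))
  f2 <- factor(rep(c("x", "y", "x"), c(20, 20, 10)))
  res2 <- choose_and_run_test(f1, f2)
  expect_equal(res2$df, 1)
})

test_that("summary-based t-tests match tests on data with those exact summaries", {
  set.seed(34)
  make_data <- function(m, s, n) {
    x <- rnorm(n)
    m + s * (x - mean(x)) / sd(x)
  }
  x <- make_data(5.78, 0.96, 96)
  y <- make_data(5.09, 0.69, 56)
  ours_w <- summary_stat_tests(5.78, 0.96, 96, 5.09, 0.69, 56, "welch")
  ref_w <- t.test(x, y)
  expect_equal(ours_w$statistic, unname(ref_w$statistic), tolerance = 1e-10)
  expect_equal(ours_w$df, unname(ref_w$parameter), tolerance = 1e-10)
  expect_equal(ours_w$p, ref_w$p.value, tolerance = 1e-10)
  ours_s <- summary_stat_tests(5.78, 0.96, 96, 5.09, 0.69, 56, "student")
  ref_s <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours_s$statistic, unname(ref_s$statistic), tolerance = 1e-10)
  # equal means give t = 0; doubling both n scales |t| by sqrt(2)
  expect_equal(summary_stat_tests(3, 1, 20, 3, 1, 20)$statistic, 0)
  t1 <- summary_stat_tests(3.2, 1, 20, 3.0, 1, 30)$statistic
  t2 <- summary_stat_tests(3.2, 1, 40, 3.0, 1, 60)$statistic
  expect_equal(t2 / t1, sqrt(2), tolerance = 1e-12)
})

test_that("Box-Cox transform closed forms and the Shapiro gate", {
  x <- c(0.5, 1, exp(1), 4, 9)
  expect_equal(boxcox_transform(x, 1), x - 1)
  expect_equal(boxcox_transform(exp(1), 0), 1)
  expect_error(boxcox_transform(c(-1, 2), 0.5), "positive")
  # a clean normal sample passes the gate untouched
  set.seed(35)
  xn <- qnorm(ppoints(50))
  res <- boxcox_if_nonnormal(xn)
  expect_true(is.na(res$lambda))
  expect_identical(res$transformed, xn)
  expect_error(boxcox_if_nonnormal(rep(1, 20)), "zero-variance")
  expect_error(boxcox_if_nonnormal(rnorm(5)), "at least 8")
})

test_that("Box-Cox normalizes lognormal samples in most replicates", {
  set.seed(36)
  wins <- 0
  lambdas <- numeric(10)
  for (i in 1:10) {
    x <- rlnorm(200)
    res <- boxcox_if_nonnormal(x)
    lambdas[i] <- res$lambda
    wins <- wins + (res$shapiro_after > 0.05)
    expect_gt(cor(res$transformed, x, method = "spearman"), 0.999)
  }
  expect_gte(wins, 9)
  expect_lt(max(abs(lambdas)), 0.25)  # lognormal truth has lambda = 0
})

test_that("Box-Cox shifts non-positive data by 1 - min before transforming", {
  set.seed(37)
  x <- rlnorm(100) - 2
  res <- boxcox_if_nonnormal(x)
  expect_equal(res$shift, 1 - min(x))
  expect_false(is.na(res$lambda))
  expect_true(all(diff(res$transformed[order(x)]) >= 0))  # monotone
})

test_that("partial correlation reduces to plain correlation for orthogonal nuisance", {
  set.seed(38)
  n <- 100
  x <- rnorm(n)
  y <- rnorm(n)
  Q <- qr.Q(qr(cbind(1, x, y, rnorm(n))))[, 4]  # orthogonal to x, y, 1
  plain <- cor(x, y)
  pc <- partial_correlation(x, y, Q)
  expect_equal(pc$r, plain, tolerance = 1e-10)
  expect_equal(pc$df, n - 3)
  # nuisance identical to y: flagged as collinear
  expect_error(partial_correlation(x, y, y), "collinear")
  expect_error(partial_correlation(rnorm(4), rnorm(4), cbind(rnorm(4), rnorm(4))),
               "n >")
})

test_that("partial correlation recovers a planted negative coupling", {
  set.seed(39)
  signs <- replicate(40, {
    n <- 96
    nuis <- rnorm(n)
    x <- rnorm(n)
    y <- -0.5 * x + nuis + rnorm(n)
    sign(partial_correlation(x, y, nuis)$r)
  })
  expect_gte(mean(signs == -1), 0.95)
  # spearman flavor is rank-based hence monotone-invariant in x
  set.seed(40)
  n <- 60
  x <- rexp(n)
  y <- -x + rnorm(n, sd = 0.3)
  nuis <- rnorm(n)
  expect_equal(partial_correlation(exp(x), y, nuis, "spearman")$r,
               partial_correlation(x, y, nuis, "spearman")$r)
})

test_that("DAP correction interpolates between no correction and Sidak", {
  R1 <- matrix(1, 4, 4)
  out1 <- dap_bonferroni(rep(0.05, 4), R1)
  expect_equal(out1$p_corrected, rep(0.05, 4), tolerance = 1e-12)
  R0 <- diag(4)
  out0 <- dap_bonferroni(rep(0.05, 4), R0)
  expect_equal(out0$p_corrected, rep(1 - 0.95^4, 4), tolerance = 1e-12)
  expect_equal(out0$p_corrected[1], 0.18549375, tolerance = 1e-8)
  Rh <- matrix(0.5, 4, 4)
  diag(Rh) <- 1
  outh <- dap_bonferroni(rep(0.05, 4), Rh)
  expect_equal(outh$m_eff, rep(2, 4))
  expect_equal(outh$p_corrected, rep(1 - 0.95^2, 4), tolerance = 1e-12)
  expect_equal(outh$p_corrected[1], 0.0975, tolerance = 1e-10)
  # bounded between raw p and Sidak for random correlation structures
  set.seed(41)
  for (i in 1:20) {
    m <- sample(2:8, 1)
    A <- matrix(rnorm(m * m), m)
    R <- cov2cor(crossprod(A) + diag(m))
    p <- runif(m)
    out <- dap_bonferroni(p, R)
    expect_true(all(out$p_corrected >= p - 1e-12))
    expect_true(all(out$p_corrected <= 1 - (1 - p)^m + 1e-12))
    expect_true(all(out$m_eff >= 1 & out$m_eff <= m))
  }
  expect_equal(dap_bonferroni(0.03, matrix(1, 1, 1))$p_corrected, 0.03)
})

test_that("BH and Bonferroni corrections behave classically", {
  bh <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(bh$reject))
  expect_false(any(bh_fdr(rep(1, 5))$reject))
  expect_equal(bh_fdr(0.03)$adjusted, 0.03)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bonferroni_fwe(rep(0.004, 10))[1], 0.04)
  expect_equal(bonferroni_fwe(0.2), 0.2)
  p <- runif(7)
  expect_true(all(bonferroni_fwe(p) >= p))
})

test_that("type-I error of the selected test sits at the nominal level", {
  set.seed(43)
  rejections <- replicate(400, {
    x <- rnorm(25)
    y <- rnorm(25)
    choose_and_run_test(x, y)$p < 0.05
  })
  rate <- mean(rejections)
  half <- 3 * sqrt(0.05 * 0.95 / 400)
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
})

test_that("brain-behavior wrapper combines partial correlations with DAP", {
  set.seed(44)
  n <- 80
  dyn <- matrix(rnorm(n * 3), n, 3)
  dyn[, 2] <- dyn[, 1] + rnorm(n, sd = 0.4)
  dyn[, 3] <- dyn[, 1] + rnorm(n, sd = 0.4)
  colnames(dyn) <- c("n_changes", "total_distance", "span")
  dose <- rexp(n)
  score <- 15 - 0.8 * dyn[, 1] + 0.3 * dose + rnorm(n, sd = 0.6)
  res <- brain_behavior_correlations(score, dyn, nuisance = dose)
  expect_equal(res$metric, colnames(dyn))
  expect_true(all(res$p_corrected >= res$p))
  expect_equal(res$direction[1], "negative")
  expect_lt(res$p_corrected[1], 0.05)
})
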