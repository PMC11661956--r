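test_that("window count formula is exact for random geometries", {
  set.seed(14)
  for (i in 1:100) {
    T <- sample(31:500, 1)
    W <- sample(2:30, 1)
    step <- sample(1:7, 1)
    # brute-force enumeration of fitting start positions
    brute <- sum(vapply(0:T, function(s) s %% step == 0 && s + W <= T,
                        logical(1)))
    expect_identical(n_windows(T, W, step), as.integer(brute))
  }
  expect_identical(n_windows(400, 30, 1), 371L)
  expect_error(n_windows(20, 30), "exceeds")
})

test_that("the taper is a normalized, symmetric, center-peaked boxcar-Gaussian", {
  w <- make_taper(30, 3, 400)
  expect_equal(sum(w), 1)
  expect_equal(w, rev(w), tolerance = 1e-12)
  expect_equal(which.max(w), 15L, tolerance = 1)
  expect_true(all(diff(w[1:15]) >= -1e-15))
  # delta-kernel limit: uniform weights
  w0 <- make_taper(20, 1e-4)
  expect_equal(w0, rep(1 / 20, 20), tolerance = 1e-12)
  expect_error(make_taper(50, 3, 40), "exceeds")
})

test_that("windowed covariance reduces to the sample covariance under uniform weights", {
  set.seed(15)
  X <- matrix(rnorm(60 * 4), 60, 4)
  wc <- windowed_covariance(X, width = 20, step = 5,
                            weights = rep(1 / 20, 20))
  expect_equal(length(wc$cov), n_windows(60, 20, 5))
  expect_equal(wc$starts[1:3], c(0, 5, 10))
  w1 <- X[1:20, ]
  expect_equal(wc$cov[[1]], crossprod(scale(w1, scale = FALSE)) / 20,
               tolerance = 1e-12)
  # PSD and symmetric for tapered weights
  wc2 <- windowed_covariance(X, 20, 5)
  for (S in wc2$cov) {
    expect_equal(S, t(S))
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
  # constant component: zero variance row/column
  X[, 2] <- 1
  wc3 <- windowed_covariance(X, 20, 5, rep(1 / 20, 20))
  expect_equal(wc3$cov[[1]][2, ], rep(0, 4))
})

test_that("graphical lasso reproduces an independently computed sparse fit", {
  # fixture: correlation of an AR-structured 5-variate sample; expected
  # values computed with scikit-learn graphical_lasso (alpha = 0.1) and
  # frozen here
  set.seed(42)
  Sigma <- matrix(c(1, .5, .2, 0, 0, .5, 1, .3, 0, 0, .2, .3, 1, .1, 0,
                    0, 0, .1, 1, .4, 0, 0, 0, .4, 1), 5, 5)
  X <- matrix(rnorm(200 * 5), 200, 5) %*% chol(Sigma)
  S <- cor(X)
  fit <- glasso_regularize(S, 0.1, glasso_params(tol = 1e-6))
  expected_w12 <- c(0.358145, 0.069634, 0.194431, 0.275882)
  expect_equal(fit$correlation[cbind(c(1, 1, 2, 4), c(2, 3, 3, 5))],
               expected_w12, tolerance = 1e-4)
  expect_equal(fit$correlation[1, 4], 0, tolerance = 1e-4)
  expect_equal(fit$correlation[3, 5], 0, tolerance = 1e-4)
  expected_prec <- c(1.147141, -0.410842, 1.186429, -0.202070, 1.039289)
  expect_equal(fit$precision[cbind(c(1, 1, 2, 2, 3), c(1, 2, 2, 3, 3))],
               expected_prec, tolerance = 1e-3)
  expect_gt(min(eigen(fit$precision, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("penalty 0 returns the weighted sample correlation", {
  set.seed(16)
  X <- matrix(rnorm(80 * 5), 80, 5)
  wc <- windowed_covariance(X, 40, 10)
  R <- dynconn:::safe_cov2cor(wc$cov[[1]])
  fit <- glasso_regularize(wc$cov[[1]], 0, glasso_params(tol = 1e-7))
  expect_lt(max(abs(fit$correlation - R)), 1e-4)
})

test_that("increasing penalty monotonically shrinks the precision off-diagonal", {
  set.seed(17)
  X <- matrix(rnorm(60 * 6), 60, 6) %*%
    chol(make_planted_states(1, 6, within = 0.5, between = 0.2)$states[[1]])
  S <- cov(X)
  m <- vapply(c(0.01, 0.05, 0.1, 0.3, 0.6), function(p) {
    Th <- glasso_regularize(S, p)$precision
    mean(abs(Th[upper.tri(Th)]))
  }, numeric(1))
  expect_true(all(diff(m) <= 1e-8))
})

test_that("a diagonal truth is recovered as near-diagonal under a strong penalty", {
  set.seed(18)
  X <- matrix(rnorm(500 * 5), 500, 5)
  fit <- glasso_regularize(cov(X), 0.5)
  off <- fit$correlation[upper.tri(fit$correlation)]
  expect_lt(max(abs(off)), 0.01)
})

test_that("penalty selection is seeded and honors a fixed grid", {
  set.seed(19)
  X <- matrix(rnorm(150 * 5), 150, 5)
  wc <- windowed_covariance(X, 30, 5)
  p1 <- select_glasso_penalty(wc$cov, glasso_params(), seed = 5)
  p2 <- select_glasso_penalty(wc$cov, glasso_params(), seed = 5)
  expect_identical(p1$penalty, p2$penalty)
  expect_identical(p1$loglik, p2$loglik)
  fixed <- select_glasso_penalty(wc$cov, glasso_params(penalty_grid = 0.07))
  expect_equal(fixed$penalty, 0.07)
})

test_that("windowed FNC trajectories are deterministic given the seed", {
  sim <- tiny_cohort(seed = 20, n_ep = 2, n_hc = 2, T = 90, C = 5)
  cond <- preprocess_timecourses(sim$data)
  gp <- glasso_params(penalty_grid = c(0.05, 0.2), n_repetitions = 3)
  w1 <- windowed_fnc(cond, window_params(), gp, seed = 77)
  w2 <- windowed_fnc(cond, window_params(), gp, seed = 77)
  expect_identical(w1$z, w2$z)
  expect_identical(w1$penalty, w2$penalty)
  expect_equal(nrow(w1$z[[1]]), n_windows(90, 30, 1))
  expect_true(all(is.finite(unlist(w1$z))))
})

test_that("motion regression is exact, orthogonal, and a no-op without motion", {
  sim <- tiny_cohort(seed = 22, n_ep = 2, n_hc = 2, T = 90, C = 5)
  cond <- preprocess_timecourses(sim$data)
  gp <- glasso_params(penalty_grid = 0.1)
  wf <- windowed_fnc(cond, window_params(), gp, seed = 1)

  # zero motion: all regressors constant, output unchanged (with warning)
  zero <- cond
  zero$motion <- lapply(zero$motion, function(m) motion_trace(m$params * 0))
  expect_warning(wf0 <- regress_motion_from_windows(wf, zero),
                 "constant motion regressor")
  expect_equal(wf0$z, wf$z)

  # genuine motion: residual series orthogonal to the windowed regressors
  wfm <- regress_motion_from_windows(wf, cond)
  M <- dynconn:::window_motion_summaries(cond$motion[[1]], wf$starts, 30,
                                         wf$taper)
  Mc <- scale(M, scale = FALSE)
  ip <- crossprod(Mc, scale(wfm$z[[1]], scale = FALSE))
  expect_lt(max(abs(ip)) / nrow(Mc), 1e-6)

  # a z-series exactly linear in windowed FD becomes constant
  wf2 <- wf
  wf2$z[[1]][, 1] <- 3 + 2 * M[, "fd"]
  wfl <- regress_motion_from_windows(wf2, cond)
  expect_lt(var(wfl$z[[1]][, 1]), 1e-10)
})

test_that("windows inside a planted segment sit closer to their own state", {
  ps <- make_planted_states(2, 8, within = c(0.7, 0.1),
                            between = c(-0.3, 0.05))
  spec <- cohort_spec(n_ep = 3, n_hc = 3, states = ps,
                      transition_ep = sticky_transition(c(0.99, 0.99)),
                      transition_hc = sticky_transition(c(0.99, 0.99)),
                      n_timepoints = 250, stay_jitter = 0, seed = 23)
  sim <- simulate_cohort(spec)
  cond <- preprocess_timecourses(sim$data)
  wf <- windowed_fnc(cond, window_params(),
                     glasso_params(penalty_grid = 0.05), seed = 2)
  pz <- sapply(ps$states, function(R)
    atanh(pmin(pmax(dynconn:::vec_upper(R), -0.999), 0.999)))
  good <- 0
  total <- 0
  for (i in seq_along(wf$z)) {
    s <- sim$truth$state_seq[[i]]
    for (k in seq_along(wf$starts)) {
      seg <- s[wf$starts[k] + 1:30]
      if (length(unique(seg)) == 1) {
        d <- colSums(abs(wf$z[[i]][k, ] - pz))
        good <- good + (which.min(d) == seg[1])
        total <- total + 1
      }
    }
  }
  expect_gte(good / total, 0.9)
})
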