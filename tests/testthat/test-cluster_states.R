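test_that("state metrics match hand-enumerated examples", {
  m <- state_metrics(c(1, 1, 1, 2, 2, 1, 3), k = 3)
  expect_equal(m$dwell, c(2, 2, 1))
  expect_equal(m$fraction, c(4, 2, 1) / 7)
  expect_equal(m$nt, 3)
  expect_equal(m$visited, c(TRUE, TRUE, TRUE))

  const <- state_metrics(rep(2, 371), k = 3)
  expect_equal(const$nt, 0)
  expect_equal(const$dwell, c(0, 371, 0))
  expect_equal(const$visited, c(FALSE, TRUE, FALSE))

  alt <- state_metrics(c(1, 2, 1, 2), k = 2)
  expect_equal(alt$nt, 3)
  expect_equal(alt$dwell, c(1, 1))
})

test_that("state metrics agree with brute-force enumeration on random sequences", {
  set.seed(24)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    x <- sample(seq_len(k), sample(1:50, 1), replace = TRUE)
    ours <- state_metrics(x, k)
    oracle <- oracle_state_metrics(x, k)
    expect_equal(ours$dwell, oracle$dwell)
    expect_equal(ours$fraction, oracle$fraction)
    expect_equal(ours$nt, oracle$nt)
    # NT equals number of maximal runs minus one
    expect_equal(ours$nt, oracle$n_runs - 1)
    expect_equal(sum(ours$fraction), 1, tolerance = 1e-12)
    # permutation invariance of NT and the dwell multiset
    p <- sample(k)
    perm <- state_metrics(p[x], k)
    expect_equal(perm$nt, ours$nt)
    expect_equal(sort(perm$dwell), sort(ours$dwell))
  }
})

# two clean, well-separated window populations
two_blob_wfnc <- function(n_sub = 6, nw = 40, npair = 10, sep = 6,
                          seed = 25) {
  dynconn:::with_seed(seed, {
    centers <- rbind(rep(0, npair), c(rep(sep, npair / 2), rep(-sep, npair / 2)))
    z <- lapply(seq_len(n_sub), function(i) {
      lab <- rep(1:2, length.out = nw)
      centers[lab, ] + matrix(rnorm(nw * npair, sd = 0.3), nw, npair)
    })
    list(wfnc = make_wfnc(z), truth = rep(rep(1:2, length.out = nw), n_sub))
  })
}

test_that("k-means recovers a clean planted partition perfectly", {
  tb <- two_blob_wfnc()
  model <- fit_cluster_states(tb$wfnc,
                              cluster_params(k = 2, n_replicates = 5,
                                             seed = 1))
  est <- unlist(model$assignments)
  expect_equal(match_agreement(est, tb$truth, 2), 1.0)
})

test_that("duplicating every window preserves centroids and doubles the cost", {
  tb <- two_blob_wfnc(n_sub = 4)
  m1 <- fit_cluster_states(tb$wfnc, cluster_params(k = 2, n_replicates = 3,
                                                   seed = 2))
  dup <- make_wfnc(c(tb$wfnc$z, tb$wfnc$z))
  m2 <- fit_cluster_states(dup, cluster_params(k = 2, n_replicates = 1,
                                               seed = 2),
                           init = m1$centroids)
  expect_equal(m2$centroids, m1$centroids)
  expect_equal(m2$cost, 2 * m1$cost, tolerance = 1e-10)
})

test_that("more restarts never increase the cost, and k is validated", {
  set.seed(26)
  z <- list(matrix(rnorm(200 * 10), 200, 10))
  wf <- make_wfnc(z, groups = "EP")
  c1 <- fit_cluster_states(wf, cluster_params(k = 4, n_replicates = 1,
                                              seed = 3))$cost
  c10 <- fit_cluster_states(wf, cluster_params(k = 4, n_replicates = 10,
                                               seed = 3))$cost
  expect_lte(c10, c1)
  tiny <- make_wfnc(list(matrix(rep(1:2, each = 3), 4, 3, byrow = TRUE)))
  expect_error(fit_cluster_states(tiny, cluster_params(k = 3)), "distinct")
})

test_that("relabeling invariance: permuted init gives permuted states, same metrics", {
  tb <- two_blob_wfnc(n_sub = 4)
  m1 <- fit_cluster_states(tb$wfnc, cluster_params(k = 2, n_replicates = 1,
                                                   seed = 4))
  m2 <- fit_cluster_states(tb$wfnc, cluster_params(k = 2, n_replicates = 1,
                                                   seed = 4),
                           init = m1$centroids[2:1, ])
  expect_equal(m2$centroids, m1$centroids[2:1, ], check.attributes = FALSE)
  t1 <- cohort_state_metrics(m1)
  t2 <- cohort_state_metrics(m2)
  expect_equal(t1$nt, t2$nt)
  expect_equal(t1$dwell_1, t2$dwell_2)
  expect_equal(sort(names(t1)), sort(names(t2)))
})

test_that("fraction-time bookkeeping is exact", {
  tb <- two_blob_wfnc(n_sub = 3, nw = 37)
  model <- fit_cluster_states(tb$wfnc, cluster_params(k = 2,
                                                      n_replicates = 2,
                                                      seed = 5))
  tab <- cohort_state_metrics(model)
  expect_equal((tab$frac_1 + tab$frac_2) * 37, rep(37, 3))
})

test_that("per-state group comparison detects a planted coupling in one state", {
  set.seed(27)
  n_sub <- 24
  nw <- 60
  npair <- 10
  groups <- rep(c("EP", "HC"), each = n_sub / 2)
  z <- lapply(seq_len(n_sub), function(i) {
    lab <- rep(1:2, each = nw / 2)
    base <- rbind(rep(-2, npair), rep(2, npair))[lab, ]
    # EP subjects: pair 3 shifted in state 2 only
    if (groups[i] == "EP") base[lab == 2, 3] <- base[lab == 2, 3] + 1.5
    base + matrix(rnorm(nw * npair, sd = 0.5), nw, npair)
  })
  wf <- make_wfnc(z, groups = groups)
  model <- fit_cluster_states(wf, cluster_params(k = 2, n_replicates = 3,
                                                 seed = 6))
  res <- per_state_group_compare(wf, model)
  # identify the model state corresponding to planted state 2
  s2 <- model$assignments[[1]][nw]
  hit <- res[res$state == s2 & res$pair == wf$pairs[3], ]
  expect_lt(hit$p, 0.01)
  expect_match(hit$direction, "EP >")
  # all other pairs in the other state stay null-ish on average
  other <- res[res$state != s2, ]
  expect_lt(mean(other$p < 0.05), 0.2)
})

test_that("subjects without windows in a state are excluded from its test", {
  set.seed(28)
  npair <- 6
  z <- lapply(1:10, function(i) {
    lab <- if (i == 1) rep(1, 30) else rep(1:2, each = 15)
    rbind(rep(-2, npair), rep(2, npair))[lab, ] +
      matrix(rnorm(30 * npair, sd = 0.4), 30, npair)
  })
  wf <- make_wfnc(z, groups = rep(c("EP", "HC"), 5))
  model <- fit_cluster_states(wf, cluster_params(k = 2, n_replicates = 3,
                                                 seed = 7))
  res <- per_state_group_compare(wf, model)
  s_absent <- setdiff(1:2, unique(model$assignments[[1]]))
  n_col <- if (wf$subjects$group[1] == "EP") "n_a" else "n_b"
  expect_equal(unique(res[[n_col]][res$state == s_absent]), 4)
})

test_that("a state visited by a single group is skipped with a notice", {
  set.seed(29)
  npair <- 6
  z <- lapply(1:8, function(i) {
    lab <- if (i <= 4) rep(1:2, each = 15) else rep(1, 30)
    rbind(rep(-3, npair), rep(3, npair))[lab, ] +
      matrix(rnorm(30 * npair, sd = 0.3), 30, npair)
  })
  wf <- make_wfnc(z, groups = rep(c("EP", "HC"), each = 4))
  model <- fit_cluster_states(wf, cluster_params(k = 2, n_replicates = 3,
                                                 seed = 8))
  expect_message(res <- per_state_group_compare(wf, model), "skipped")
  expect_equal(length(unique(res$state)), 1L)
  expect_equal(length(attr(res, "skipped")), 1L)
})

test_that("the k sweep is deterministic with monotone cost", {
  set.seed(30)
  z <- lapply(1:6, function(i) {
    lab <- sample(1:3, 50, replace = TRUE)
    (rbind(rep(-3, 10), rep(0, 10), rep(3, 10)))[lab, ] +
      matrix(rnorm(50 * 10, sd = 0.4), 50, 10)
  })
  wf <- make_wfnc(z)
  s1 <- sweep_k(wf, ks = 2:4, n_replicates = 3, seed = 9)
  s2 <- sweep_k(wf, ks = 2:4, n_replicates = 3, seed = 9)
  expect_identical(s1$cost, s2$cost)
  expect_true(all(diff(s1$cost$cost) < 0))
  expect_named(s1$models, c("k2", "k3", "k4"))
})
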