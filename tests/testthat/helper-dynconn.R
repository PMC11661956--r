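# shared fixtures and independent oracles, built in code at test time

# brute-force state metrics by direct enumeration (independent of rle)
oracle_state_metrics <- function(x, k = max(x)) {
  runs <- list()
  start <- 1
  for (t in seq_along(x)[-1]) {
    if (x[t] != x[t - 1]) {
      runs[[length(runs) + 1]] <- c(state = x[start], len = t - start)
      start <- t
    }
  }
  runs[[length(runs) + 1]] <- c(state = x[start], len = length(x) - start + 1)
  rm <- do.call(rbind, runs)
  dwell <- vapply(seq_len(k), function(s) {
    l <- rm[rm[, "state"] == s, "len"]
    if (length(l)) mean(l) else 0
  }, numeric(1))
  nt <- 0
  for (t in seq_along(x)[-1]) if (x[t] != x[t - 1]) nt <- nt + 1
  list(dwell = dwell,
       fraction = vapply(seq_len(k), function(s) mean(x == s), numeric(1)),
       nt = nt, n_runs = nrow(rm))
}

# brute-force meta-state metrics by pairwise enumeration
oracle_meta_metrics <- function(traj) {
  traj <- as.matrix(traj)
  seen <- list()
  for (t in seq_len(nrow(traj))) {
    v <- traj[t, ]
    if (!any(vapply(seen, function(u) all(u == v), logical(1))))
      seen[[length(seen) + 1]] <- v
  }
  nch <- 0
  tot <- 0
  if (nrow(traj) > 1) {
    for (t in 2:nrow(traj)) {
      d <- sum(abs(traj[t, ] - traj[t - 1, ]))
      if (d > 0) nch <- nch + 1
      tot <- tot + d
    }
  }
  span <- 0
  if (length(seen) > 1) {
    for (a in 1:(length(seen) - 1)) for (b in (a + 1):length(seen))
      span <- max(span, sum(abs(seen[[a]] - seen[[b]])))
  }
  list(n_meta_states = length(seen), n_changes = nch, span = span,
       total_distance = tot)
}

# best assignment agreement over all label permutations (small k)
match_agreement <- function(est, truth, k) {
  perms <- gtools_permutations(k)
  best <- 0
  for (i in seq_len(nrow(perms))) {
    best <- max(best, mean(est == perms[i, ][truth]))
  }
  best
}

gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(k - 1)
  out <- NULL
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                            if (pos <= k - 1)
                              sub[, pos:(k - 1), drop = FALSE]))
  }
  unname(out)
}

# windowed_fnc object built directly from given per-subject z matrices
# (bypasses the covariance/glasso pipeline for clustering/meta tests)
make_wfnc <- function(z_list, groups = NULL, components = NULL) {
  nw <- nrow(z_list[[1]])
  npair <- ncol(z_list[[1]])
  if (is.null(components)) {
    C <- round((1 + sqrt(1 + 8 * npair)) / 2)
    stopifnot(C * (C - 1) / 2 == npair)   # npair must be triangular
    components <- paste0("IC", seq_len(C))
  }
  pairs <- dynconn:::upper_pairs(components)$label
  if (is.null(groups)) groups <- rep(c("EP", "HC"), length.out = length(z_list))
  z_list <- lapply(z_list, function(z) {
    colnames(z) <- pairs
    z
  })
  structure(list(z = z_list, starts = seq_len(nw) - 1L, pairs = pairs,
                 window_params = window_params(),
                 glasso_params = glasso_params(),
                 penalty = rep(0, length(z_list)),
                 taper = make_taper(30, 3, 400),
                 subjects = data.frame(
                   subject_id = sprintf("sub-%03d", seq_along(z_list)),
                   group = groups, stringsAsFactors = FALSE),
                 components = components, tr = 0.72),
            class = "windowed_fnc")
}

# small ready-made cohort shared by a few tests (kept tiny for speed)
tiny_cohort <- function(seed = 42, n_ep = 4, n_hc = 4, T = 120, C = 8) {
  simulate_cohort(cohort_spec(
    n_ep = n_ep, n_hc = n_hc,
    states = make_planted_states(3, C),
    n_timepoints = T, seed = seed))
}
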