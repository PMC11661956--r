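#' Clustering parameters for the state analysis
#'
#' @param k number of states (>= 2); the headline analysis uses k = 5
#'   with an exploratory sweep over 4-6.
#' @param n_replicates random restarts; the solution with the lowest
#'   total city-block cost is kept.
#' @param distance `"cityblock"` (with median centroid update, default)
#'   or `"euclidean"` (squared-Euclidean with mean update).
#' @param max_iter iteration cap per restart.
#' @param seed integer seed making the fit deterministic.
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(k = 5, n_replicates = 100,
                           distance = c("cityblock", "euclidean"),
                           max_iter = 100, seed = 1L) {
  stopifnot(k >= 2, n_replicates >= 1)
  structure(list(k = k, n_replicates = n_replicates,
                 distance = match.arg(distance),
                 max_iter = max_iter, seed = seed),
            class = "cluster_params")
}

# n x k matrix of distances from rows of X to rows of centroids
point_centroid_dist <- function(X, centroids, distance) {
  k <- nrow(centroids)
  D <- matrix(0, nrow(X), k)
  for (j in seq_len(k)) {
    dif <- X - matrix(centroids[j, ], nrow(X), ncol(X), byrow = TRUE)
    D[, j] <- if (distance == "cityblock") rowSums(abs(dif))
              else rowSums(dif * dif)
  }
  D
}

# one k-means run from given initial centroids; median update for
# city-block distance, mean update for squared-Euclidean
kmeans_run <- function(X, centroids, distance, max_iter) {
  assign_old <- rep(0L, nrow(X))
  for (it in seq_len(max_iter)) {
    D <- point_centroid_dist(X, centroids, distance)
    assign_new <- max.col(-D, ties.method = "first")
    for (j in seq_len(nrow(centroids))) {
      rows <- which(assign_new == j)
      if (length(rows) == 0) {
        # re-seed an empty cluster at the worst-fitted point
        worst <- which.max(D[cbind(seq_len(nrow(X)), assign_new)])
        centroids[j, ] <- X[worst, ]
        assign_new[worst] <- j
        rows <- worst
      }
      centroids[j, ] <- if (distance == "cityblock")
        apply(X[rows, , drop = FALSE], 2, median)
      else colMeans(X[rows, , drop = FALSE])
    }
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
  }
  D <- point_centroid_dist(X, centroids, distance)
  assignment <- max.col(-D, ties.method = "first")
  cost <- sum(D[cbind(seq_len(nrow(X)), assignment)])
  list(centroids = centroids, assignment = assignment, cost = cost)
}

#' Fit recurring connectivity states by k-means
#'
#' Pools all subjects' windowed FNC vectors and clusters them with
#' city-block distance and median centroid updates (the geometry shared
#' with the meta-state metrics), keeping the best of `n_replicates`
#' random initializations by total cost. Assignments are mapped back per
#' subject in window order.
#'
#' @param wfnc `windowed_fnc`.
#' @param params `cluster_params`.
#' @param init optional k x pairs matrix of initial centroids (used for
#'   every replicate; mainly for testing determinism/invariance).
#' @return object of class `cluster_state_model`: `centroids` (k x pairs,
#'   Fisher-z units), `state_matrices` (per-state component correlation
#'   matrices, back-transformed), `assignments` (per-subject integer
#'   sequences), `cost`, `params`, `subjects`.
#' @export
fit_cluster_states <- function(wfnc, params = cluster_params(), init = NULL) {
  stopifnot(inherits(wfnc, "windowed_fnc"))
  X <- do.call(rbind, wfnc$z)
  k <- params$k
  n_distinct <- nrow(unique(X))
  if (k > n_distinct)
    stop(sprintf("k = %d exceeds the number of distinct windows (%d)",
                 k, n_distinct))
  best <- NULL
  seeds <- with_seed(params$seed,
                     sample.int(.Machine$integer.max, params$n_replicates))
  for (r in seq_len(params$n_replicates)) {
    cent <- if (!is.null(init)) as.matrix(init)
            else X[with_seed(seeds[r], sample.int(nrow(X), k)), , drop = FALSE]
    run <- kmeans_run(X, cent, params$distance, params$max_iter)
    if (is.null(best) || run$cost < best$cost) best <- run
  }
  nw <- vapply(wfnc$z, nrow, integer(1))
  idx_end <- cumsum(nw)
  idx_start <- c(1L, head(idx_end, -1) + 1L)
  assignments <- Map(function(a, b) best$assignment[a:b], idx_start, idx_end)
  names(assignments) <- wfnc$subjects$subject_id
  colnames(best$centroids) <- wfnc$pairs
  C <- length(wfnc$components)
  state_matrices <- lapply(seq_len(k), function(j) {
    m <- unvec_upper(tanh(best$centroids[j, ]), C, diag_value = 1)
    dimnames(m) <- list(wfnc$components, wfnc$components)
    m
  })
  structure(list(centroids = best$centroids,
                 state_matrices = state_matrices,
                 assignments = assignments, cost = best$cost,
                 k = k, params = params, pairs = wfnc$pairs,
                 subjects = wfnc$subjects), class = "cluster_state_model")
}

#' @export
print.cluster_state_model <- function(x, ...) {
  cat(sprintf("cluster_state_model: k = %d states, %d subjects, cost = %.4g\n",
              x$k, length(x$assignments), x$cost))
  occ <- table(factor(unlist(x$assignments), levels = seq_len(x$k)))
  cat("window occupancy:", paste(occ, collapse = " "), "\n")
  invisible(x)
}

#' Dwell, fraction, and transition metrics for one state sequence
#'
#' Mean dwell time is the mean length of maximal constant runs per state
#' (in windows); fraction time is the share of windows in each state; NT
#' is the number of adjacent unequal pairs. Unvisited states get dwell 0
#' and `visited = FALSE`.
#'
#' @param assignment non-empty integer state sequence.
#' @param k number of states (default: max observed).
#' @return list with `dwell`, `fraction`, `visited` (each length k) and
#'   `nt`.
#' @export
state_metrics <- function(assignment, k = max(assignment)) {
  stopifnot(length(assignment) >= 1)
  r <- rle(as.integer(assignment))
  dwell <- vapply(seq_len(k), function(s) {
    len <- r$lengths[r$values == s]
    if (length(len)) mean(len) else 0
  }, numeric(1))
  counts <- vapply(seq_len(k), function(s) sum(assignment == s), numeric(1))
  list(dwell = dwell, fraction = counts / length(assignment),
       visited = counts > 0, nt = sum(diff(as.integer(assignment)) != 0))
}

#' Per-subject state-metric table for a fitted model
#'
#' @param model `cluster_state_model`.
#' @return data.frame: subject_id, group, dwell_1..k, frac_1..k, nt.
#' @export
cohort_state_metrics <- function(model) {
  stopifnot(inherits(model, "cluster_state_model"))
  k <- model$k
  rows <- lapply(model$assignments, function(a) {
    m <- state_metrics(a, k)
    c(m$dwell, m$fraction, m$nt)
  })
  tab <- do.call(rbind, rows)
  colnames(tab) <- c(paste0("dwell_", seq_len(k)),
                     paste0("frac_", seq_len(k)), "nt")
  cbind(model$subjects[, c("subject_id", "group")], as.data.frame(tab),
        row.names = NULL)
}

#' Per-state group comparison of windowed connectivity
#'
#' Each subject's connectivity in a state is summarized as the mean
#' z-value over that subject's windows assigned to the state; pairs are
#' then compared between groups with two-sample (Welch) t-tests. Subjects
#' with no windows in a state are excluded from that state's tests, and a
#' state visited by fewer than two subjects of either group is skipped
#' with a notice.
#'
#' @param wfnc `windowed_fnc`.
#' @param model fitted `cluster_state_model` on the same windows.
#' @param alpha significance level for the `significant` flag (raw by
#'   default, matching the source analysis).
#' @param fdr apply BH-FDR within each state instead of the raw level.
#' @return data.frame: state, pair, n per group, t, df, p (and p_adj if
#'   `fdr`), direction, significant. Skipped states are recorded in the
#'   `skipped` attribute.
#' @export
per_state_group_compare <- function(wfnc, model, alpha = 0.05, fdr = FALSE) {
  groups <- factor(wfnc$subjects$group)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  ga <- levels(groups)[1]
  gb <- levels(groups)[2]
  out <- NULL
  skipped <- integer(0)
  for (s in seq_len(model$k)) {
    means <- lapply(seq_along(wfnc$z), function(i) {
      rows <- model$assignments[[i]] == s
      if (!any(rows)) return(NULL)
      colMeans(wfnc$z[[i]][rows, , drop = FALSE])
    })
    has <- !vapply(means, is.null, logical(1))
    na <- sum(has & groups == ga)
    nb <- sum(has & groups == gb)
    if (na < 2 || nb < 2) {
      skipped <- c(skipped, s)
      message(sprintf("state %d: fewer than 2 subjects per group with windows; skipped", s))
      next
    }
    M <- do.call(rbind, means[has])
    g <- groups[has]
    res <- apply(M, 2, function(v) {
      tt <- t.test(v[g == ga], v[g == gb])
      c(t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, diff = mean(v[g == ga]) - mean(v[g == gb]))
    })
    df_s <- data.frame(state = s, pair = wfnc$pairs,
                       n_a = na, n_b = nb,
                       t = res["t", ], df = res["df", ], p = res["p", ],
                       mean_diff = res["diff", ], row.names = NULL)
    if (fdr) df_s$p_adj <- p.adjust(df_s$p, "BH")
    df_s$direction <- ifelse(df_s$mean_diff >= 0,
                             paste(ga, ">", gb), paste(ga, "<", gb))
    df_s$significant <- (if (fdr) df_s$p_adj else df_s$p) < alpha
    out <- rbind(out, df_s)
  }
  attr(out, "skipped") <- skipped
  attr(out, "groups") <- c(ga, gb)
  out
}

#' Sensitivity sweep over the number of states
#'
#' Refits the cluster-state model and recomputes the per-subject metric
#' table for each k.
#'
#' @param wfnc `windowed_fnc`.
#' @param ks integer vector of state counts (default 4:6).
#' @param n_replicates restarts per k.
#' @param seed integer seed (shared across k for reproducibility).
#' @return list with `models` (named by k), `metrics` (named list of
#'   metric tables), and `cost` (data.frame of k vs within-cluster cost).
#' @export
sweep_k <- function(wfnc, ks = c(4, 5, 6), n_replicates = 20, seed = 1L) {
  models <- lapply(ks, function(k)
    fit_cluster_states(wfnc, cluster_params(k = k,
                                            n_replicates = n_replicates,
                                            seed = seed)))
  names(models) <- paste0("k", ks)
  metrics <- lapply(models, cohort_state_metrics)
  list(models = models, metrics = metrics,
       cost = data.frame(k = ks,
                         cost = vapply(models, `[[`, numeric(1), "cost")))
}
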