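#' Meta-state analysis parameters
#'
#' @param model_order number of maximally independent connectivity
#'   patterns (>= 2; default 5).
#' @param per_subject_quartiles discretize weights with per-subject
#'   quartiles instead of the default pooled (global) quartiles.
#' @param seed integer seed; the decomposition is deterministic given it.
#' @return list of class `meta_params`.
#' @export
meta_params <- function(model_order = 5, per_subject_quartiles = FALSE,
                        seed = 1L) {
  stopifnot(model_order >= 2)
  structure(list(model_order = model_order,
                 per_subject_quartiles = per_subject_quartiles,
                 seed = seed), class = "meta_params")
}

#' Fit maximally independent connectivity patterns
#'
#' The pooled windows x pairs matrix is reduced to `model_order`
#' principal axes and rotated by FastICA so that the patterns (loadings
#' over component pairs) are maximally independent — spatial ICA on the
#' group's windowed connectivity. Patterns are normalized to unit norm
#' with their largest-magnitude entry positive; per-window weights are the
#' least-squares projection of each window's FNC vector onto the
#' patterns, so held-out subjects can be projected onto a fitted model.
#'
#' @param wfnc `windowed_fnc`.
#' @param params `meta_params`.
#' @return object of class `meta_state_model`: `patterns` (model_order x
#'   pairs), `weights` (per subject, windows x model_order), `params`,
#'   `subjects`.
#' @export
fit_meta_states <- function(wfnc, params = meta_params()) {
  stopifnot(inherits(wfnc, "windowed_fnc"))
  m <- params$model_order
  X <- do.call(rbind, wfnc$z)
  if (nrow(X) < m) stop("fewer pooled windows than the model order")
  Xc <- scale(X, scale = FALSE)
  sv <- svd(Xc, nu = 0, nv = min(dim(Xc)))
  rank <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1])
  if (rank < m)
    stop(sprintf("window matrix rank %d is below the model order %d",
                 rank, m))
  # sources live in pair space: run ICA on the reduced pairs x m matrix
  Y <- sv$v[, seq_len(m), drop = FALSE] %*% diag(sv$d[seq_len(m)], m)
  ic <- with_seed(params$seed,
                  ica::icafast(Y, nc = m, maxit = 200, tol = 1e-7))
  P <- t(ic$S)                         # model_order x pairs
  for (j in seq_len(m)) {
    P[j, ] <- P[j, ] / sqrt(sum(P[j, ]^2))
    if (P[j, which.max(abs(P[j, ]))] < 0) P[j, ] <- -P[j, ]
  }
  colnames(P) <- wfnc$pairs
  rownames(P) <- paste0("pattern_", seq_len(m))
  W_all <- t(qr.solve(tcrossprod(P), P %*% t(X)))   # least-squares weights
  colnames(W_all) <- rownames(P)
  nw <- vapply(wfnc$z, nrow, integer(1))
  idx_end <- cumsum(nw)
  idx_start <- c(1L, head(idx_end, -1) + 1L)
  weights <- Map(function(a, b) W_all[a:b, , drop = FALSE],
                 idx_start, idx_end)
  names(weights) <- wfnc$subjects$subject_id
  structure(list(patterns = P, weights = weights, params = params,
                 subjects = wfnc$subjects), class = "meta_state_model")
}

# signed-quartile map of a weight matrix given |w| quartile boundaries
discretize_matrix <- function(W, boundaries) {
  lev <- findInterval(abs(W), boundaries) + 1L
  sgn <- sign(W)
  sgn[sgn == 0] <- 1
  out <- matrix(as.integer(sgn * lev), nrow(W), ncol(W))
  colnames(out) <- colnames(W)
  out
}

#' Discretize meta-state weights to signed quartiles
#'
#' Per pattern, quartile boundaries of the absolute weights are computed
#' over all subjects' windows pooled (or per subject if the model was
#' built with `per_subject_quartiles`); each weight maps to
#' `sign(w) * quartile(|w|)` in {-4..-1, 1..4}, with zero weights mapping
#' to +1. Degenerate (tied) quartile boundaries are collapsed by a stable
#' rule — duplicated boundaries are dropped via `unique()` and the lower
#' quartile levels merged — and reported with a message.
#'
#' @param model `meta_state_model`.
#' @return object of class `meta_state_trajectories`: list with
#'   `trajectories` (per subject, windows x model_order integer matrices)
#'   and `boundaries`.
#' @export
discretize_weights <- function(model) {
  stopifnot(inherits(model, "meta_state_model"))
  m <- ncol(model$weights[[1]])
  qs <- c(0.25, 0.5, 0.75)
  if (!model$params$per_subject_quartiles) {
    pooled <- do.call(rbind, model$weights)
    boundaries <- lapply(seq_len(m), function(j) {
      b <- quantile(abs(pooled[, j]), qs, names = FALSE)
      ub <- unique(b)
      if (length(ub) < length(b))
        message(sprintf("pattern %d: tied quartile boundaries collapsed (%d distinct)",
                        j, length(ub)))
      ub
    })
    traj <- lapply(model$weights, function(W) {
      out <- W
      for (j in seq_len(m))
        out[, j] <- discretize_matrix(W[, j, drop = FALSE],
                                      boundaries[[j]])
      storage.mode(out) <- "integer"
      out
    })
  } else {
    boundaries <- NULL
    traj <- lapply(model$weights, function(W) {
      out <- W
      for (j in seq_len(m)) {
        b <- unique(quantile(abs(W[, j]), qs, names = FALSE))
        out[, j] <- discretize_matrix(W[, j, drop = FALSE], b)
      }
      storage.mode(out) <- "integer"
      out
    })
  }
  structure(list(trajectories = traj, boundaries = boundaries,
                 subjects = model$subjects),
            class = "meta_state_trajectories")
}

#' Meta-state dynamism metrics for one trajectory
#'
#' Fluidity: `n_meta_states`, the number of distinct discretized vectors
#' occupied, and `n_changes`, the number of window-to-window vector
#' changes. Range (city-block geometry): `span`, the largest L1 distance
#' between any two occupied vectors, and `total_distance`, the summed L1
#' length of the trajectory.
#'
#' @param traj windows x model_order integer matrix (>= 1 window).
#' @return list with `n_meta_states`, `n_changes`, `span`,
#'   `total_distance`.
#' @export
meta_state_metrics <- function(traj) {
  traj <- as.matrix(traj)
  stopifnot(nrow(traj) >= 1)
  u <- unique(traj)
  n_meta <- nrow(u)
  if (nrow(traj) == 1)
    return(list(n_meta_states = 1L, n_changes = 0L, span = 0,
                total_distance = 0))
  step <- abs(traj[-1, , drop = FALSE] - traj[-nrow(traj), , drop = FALSE])
  n_changes <- sum(rowSums(step) > 0)
  total <- sum(step)
  span <- 0
  if (n_meta > 1) {
    for (a in seq_len(n_meta - 1)) {
      d <- rowSums(abs(u[(a + 1):n_meta, , drop = FALSE] -
                         matrix(u[a, ], n_meta - a, ncol(u), byrow = TRUE)))
      span <- max(span, max(d))
    }
  }
  list(n_meta_states = n_meta, n_changes = as.integer(n_changes),
       span = span, total_distance = total)
}

#' Per-subject meta-state metric table
#'
#' @param traj `meta_state_trajectories`.
#' @return data.frame: subject_id, group, n_meta_states, n_changes, span,
#'   total_distance.
#' @export
cohort_meta_metrics <- function(traj) {
  stopifnot(inherits(traj, "meta_state_trajectories"))
  rows <- lapply(traj$trajectories, function(m) {
    unlist(meta_state_metrics(m))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  cbind(traj$subjects[, c("subject_id", "group")], tab, row.names = NULL)
}
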