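#' Sliding-window parameters
#'
#' @param width window width in TRs (>= 2); the default 30 TRs is 60 s at
#'   TR = 0.72 s (usual fMRI dFNC convention, rounded).
#' @param gauss_alpha SD (in TRs) of the Gaussian kernel convolved with
#'   the boxcar to taper the window.
#' @param step slide step in TRs.
#' @return list of class `window_params`.
#' @export
window_params <- function(width = 30, gauss_alpha = 3, step = 1) {
  stopifnot(width >= 2, step >= 1, gauss_alpha > 0)
  structure(list(width = width, gauss_alpha = gauss_alpha, step = step),
            class = "window_params")
}

#' Graphical-LASSO parameters
#'
#' @param penalty_grid candidate L1 penalties (>= 0, non-empty); the
#'   per-subject penalty is chosen from this grid by held-out
#'   log-likelihood. A length-1 grid fixes the penalty.
#' @param n_repetitions number of random train/test window splits used
#'   for penalty selection.
#' @param tol convergence tolerance of the coordinate-descent solver.
#' @param max_iter maximum outer iterations.
#' @param measure connectivity measure extracted from the fit:
#'   `"correlation"` (default; correlation implied by the regularized
#'   covariance) or `"partial"` (negative partial correlations from the
#'   precision matrix).
#' @return list of class `glasso_params`.
#' @export
glasso_params <- function(penalty_grid = 10^seq(-3, 0, length.out = 10),
                          n_repetitions = 10,
                          tol = 1e-4, max_iter = 2000,
                          measure = c("correlation", "partial")) {
  if (length(penalty_grid) < 1) stop("penalty_grid must be non-empty")
  if (any(penalty_grid < 0)) stop("penalties must be >= 0")
  structure(list(penalty_grid = sort(penalty_grid),
                 n_repetitions = n_repetitions,
                 tol = tol, max_iter = max_iter,
                 measure = match.arg(measure)), class = "glasso_params")
}

#' Tapered window weights
#'
#' A boxcar of length `width` convolved with a unit-area Gaussian kernel
#' of SD `gauss_alpha` TRs, truncated to the window support and
#' renormalized to sum 1. Symmetric and maximal at the window center; as
#' `gauss_alpha` approaches 0 the weights tend to the uniform 1/width.
#'
#' @param width window width in TRs.
#' @param gauss_alpha Gaussian SD in TRs.
#' @param T total series length (the window must fit: `width <= T`).
#' @return numeric weight vector of length `width` summing to 1.
#' @export
make_taper <- function(width, gauss_alpha, T = width) {
  if (width > T) stop(sprintf("window width %d exceeds series length %d",
                              width, T))
  i <- seq_len(width)
  w <- vapply(i, function(ii) sum(stats::dnorm(ii - i, sd = gauss_alpha)),
              numeric(1))
  w / sum(w)
}

#' Number of sliding windows
#'
#' `floor((T - width)/step) + 1`, the exact count for all inputs.
#'
#' @param T series length; `width`, `step` window parameters.
#' @param width,step window width and slide step (TRs).
#' @export
n_windows <- function(T, width, step = 1) {
  if (width > T) stop("width exceeds series length")
  as.integer(floor((T - width) / step)) + 1L
}

#' Weighted covariance matrices over sliding windows
#'
#' For each window the taper-weighted mean is removed and the
#' taper-weighted covariance computed (weights summing to 1); each window
#' covariance is symmetric positive semidefinite. Uniform weights reduce
#' to the ordinary (1/W-normalized) sample covariance of the window.
#'
#' @param tc T x C matrix of conditioned time courses.
#' @param width,step window width and step (TRs).
#' @param weights length-`width` taper (default [make_taper]).
#' @return list with `cov` (list of C x C matrices), `starts` (0-based
#'   window start TRs), and `weights`.
#' @export
windowed_covariance <- function(tc, width = 30, step = 1, weights = NULL) {
  tc <- as.matrix(tc)
  T <- nrow(tc)
  if (is.null(weights)) weights <- make_taper(width, 3, T)
  if (length(weights) != width) stop("weights must have length width")
  w <- weights / sum(weights)
  nw <- n_windows(T, width, step)
  starts <- (seq_len(nw) - 1L) * step
  covs <- vector("list", nw)
  for (k in seq_len(nw)) {
    X <- tc[starts[k] + seq_len(width), , drop = FALSE]
    mu <- colSums(w * X)
    Xc <- sweep(X, 2, mu)
    covs[[k]] <- crossprod(Xc * sqrt(w))
  }
  list(cov = covs, starts = starts, weights = w)
}

# covariance -> correlation with a guard for zero-variance components
safe_cov2cor <- function(S) {
  d <- diag(S)
  bad <- d <= 0
  if (any(bad)) {
    d[bad] <- 1
    S[bad, ] <- 0
    S[, bad] <- 0
    diag(S)[bad] <- 1
  }
  D <- 1 / sqrt(d)
  R <- S * tcrossprod(D)
  diag(R) <- 1
  R
}

#' Graphical-LASSO regularized window connectivity
#'
#' Estimates an L1-penalized inverse covariance on the correlation scale
#' and returns the implied regularized correlation matrix (or, with
#' `measure = "partial"`, the negative partial correlations from the
#' precision matrix). At penalty 0 the result equals the input (weighted
#' sample) correlation.
#'
#' @param S window covariance (symmetric PSD).
#' @param penalty L1 penalty (>= 0).
#' @param params `glasso_params` (tolerance, iterations, measure).
#' @return list with `correlation` (the connectivity matrix), `precision`,
#'   and `converged`.
#' @export
glasso_regularize <- function(S, penalty, params = glasso_params()) {
  R0 <- safe_cov2cor(as.matrix(S))
  fit <- .glasso_cpp(R0, penalty, tol = params$tol, maxit = params$max_iter)
  if (!fit$converged)
    stop(sprintf(paste0("graphical lasso did not converge at penalty %.3g; ",
                        "consider the largest grid penalty %.3g"),
                 penalty, max(params$penalty_grid)))
  Th <- fit$theta
  R <- if (params$measure == "partial") {
    D <- 1 / sqrt(diag(Th))
    P <- -Th * tcrossprod(D)
    diag(P) <- 1
    P
  } else {
    safe_cov2cor(fit$w)
  }
  list(correlation = R, precision = Th, converged = fit$converged)
}

# Gaussian held-out log-likelihood of precision Theta against sample
# correlation R (constants dropped)
gaussian_ll <- function(Theta, R) {
  determinant(Theta, logarithm = TRUE)$modulus - sum(Theta * R)
}

#' Select the graphical-LASSO penalty for one subject
#'
#' Repeated random train/test splits of the subject's windows: in each
#' repetition one randomly drawn window is the training target — matching
#' the downstream use of the penalty, which regularizes single windows —
#' and each candidate penalty's fit to it is scored by the average
#' Gaussian log-likelihood of a held-out sample of the remaining windows.
#' The penalty maximizing the mean held-out log-likelihood across
#' repetitions is chosen. A penalty that fails to converge, or whose fit
#' is singular on held-out data, drops out of the comparison; if the
#' whole grid fails an error suggests the largest-penalty fallback.
#'
#' @param covs list of window covariance matrices.
#' @param params `glasso_params`; `n_test` held-out windows are scored
#'   per repetition (capped at the available count).
#' @param seed integer seed for the random splits.
#' @param n_test held-out windows scored per repetition.
#' @return list with `penalty` and `loglik` (grid x repetitions matrix).
#' @export
select_glasso_penalty <- function(covs, params = glasso_params(),
                                  seed = NULL, n_test = 50) {
  grid <- params$penalty_grid
  if (length(grid) == 1)
    return(list(penalty = grid, loglik = NULL))
  Rs <- lapply(covs, safe_cov2cor)
  nw <- length(Rs)
  if (nw < 2) stop("need at least 2 windows to select a penalty")
  with_seed(seed, {
    ll <- matrix(NA_real_, length(grid), params$n_repetitions)
    for (rep in seq_len(params$n_repetitions)) {
      tr_idx <- sample.int(nw, 1)
      te_idx <- sample(setdiff(seq_len(nw), tr_idx),
                       min(n_test, nw - 1))
      warm <- NULL
      for (g in rev(seq_along(grid))) {   # sparse to dense, warm-started
        fit <- .glasso_cpp(Rs[[tr_idx]], grid[g], tol = params$tol,
                           maxit = params$max_iter,
                           W_init = warm$w, B_init = warm$b)
        warm <- fit
        if (!fit$converged) next
        det_th <- determinant(fit$theta, logarithm = TRUE)
        if (det_th$sign <= 0) next
        ld <- as.numeric(det_th$modulus)
        ll[g, rep] <- mean(vapply(Rs[te_idx],
                                  function(R) ld - sum(fit$theta * R),
                                  numeric(1)))
      }
    }
    score <- rowMeans(ll, na.rm = TRUE)
    if (all(!is.finite(score)))
      stop(sprintf("graphical lasso failed to converge on the whole grid; largest penalty tried %.3g", max(grid)))
    list(penalty = grid[which.max(score)], loglik = ll)
  })
}

#' Windowed, regularized FNC trajectories for a cohort
#'
#' For every subject: tapered sliding-window covariances, per-subject
#' penalty selection, graphical-LASSO regularization of every window, and
#' Fisher z-transform of the resulting correlations.
#'
#' @param set conditioned `timecourse_set`.
#' @param wparams `window_params`.
#' @param gparams `glasso_params`.
#' @param seed master seed for the penalty-selection splits.
#' @return object of class `windowed_fnc`: list with `z` (per subject,
#'   windows x pairs matrix of Fisher-z values), `starts`, `pairs`,
#'   `penalty` (chosen per subject), the parameter objects, `subjects`,
#'   `components`, and `tr`.
#' @export
windowed_fnc <- function(set, wparams = window_params(),
                         gparams = glasso_params(), seed = 1L) {
  stopifnot(inherits(set, "timecourse_set"))
  T <- nrow(set$timecourses[[1]])
  taper <- make_taper(wparams$width, wparams$gauss_alpha, T)
  pairs <- upper_pairs(set$components)
  n <- n_subjects(set)
  z <- vector("list", n)
  penalty <- numeric(n)
  starts <- NULL
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n))
  for (i in seq_len(n)) {
    wc <- windowed_covariance(set$timecourses[[i]], wparams$width,
                              wparams$step, taper)
    starts <- wc$starts
    sel <- select_glasso_penalty(wc$cov, gparams, seed = sub_seeds[i])
    penalty[i] <- sel$penalty
    Z <- matrix(NA_real_, length(wc$cov), length(pairs$label))
    for (k in seq_along(wc$cov)) {
      R <- glasso_regularize(wc$cov[[k]], sel$penalty, gparams)$correlation
      r <- pmin(pmax(vec_upper(R), -(1 - 1e-7)), 1 - 1e-7)
      Z[k, ] <- atanh(r)
    }
    colnames(Z) <- pairs$label
    z[[i]] <- Z
  }
  structure(list(z = z, starts = starts, pairs = pairs$label,
                 window_params = wparams, glasso_params = gparams,
                 penalty = penalty, taper = taper,
                 subjects = set$subjects, components = set$components,
                 tr = set$tr), class = "windowed_fnc")
}

#' @export
print.windowed_fnc <- function(x, ...) {
  cat(sprintf("windowed_fnc: %d subjects, %d windows x %d pairs (width %d, step %d)\n",
              length(x$z), nrow(x$z[[1]]), length(x$pairs),
              x$window_params$width, x$window_params$step))
  invisible(x)
}

# taper-weighted per-window motion summaries: mean FD and mean absolute
# derivative of each motion parameter
window_motion_summaries <- function(motion, starts, width, taper) {
  fd <- motion$fd
  dpar <- rbind(0, abs(diff(motion$params)))
  M <- matrix(NA_real_, length(starts), 1 + ncol(dpar))
  for (k in seq_along(starts)) {
    idx <- starts[k] + seq_len(width)
    M[k, 1] <- sum(taper * fd[idx])
    M[k, -1] <- colSums(taper * dpar[idx, , drop = FALSE])
  }
  colnames(M) <- c("fd", paste0("d_", colnames(motion$params)))
  M
}

#' Regress motion from windowed connectivity
#'
#' For each subject and component pair, the window series of z-values is
#' residualized by ordinary least squares (intercept restored, so the
#' subject's mean level is preserved) against per-window motion
#' summaries: the taper-weighted mean framewise displacement and the
#' taper-weighted mean absolute derivative of each of the six motion
#' parameters. Constant regressors are dropped with a warning; if all
#' regressors are constant (e.g. zero motion) the input is returned
#' unchanged.
#'
#' @param wfnc `windowed_fnc`.
#' @param set the `timecourse_set` carrying the motion traces.
#' @return `windowed_fnc` with motion-residualized z-values.
#' @export
regress_motion_from_windows <- function(wfnc, set) {
  stopifnot(inherits(wfnc, "windowed_fnc"), inherits(set, "timecourse_set"))
  if (is.null(set$motion)) stop("set has no motion traces")
  width <- wfnc$window_params$width
  for (i in seq_along(wfnc$z)) {
    M <- window_motion_summaries(set$motion[[i]], wfnc$starts, width,
                                 wfnc$taper)
    keep <- apply(M, 2, function(v) sd(v) > 0)
    if (!all(keep))
      warning(sprintf("subject %s: constant motion regressor(s) dropped: %s",
                      set$subjects$subject_id[i],
                      paste(colnames(M)[!keep], collapse = ", ")))
    if (!any(keep)) next
    Mk <- scale(M[, keep, drop = FALSE], scale = FALSE)
    Q <- qr(cbind(1, Mk))
    Z <- wfnc$z[[i]]
    wfnc$z[[i]] <- qr.resid(Q, Z) +
      matrix(colMeans(Z), nrow(Z), ncol(Z), byrow = TRUE)
  }
  wfnc
}
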