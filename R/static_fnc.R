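#' Static functional network connectivity matrix
#'
#' Pairwise Pearson correlation of conditioned component time courses,
#' Fisher z-transformed. Correlations are clipped to +/-(1 - 1e-7) before
#' the transform so every entry is finite; the diagonal is 0 by
#' convention. A constant component yields zero correlations (with a
#' warning) rather than NAs.
#'
#' @param tc T x C matrix of conditioned time courses (T >= 3).
#' @return C x C symmetric matrix of Fisher-z values, class `fnc_matrix`.
#' @export
compute_fnc <- function(tc) {
  tc <- as.matrix(tc)
  if (nrow(tc) < 3) stop("need at least 3 time points")
  sds <- apply(tc, 2, sd)
  const <- sds == 0
  if (any(const))
    warning(sprintf("constant component(s) %s: correlations set to 0",
                    paste(which(const), collapse = ", ")))
  r <- suppressWarnings(cor(tc))
  r[const, ] <- 0
  r[, const] <- 0
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  if (!is.null(colnames(tc))) dimnames(z) <- list(colnames(tc), colnames(tc))
  class(z) <- c("fnc_matrix", class(z))
  z
}

#' Subject-by-pair static FNC feature matrix
#'
#' @param set conditioned `timecourse_set`.
#' @return n_subjects x n_pairs matrix of Fisher-z values; columns labeled
#'   "compA|compB" over the upper triangle.
#' @export
fnc_feature_matrix <- function(set) {
  stopifnot(inherits(set, "timecourse_set"))
  pairs <- upper_pairs(set$components)
  F <- t(vapply(set$timecourses,
                function(m) vec_upper(unclass(compute_fnc(m))),
                numeric(length(pairs$label))))
  colnames(F) <- pairs$label
  rownames(F) <- set$subjects$subject_id
  F
}

# Pillai-trace F-approximation for a rank-q hypothesis on a d-variate
# multivariate linear model. E = error SSCP, H = hypothesis SSCP, nu =
# error df.
pillai_f_test <- function(H, E, q, nu) {
  d <- nrow(E)
  V <- sum(diag(H %*% solve(H + E)))
  s <- min(q, d)
  m <- (abs(q - d) - 1) / 2
  np <- (nu - d - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * np + s + 1)
  Fstat <- (df2 / df1) * V / (s - V)
  list(pillai = V, F = Fstat, df1 = df1, df2 = df2,
       p = pf(Fstat, df1, df2, lower.tail = FALSE))
}

# partial Pillai test for each column of X (adjusting for the others) on
# multivariate response Y; intercept always included
partial_pillai <- function(Y, X) {
  n <- nrow(Y)
  Xf <- cbind(`(Intercept)` = 1, X)
  qrf <- qr(Xf)
  if (qrf$rank < ncol(Xf)) stop("design matrix is rank deficient")
  Rf <- qr.resid(qrf, Y)
  E <- crossprod(Rf)
  nu <- n - qrf$rank
  out <- lapply(seq_len(ncol(X)), function(j) {
    Xr <- Xf[, -(j + 1), drop = FALSE]
    Rr <- qr.resid(qr(Xr), Y)
    H <- crossprod(Rr) - E
    pillai_f_test(H, E, q = 1, nu = nu)
  })
  names(out) <- colnames(X)
  out
}

#' Backward step-wise multivariate selection on FNC features
#'
#' Features are column-standardized and projected onto principal axes
#' retaining `variance_kept` of the variance; each candidate predictor
#' then receives a partial multivariate test (Pillai-trace
#' F-approximation, adjusting for the other predictors) on the reduced
#' response. The least significant predictor is removed iteratively until
#' every survivor passes BH-FDR at `alpha`.
#'
#' @param features subjects x features numeric matrix.
#' @param design data.frame or matrix of candidate predictors (e.g. age,
#'   diagnosis 0/1, mean FD, RMS motion); no missing values.
#' @param alpha FDR level (default 0.05).
#' @param variance_kept fraction of feature variance retained by the
#'   principal-axis reduction (default 0.95).
#' @return list with `retained` (character vector), `steps` (per-step
#'   trace: predictor p-values and the removal at each step), `tests`
#'   (final per-predictor statistics), `n_dims` (reduced dimension), and
#'   `dropped_constant` (predictors removed up front).
#' @export
mancova_backward_select <- function(features, design, alpha = 0.05,
                                    variance_kept = 0.95) {
  features <- as.matrix(features)
  X <- as.matrix(as.data.frame(design))
  storage.mode(X) <- "double"
  if (anyNA(features) || anyNA(X)) stop("missing values are not allowed")
  n <- nrow(features)
  if (nrow(X) != n) stop("design rows must match feature rows")

  const <- apply(X, 2, function(v) sd(v) == 0)
  dropped <- colnames(X)[const]
  if (any(const)) {
    warning(sprintf("constant predictor(s) removed: %s",
                    paste(dropped, collapse = ", ")))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no non-constant predictors")

  keep_f <- apply(features, 2, sd) > 0
  Fstd <- scale(features[, keep_f, drop = FALSE])
  sv <- svd(Fstd)
  varexp <- cumsum(sv$d^2) / sum(sv$d^2)
  d <- which(varexp >= variance_kept)[1]
  d <- min(d, n - ncol(X) - 2)   # keep residual df for the F approximation
  if (d < 1) stop("too few subjects for the requested reduced dimension")
  Y <- sv$u[, seq_len(d), drop = FALSE] %*% diag(sv$d[seq_len(d)], d)

  current <- colnames(X)
  steps <- NULL
  repeat {
    tests <- partial_pillai(Y, X[, current, drop = FALSE])
    p <- vapply(tests, `[[`, numeric(1), "p")
    p_adj <- p.adjust(p, "BH")
    worst <- which.max(p_adj)
    action <- if (max(p_adj) > alpha && length(current) > 0)
      current[worst] else NA_character_
    steps <- rbind(steps, data.frame(
      step = if (is.null(steps)) 1L else max(steps$step) + 1L,
      predictor = current, p = p, p_adj = p_adj,
      removed = current == ifelse(is.na(action), "", action),
      row.names = NULL))
    if (is.na(action)) break
    current <- setdiff(current, action)
    if (length(current) == 0) {
      tests <- list()
      break
    }
  }
  list(retained = current, steps = steps, tests = tests, n_dims = d,
       variance_explained = varexp[d], dropped_constant = dropped)
}

#' Univariate follow-up tests for one retained predictor
#'
#' For each feature, a partial F-test compares the model with all retained
#' predictors against the model without `target`; the effect direction is
#' the sign of the target's coefficient. P-values are BH-FDR adjusted
#' across features.
#'
#' @param features subjects x features matrix.
#' @param design design matrix/data.frame restricted to the retained
#'   predictors (must include `target`).
#' @param target name of the predictor under test.
#' @param alpha FDR level used for the `significant` flag.
#' @return data.frame with one row per feature: estimate, F, df1, df2,
#'   p, p_adj, direction, significant.
#' @export
univariate_effects <- function(features, design, target, alpha = 0.05) {
  features <- as.matrix(features)
  X <- as.matrix(as.data.frame(design))
  storage.mode(X) <- "double"
  if (!target %in% colnames(X)) stop("target must be among the design columns")
  n <- nrow(features)
  Xf <- cbind(`(Intercept)` = 1, X)
  Xr <- Xf[, setdiff(colnames(Xf), target), drop = FALSE]
  qf <- qr(Xf)
  qr_ <- qr(Xr)
  dff <- n - qf$rank
  tcol <- which(colnames(Xf) == target)
  res <- apply(features, 2, function(y) {
    cf <- qr.coef(qf, y)
    rf <- sum(qr.resid(qf, y)^2)
    rr <- sum(qr.resid(qr_, y)^2)
    Fstat <- (rr - rf) / (rf / dff)
    c(estimate = unname(cf[tcol]), F = Fstat,
      p = pf(Fstat, 1, dff, lower.tail = FALSE))
  })
  out <- data.frame(feature = colnames(features),
                    estimate = res["estimate", ],
                    F = res["F", ], df1 = 1, df2 = dff,
                    p = res["p", ],
                    p_adj = p.adjust(res["p", ], "BH"),
                    row.names = NULL)
  out$direction <- ifelse(out$estimate >= 0, "positive", "negative")
  out$significant <- out$p_adj < alpha
  out
}
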