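#' Automatic two-group test selection
#'
#' Continuous data: if the Shapiro-Wilk test rejects normality (p < .05)
#' in either group, a Mann-Whitney U test is run; otherwise an F-test of
#' variance homogeneity decides between the Welch and Student t-test.
#' Categorical data (a contingency matrix, or a pair of factors) gets a
#' Pearson chi-square test without continuity correction. The decision
#' rule and its intermediate p-values are returned.
#'
#' @param x,y numeric vectors (one per group, each n >= 3), or for the
#'   categorical branch a 2-column contingency matrix in `x` (leave `y`
#'   missing) or two factors.
#' @return one-row data.frame (a "stat result"): test, statistic, df,
#'   p, p_corrected (NA until corrected), correction, direction, plus a
#'   `decision` attribute logging the gate p-values.
#' @export
choose_and_run_test <- function(x, y = NULL) {
  if (is.matrix(x) || is.table(x)) {
    ct <- chisq.test(x, correct = FALSE)
    return(stat_result("chi-square", unname(ct$statistic),
                       unname(ct$parameter), ct$p.value))
  }
  if (is.factor(x) || is.character(x)) {
    ct <- chisq.test(table(x, y), correct = FALSE)
    return(stat_result("chi-square", unname(ct$statistic),
                       unname(ct$parameter), ct$p.value))
  }
  if (length(x) < 3 || length(y) < 3)
    stop("each group needs at least 3 observations")
  if (sd(x) == 0 && sd(y) == 0)
    stop("both groups are constant; no test is applicable")
  sw_x <- tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
  sw_y <- tryCatch(shapiro.test(y)$p.value, error = function(e) 0)
  decision <- list(shapiro_x = sw_x, shapiro_y = sw_y, var_test = NA_real_)
  if (min(sw_x, sw_y) < 0.05) {
    wt <- wilcox.test(x, y, exact = FALSE)
    res <- stat_result("mann-whitney", unname(wt$statistic), NA_real_,
                       wt$p.value,
                       direction = sign(median(x) - median(y)))
  } else {
    vt <- var.test(x, y)
    decision$var_test <- vt$p.value
    flavor <- if (vt$p.value < 0.05) "welch" else "student"
    tt <- t.test(x, y, var.equal = flavor == "student")
    res <- stat_result(paste0(flavor, "-t"), unname(tt$statistic),
                       unname(tt$parameter), tt$p.value,
                       direction = sign(mean(x) - mean(y)))
  }
  attr(res, "decision") <- decision
  res
}

stat_result <- function(test, statistic, df, p, p_corrected = NA_real_,
                        correction = NA_character_, direction = NA_real_) {
  data.frame(test = test, statistic = statistic, df = df, p = p,
             p_corrected = p_corrected, correction = correction,
             direction = c("negative", "none", "positive",
                           NA)[match(direction, c(-1, 0, 1, NA))],
             stringsAsFactors = FALSE)
}

#' Two-sample t-test from printed group summaries
#'
#' Computes a pooled-variance (Student) or Welch t statistic from group
#' means, SDs, and sizes — the form needed to recompute the statistics
#' printed in a demographics table. Degrees of freedom follow the flavor
#' (Welch-Satterthwaite for `"welch"`).
#'
#' @param mean1,sd1,n1 group-1 summary (sd > 0, n >= 2).
#' @param mean2,sd2,n2 group-2 summary.
#' @param flavor `"student"` or `"welch"`.
#' @return one-row stat-result data.frame.
#' @export
summary_stat_tests <- function(mean1, sd1, n1, mean2, sd2, n2,
                               flavor = c("student", "welch")) {
  flavor <- match.arg(flavor)
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  if (flavor == "student") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  stat_result(paste0(flavor, "-t"), t, df,
              2 * pt(abs(t), df, lower.tail = FALSE),
              direction = sign(mean1 - mean2))
}

#' Shapiro-Wilk-gated Box-Cox transformation
#'
#' If the sample passes the Shapiro-Wilk test (p >= .05) the identity is
#' returned with no lambda. Otherwise values are shifted to positivity
#' when needed (by `1 - min(x)`), lambda is chosen by profile maximum
#' likelihood, and the transform `(x^lambda - 1)/lambda` (or `log x` at
#' lambda = 0) applied.
#'
#' @param x numeric vector, n >= 8, non-constant.
#' @return list of class `transform_result`: `lambda` (NA when the gate
#'   passes), `shift`, `transformed`, `shapiro_before`, `shapiro_after`.
#' @export
boxcox_if_nonnormal <- function(x) {
  if (length(x) < 8) stop("need at least 8 observations")
  if (sd(x) == 0) stop("zero-variance input")
  sw_before <- shapiro.test(x)$p.value
  if (sw_before >= 0.05) {
    return(structure(list(lambda = NA_real_, shift = 0, transformed = x,
                          shapiro_before = sw_before,
                          shapiro_after = sw_before),
                     class = "transform_result"))
  }
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  xs <- x + shift
  bc <- MASS::boxcox(xs ~ 1, lambda = seq(-3, 3, 0.01), plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  y <- boxcox_transform(xs, lambda)
  structure(list(lambda = lambda, shift = shift, transformed = y,
                 shapiro_before = sw_before,
                 shapiro_after = shapiro.test(y)$p.value),
            class = "transform_result")
}

#' Box-Cox power transform at a given lambda
#'
#' `(x^lambda - 1)/lambda` for lambda != 0, `log(x)` at lambda = 0;
#' requires positive input.
#'
#' @param x positive numeric vector.
#' @param lambda power parameter.
#' @export
boxcox_transform <- function(x, lambda) {
  if (any(x <= 0)) stop("Box-Cox transform requires positive values")
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Partial correlation with nuisance covariates
#'
#' Residualizes `x` and `y` on the nuisance columns (with intercept) by
#' least squares and correlates the residuals; for the Spearman flavor
#' all variables are rank-transformed first. The p-value comes from a
#' t-distribution with `n - k - 2` degrees of freedom (k nuisance
#' columns).
#'
#' @param x,y numeric vectors.
#' @param nuisance vector, matrix, or data.frame of nuisance covariates
#'   (may be NULL for a plain correlation).
#' @param flavor `"pearson"` or `"spearman"`.
#' @return one-row stat-result data.frame with the partial r as
#'   `statistic` and an `r` column.
#' @export
partial_correlation <- function(x, y, nuisance = NULL,
                                flavor = c("pearson", "spearman")) {
  flavor <- match.arg(flavor)
  n <- length(x)
  stopifnot(length(y) == n)
  Z <- if (is.null(nuisance)) matrix(numeric(0), n, 0)
       else as.matrix(as.data.frame(nuisance))
  k <- ncol(Z)
  if (n <= k + 2) stop("need n > number of nuisance covariates + 2")
  if (flavor == "spearman") {
    x <- rank(x)
    y <- rank(y)
    if (k > 0) Z <- apply(Z, 2, rank)
  }
  X <- cbind(1, Z)
  qx <- qr(X)
  rx <- qr.resid(qx, x)
  ry <- qr.resid(qx, y)
  if (sd(rx) < 1e-12 * sd(x) || sd(ry) < 1e-12 * sd(y))
    stop("nuisance covariates are collinear with x or y")
  r <- cor(rx, ry)
  df <- n - k - 2
  t <- r * sqrt(df / (1 - r^2))
  res <- stat_result(paste0("partial-", flavor), r, df,
                     2 * pt(abs(t), df, lower.tail = FALSE),
                     direction = sign(r))
  res$r <- r
  res
}

#' Dubey/Armitage-Parmar effective-number-of-tests Bonferroni correction
#'
#' For endpoint j with mean absolute correlation `rbar_j` to the other
#' endpoints (clamped to \[0, 1\]), the effective number of tests is
#' `m_eff_j = m^(1 - rbar_j)` and the corrected p-value
#' `1 - (1 - p_j)^m_eff_j`, capped at 1. Perfectly correlated endpoints
#' (rbar = 1) leave p unchanged; independent endpoints (rbar = 0) give
#' the Sidak correction.
#'
#' @param pvals raw p-values (length m).
#' @param R m x m endpoint correlation matrix.
#' @return data.frame: p, rbar, m_eff, p_corrected.
#' @export
dap_bonferroni <- function(pvals, R) {
  m <- length(pvals)
  R <- as.matrix(R)
  if (nrow(R) != m || ncol(R) != m)
    stop("correlation matrix dimension must equal the number of endpoints")
  if (m == 1)
    return(data.frame(p = pvals, rbar = 1, m_eff = 1, p_corrected = pvals))
  rbar <- vapply(seq_len(m),
                 function(j) mean(abs(R[j, -j])), numeric(1))
  rbar <- pmin(pmax(rbar, 0), 1)
  m_eff <- m^(1 - rbar)
  # -expm1(m log1p(-p)) = 1 - (1-p)^m, accurate down to p ~ 1e-300
  data.frame(p = pvals, rbar = rbar, m_eff = m_eff,
             p_corrected = pmin(1, -expm1(m_eff * log1p(-pvals))))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvals raw p-values in \[0, 1\].
#' @param q FDR level for the rejection set.
#' @return list with `adjusted` (BH step-up adjusted p-values) and
#'   `reject` (logical).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1)) stop("p-values must be in [0, 1]")
  adj <- p.adjust(pvals, "BH")
  list(adjusted = adj, reject = adj <= q)
}

#' Bonferroni family-wise-error correction
#'
#' @param pvals raw p-values.
#' @return corrected p-values `min(1, m * p)`.
#' @export
bonferroni_fwe <- function(pvals) {
  pmin(1, length(pvals) * pvals)
}

#' Brain-behavior partial correlations with DAP correction
#'
#' Correlates one clinical score with each of several dynamism metrics by
#' partial correlation (shared nuisance covariates), then applies the
#' Dubey/Armitage-Parmar correction using the empirical correlation
#' matrix of the metrics. Scores failing the Shapiro-Wilk gate are
#' Box-Cox transformed first.
#'
#' @param score numeric clinical score (e.g. positive symptoms).
#' @param metrics data.frame or matrix of dynamism metrics (columns are
#'   the endpoints).
#' @param nuisance nuisance covariates (e.g. chlorpromazine equivalents).
#' @param flavor correlation flavor passed to [partial_correlation].
#' @param boxcox_gate apply [boxcox_if_nonnormal] to the score first.
#' @return data.frame: metric, r, p, rbar, m_eff, p_corrected, direction.
#' @export
brain_behavior_correlations <- function(score, metrics, nuisance = NULL,
                                        flavor = c("spearman", "pearson"),
                                        boxcox_gate = TRUE) {
  flavor <- match.arg(flavor)
  M <- as.matrix(as.data.frame(metrics))
  if (boxcox_gate) score <- boxcox_if_nonnormal(score)$transformed
  res <- lapply(seq_len(ncol(M)), function(j)
    partial_correlation(score, M[, j], nuisance, flavor))
  p <- vapply(res, `[[`, numeric(1), "p")
  r <- vapply(res, `[[`, numeric(1), "r")
  corr <- dap_bonferroni(p, cor(M))
  data.frame(metric = colnames(M), r = r, p = p,
             rbar = corr$rbar, m_eff = corr$m_eff,
             p_corrected = corr$p_corrected,
             direction = ifelse(r >= 0, "positive", "negative"),
             row.names = NULL)
}
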