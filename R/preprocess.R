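#' Preprocessing parameters
#'
#' @param max_translation QC ceiling on maximum absolute translation (mm).
#' @param max_rotation QC ceiling on maximum absolute rotation (degrees).
#' @param despike_c1,despike_c2 despiking compression constants in MAD
#'   multiples; residuals below `c1` MADs pass unchanged, larger ones are
#'   compressed towards `c2` (requires `c2 > c1 > 0`).
#' @param filter_order Butterworth low-pass order.
#' @param filter_cutoff low-pass cutoff (Hz); must lie below Nyquist.
#' @param taper_time_bandwidth multitaper time-bandwidth product NW.
#' @param taper_count number of Slepian tapers (at most `2 NW - 1`).
#' @return list of class `preprocess_params`.
#' @export
preprocess_params <- function(max_translation = 3.0, max_rotation = 3.0,
                              despike_c1 = 2.5, despike_c2 = 4.0,
                              filter_order = 5, filter_cutoff = 0.15,
                              taper_time_bandwidth = 3, taper_count = 5) {
  if (!(despike_c2 > despike_c1 && despike_c1 > 0))
    stop("need despike_c2 > despike_c1 > 0")
  if (filter_order < 1) stop("filter_order must be >= 1")
  if (filter_cutoff <= 0) stop("filter_cutoff must be positive")
  if (taper_count > 2 * taper_time_bandwidth - 1)
    stop("taper_count must be at most 2 * taper_time_bandwidth - 1")
  structure(list(max_translation = max_translation,
                 max_rotation = max_rotation,
                 despike_c1 = despike_c1, despike_c2 = despike_c2,
                 filter_order = filter_order, filter_cutoff = filter_cutoff,
                 taper_time_bandwidth = taper_time_bandwidth,
                 taper_count = taper_count), class = "preprocess_params")
}

#' Exclude subjects for excessive head motion
#'
#' A subject is removed when any motion parameter exceeds the ceiling:
#' maximum absolute translation strictly greater than `max_translation` mm
#' or maximum absolute rotation strictly greater than `max_rotation`
#' degrees. Motion exactly at the ceiling is kept. Subjects without a
#' motion trace are flagged in the report and excluded rather than
#' silently kept.
#'
#' @param set `timecourse_set` with motion traces.
#' @param params `preprocess_params`.
#' @return list with `kept` (filtered `timecourse_set`) and `report`
#'   (data.frame: subject_id, reason, axis, value).
#' @export
qc_exclude <- function(set, params = preprocess_params()) {
  stopifnot(inherits(set, "timecourse_set"))
  n <- n_subjects(set)
  report <- data.frame(subject_id = character(0), reason = character(0),
                       axis = character(0), value = numeric(0),
                       stringsAsFactors = FALSE)
  drop <- logical(n)
  for (i in seq_len(n)) {
    m <- if (is.null(set$motion)) NULL else set$motion[[i]]
    sid <- set$subjects$subject_id[i]
    if (is.null(m)) {
      drop[i] <- TRUE
      report <- rbind(report, data.frame(subject_id = sid,
                                         reason = "missing_motion_trace",
                                         axis = NA_character_,
                                         value = NA_real_))
      next
    }
    mx <- apply(abs(m$params), 2, max)
    bad_t <- which(mx[1:3] > params$max_translation)
    bad_r <- which(mx[4:6] > params$max_rotation)
    if (length(bad_t) || length(bad_r)) {
      drop[i] <- TRUE
      if (length(bad_t)) {
        ax <- colnames(m$params)[bad_t]
        report <- rbind(report, data.frame(subject_id = sid,
                                           reason = "max_translation",
                                           axis = ax, value = mx[bad_t]))
      }
      if (length(bad_r)) {
        ax <- colnames(m$params)[3 + bad_r]
        report <- rbind(report, data.frame(subject_id = sid,
                                           reason = "max_rotation",
                                           axis = ax, value = mx[3 + bad_r]))
      }
    }
  }
  kept <- if (all(drop)) stop("all subjects excluded by motion QC")
          else subset_subjects(set, which(!drop))
  rownames(report) <- NULL
  list(kept = kept, report = report)
}

# detrend regression basis: intercept, linear trend, and sine/cosine pairs
# at one half cycle and one full cycle over the record
detrend_basis <- function(T) {
  x <- seq(0, 1, length.out = T)
  cbind(1, x, sin(pi * x), cos(pi * x), sin(2 * pi * x), cos(2 * pi * x))
}

#' Detrend a component time course
#'
#' Removes, by least squares, the mean, the linear slope, and sine/cosine
#' pairs with one half cycle and one full cycle over the record.
#'
#' @param tc numeric vector (one component's series), length >= 7.
#' @return residual series of the same length.
#' @export
detrend_timecourse <- function(tc) {
  T <- length(tc)
  if (T < 7) stop("need at least 7 time points (6 regressors)")
  X <- detrend_basis(T)
  lm.fit(X, tc)$residuals
}

#' Despike a time course by MAD-gated compression
#'
#' Residuals from a smooth fit (the detrend basis) with magnitude at most
#' `c1` sigma_MAD are unchanged; larger residuals are compressed to
#' `c1 + (c2 - c1) * tanh((|r|/sigma - c1)/(c2 - c1))` MAD units with the
#' sign preserved, then re-added to the smooth fit. `sigma_MAD` is the
#' sqrt(pi/2)-scaled median absolute residual (the 3dDespike convention).
#' A constant-residual series (`sigma_MAD = 0`) is returned unchanged.
#'
#' @param tc numeric series, length >= 8.
#' @param c1,c2 compression constants (MAD multiples), `c2 > c1 > 0`.
#' @return despiked series, same length.
#' @export
despike_timecourse <- function(tc, c1 = 2.5, c2 = 4.0) {
  T <- length(tc)
  if (T < 8) stop("need at least 8 time points")
  if (!(c2 > c1 && c1 > 0)) stop("need c2 > c1 > 0")
  X <- detrend_basis(T)
  fit <- lm.fit(X, tc)
  smooth <- tc - fit$residuals
  r <- fit$residuals
  sigma <- sqrt(pi / 2) * median(abs(r))
  if (sigma == 0) return(tc)
  s <- abs(r) / sigma
  comp <- ifelse(s <= c1, s, c1 + (c2 - c1) * tanh((s - c1) / (c2 - c1)))
  smooth + sign(r) * comp * sigma
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward application of an order-`order` Butterworth low-pass
#' filter, so the effective magnitude response is the squared single-pass
#' response and the phase response is zero. DC gain is 1.
#'
#' @param tc numeric series.
#' @param tr repetition time (s).
#' @param order filter order (default 5).
#' @param cutoff high-frequency cutoff in Hz; must be below Nyquist.
#' @return filtered series, same length.
#' @export
lowpass_filter <- function(tc, tr, order = 5, cutoff = 0.15) {
  nyq <- 0.5 / tr
  if (cutoff >= nyq)
    stop(sprintf("cutoff %.4g Hz must be below the Nyquist frequency %.4g Hz",
                 cutoff, nyq))
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  # odd (antisymmetric) edge extension so the forward-backward pass is
  # transient-free at the record boundaries
  n <- length(tc)
  # long enough for the zero-state transient to decay below ~1e-9
  pad <- min(n - 1, ceiling(25 * nyq / cutoff) + 6 * order)
  pre <- 2 * tc[1] - tc[(pad + 1):2]
  post <- 2 * tc[n] - tc[(n - 1):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, tc, post)))
  y[(pad + 1):(pad + n)]
}

# Discrete prolate spheroidal (Slepian) tapers via the standard symmetric
# tridiagonal eigenproblem; columns normalized to unit energy, sign fixed
# so each taper's mean lobe is non-negative.
dpss_tapers <- function(n, nw, k) {
  stopifnot(k >= 1, k <= 2 * nw - 1, n > k)
  w <- nw / n
  t <- 0:(n - 1)
  md <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  od <- t[-1] * (n - t[-1]) / 2
  A <- diag(md)
  A[cbind(1:(n - 1), 2:n)] <- od
  A[cbind(2:n, 1:(n - 1))] <- od
  e <- eigen(A, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    V[, j] <- V[, j] / sqrt(sum(V[, j]^2))
    if (sum(V[, j]) < 0) V[, j] <- -V[, j]
  }
  V
}

#' Multitaper power spectrum
#'
#' Average of periodograms computed with discrete prolate spheroidal
#' (Slepian) tapers. One-sided spectrum; with the default scaling the
#' integral of power over frequency approximates the series variance.
#'
#' @param tc numeric series (demeaned internally).
#' @param tr repetition time (s).
#' @param time_bandwidth time-bandwidth product NW (default 3).
#' @param n_tapers number of tapers (default 5; at most `2 NW - 1`).
#' @return list with `freq` (Hz) and `power`.
#' @export
multitaper_spectrum <- function(tc, tr, time_bandwidth = 3, n_tapers = 5) {
  if (n_tapers > 2 * time_bandwidth - 1)
    stop(sprintf("n_tapers = %d exceeds the valid count 2*NW - 1 = %d",
                 n_tapers, 2 * time_bandwidth - 1))
  T <- length(tc)
  x <- tc - mean(tc)
  V <- dpss_tapers(T, time_bandwidth, n_tapers)
  nfreq <- floor(T / 2) + 1
  P <- matrix(0, nfreq, n_tapers)
  for (j in seq_len(n_tapers)) {
    ft <- fft(V[, j] * x)
    P[, j] <- Mod(ft[seq_len(nfreq)])^2 * tr
  }
  pow <- rowMeans(P)
  # one-sided doubling (all bins except DC and, for even T, Nyquist)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (T %% 2 == 0) dbl[nfreq] <- 1
  pow <- pow * dbl
  freq <- (seq_len(nfreq) - 1) / (T * tr)
  list(freq = freq, power = pow)
}

#' Condition every time course in a set
#'
#' Applies, per subject and component, the pipeline detrend -> despike ->
#' low-pass filter.
#'
#' @param set `timecourse_set`.
#' @param params `preprocess_params`.
#' @return conditioned `timecourse_set`.
#' @export
preprocess_timecourses <- function(set, params = preprocess_params()) {
  stopifnot(inherits(set, "timecourse_set"))
  out <- lapply(set$timecourses, function(m) {
    apply(m, 2, function(x) {
      x <- detrend_timecourse(x)
      x <- despike_timecourse(x, params$despike_c1, params$despike_c2)
      lowpass_filter(x, set$tr, params$filter_order, params$filter_cutoff)
    })
  })
  timecourse_set(out, tr = set$tr, subjects = set$subjects,
                 motion = set$motion)
}
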