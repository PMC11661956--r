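#' Construct planted connectivity states
#'
#' Builds a set of component-correlation matrices with block structure, used
#' as the ground-truth "states" of the hidden-Markov switching simulator.
#' State `s` has correlation `within[s]` inside each block and `between[s]`
#' across blocks, with unit diagonal.
#'
#' @param n_states number of states (>= 1).
#' @param n_components number of components C (>= 2).
#' @param block_sizes integer vector of block sizes summing to
#'   `n_components`; default splits the components into three near-equal
#'   blocks.
#' @param within within-block correlation level per state (recycled to
#'   `n_states`); each in (-1, 1).
#' @param between between-block correlation level per state (recycled);
#'   each in (-1, 1).
#' @param labels optional state labels.
#' @return An object of class `planted_states`: a list with elements
#'   `states` (list of C x C correlation matrices), `labels`,
#'   `block_sizes`, and `min_pairwise_l1`, the minimum city-block distance
#'   between the vectorized upper triangles of any two states (a
#'   separability diagnostic).
#' @examples
#' ps <- make_planted_states(3, 10)
#' ps$min_pairwise_l1
#' @export
make_planted_states <- function(n_states, n_components,
                                block_sizes = NULL,
                                within = c(0.75, 0.55, 0.1),
                                between = c(-0.35, 0.4, 0),
                                labels = NULL) {
  stopifnot(n_states >= 1, n_components >= 2)
  if (is.null(block_sizes)) {
    nb <- min(3L, n_components)
    block_sizes <- diff(round(seq(0, n_components, length.out = nb + 1)))
  }
  if (sum(block_sizes) != n_components)
    stop("block_sizes must sum to n_components")
  within <- rep_len(within, n_states)
  between <- rep_len(between, n_states)
  if (any(abs(within) >= 1) || any(abs(between) >= 1))
    stop("correlation levels must lie in (-1, 1)")
  if (is.null(labels)) labels <- paste0("S", seq_len(n_states))

  block_id <- rep(seq_along(block_sizes), block_sizes)
  states <- vector("list", n_states)
  for (s in seq_len(n_states)) {
    same <- outer(block_id, block_id, "==")
    R <- ifelse(same, within[s], between[s])
    diag(R) <- 1
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10)
      stop(sprintf(paste0("state %d (within = %.3g, between = %.3g, blocks = %s)",
                          " is not positive definite (min eigenvalue %.3g)"),
                   s, within[s], between[s],
                   paste(block_sizes, collapse = ","), min(ev)))
    states[[s]] <- R
  }

  d <- NA_real_
  if (n_states > 1) {
    vs <- vapply(states, vec_upper, numeric(n_components * (n_components - 1) / 2))
    pr <- utils::combn(n_states, 2)
    d <- min(apply(pr, 2, function(ij) sum(abs(vs[, ij[1]] - vs[, ij[2]]))))
  }
  structure(list(states = states, labels = labels,
                 block_sizes = block_sizes, within = within,
                 between = between, min_pairwise_l1 = d),
            class = "planted_states")
}

#' Row-stochastic transition model for the hidden state chain
#'
#' @param transition_matrix S x S row-stochastic matrix.
#' @param initial_distribution length-S probability vector (default
#'   uniform).
#' @return `transition_model` object.
#' @export
transition_model <- function(transition_matrix, initial_distribution = NULL) {
  P <- as.matrix(transition_matrix)
  if (nrow(P) != ncol(P)) stop("transition matrix must be square")
  if (any(P < 0) || any(P > 1)) stop("transition probabilities must be in [0, 1]")
  if (any(abs(rowSums(P) - 1) > 1e-12)) stop("transition matrix rows must sum to 1")
  S <- nrow(P)
  if (is.null(initial_distribution)) initial_distribution <- rep(1 / S, S)
  if (length(initial_distribution) != S ||
      abs(sum(initial_distribution) - 1) > 1e-12 ||
      any(initial_distribution < 0))
    stop("initial_distribution must be a length-S probability vector")
  structure(list(transition_matrix = P,
                 initial_distribution = initial_distribution),
            class = "transition_model")
}

#' Sticky transition model with given self-transition probabilities
#'
#' Convenience constructor: state `s` stays with probability `stay[s]` and
#' leaves to each other state with equal probability. Expected dwell length
#' of state s is 1 / (1 - stay[s]) TRs.
#'
#' @param stay vector of self-transition probabilities in (0, 1].
#' @return `transition_model` object.
#' @export
sticky_transition <- function(stay) {
  S <- length(stay)
  stopifnot(S >= 1, all(stay > 0), all(stay <= 1))
  P <- matrix(0, S, S)
  for (s in seq_len(S)) {
    P[s, ] <- if (S == 1) 1 else (1 - stay[s]) / (S - 1)
    P[s, s] <- stay[s]
  }
  transition_model(P)
}

#' Artifact specification for the subject simulator
#'
#' @param drift_amplitude peak amplitude of the linear drift, in units of
#'   the (unit) state-signal SD over the whole record.
#' @param sine_amplitude amplitude of a low-frequency sinusoidal trend
#'   (same units); `sine_period_s` is its period in seconds.
#' @param sine_period_s period of the sinusoidal trend (seconds).
#' @param spike_rate per-TR, per-component probability of an additive spike.
#' @param spike_magnitude spike magnitude in multiples of the series median
#'   absolute deviation (so despiking efficacy is directly assertable).
#' @param noise_sd SD of additive white observation noise.
#' @param ar_coef lag-1 autoregressive coefficient of the network signal
#'   in \[0, 1): hemodynamic network time courses are slow, with power
#'   concentrated below the usual 0.15 Hz low-pass cutoff; the AR(1)
#'   innovation structure reproduces that band-limited character while
#'   leaving the stationary cross-component correlation exactly equal to
#'   the active state's matrix. 0 gives a temporally white signal.
#' @return list of class `artifact_spec`.
#' @export
artifact_spec <- function(drift_amplitude = 0.5, sine_amplitude = 0.3,
                          sine_period_s = 90, spike_rate = 0.01,
                          spike_magnitude = 6, noise_sd = 0.3,
                          ar_coef = 0.7) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (spike_rate < 0 || spike_rate > 1) stop("spike_rate must be in [0, 1]")
  if (ar_coef < 0 || ar_coef >= 1) stop("ar_coef must be in [0, 1)")
  structure(list(drift_amplitude = drift_amplitude,
                 sine_amplitude = sine_amplitude,
                 sine_period_s = sine_period_s,
                 spike_rate = spike_rate,
                 spike_magnitude = spike_magnitude,
                 noise_sd = noise_sd, ar_coef = ar_coef),
            class = "artifact_spec")
}

# sample a state sequence from the Markov chain (TR resolution)
simulate_state_sequence <- function(tm, n_timepoints) {
  P <- tm$transition_matrix
  S <- nrow(P)
  seq_out <- integer(n_timepoints)
  seq_out[1] <- sample.int(S, 1, prob = tm$initial_distribution)
  for (t in seq_len(n_timepoints - 1)) {
    seq_out[t + 1] <- sample.int(S, 1, prob = P[seq_out[t], ])
  }
  seq_out
}

#' Simulate one subject's component time courses
#'
#' The hidden state follows the Markov chain at TR resolution; at each TR
#' the observation is a zero-mean multivariate normal draw with the active
#' state's correlation, plus (per `artifact`) linear drift, a low-frequency
#' sinusoidal trend, sparse spikes, and white noise.
#'
#' @param states `planted_states` object.
#' @param tm `transition_model` whose dimension matches the state count.
#' @param n_timepoints number of TRs (>= 2).
#' @param tr repetition time in seconds (> 0).
#' @param artifact `artifact_spec`; use
#'   `artifact_spec(0, 0, spike_rate = 0, noise_sd = 0)` for a clean draw.
#' @param seed integer seed; equal seeds give bitwise-identical output.
#' @return list with `tc` (n_timepoints x C matrix) and `state_seq`
#'   (integer vector of true states per TR).
#' @export
simulate_subject <- function(states, tm, n_timepoints, tr = 0.72,
                             artifact = artifact_spec(), seed = NULL) {
  stopifnot(inherits(states, "planted_states"))
  if (!inherits(tm, "transition_model")) stop("tm must be a transition_model")
  S <- length(states$states)
  if (nrow(tm$transition_matrix) != S)
    stop(sprintf("transition matrix is %d x %d but there are %d states",
                 nrow(tm$transition_matrix), ncol(tm$transition_matrix), S))
  if (n_timepoints < 2) stop("n_timepoints must be >= 2")
  if (tr <= 0) stop("tr must be positive")
  if (artifact$noise_sd < 0) stop("noise_sd must be non-negative")
  C <- ncol(states$states[[1]])

  with_seed(seed, {
    st <- simulate_state_sequence(tm, n_timepoints)
    chols <- lapply(states$states, function(R) chol(R))
    Z <- matrix(rnorm(n_timepoints * C), n_timepoints, C)
    phi <- if (is.null(artifact$ar_coef)) 0 else artifact$ar_coef
    if (phi > 0) {
      # AR(1) with unit marginal variance; the stationary cross-component
      # correlation of y_t = L[s_t] x_t remains the active state's matrix
      for (t in seq_len(n_timepoints - 1))
        Z[t + 1, ] <- phi * Z[t, ] + sqrt(1 - phi^2) * Z[t + 1, ]
    }
    Y <- matrix(0, n_timepoints, C)
    for (s in unique(st)) {
      rows <- which(st == s)
      Y[rows, ] <- Z[rows, , drop = FALSE] %*% chols[[s]]
    }
    tt <- seq_len(n_timepoints)
    if (artifact$drift_amplitude != 0) {
      slope <- runif(C, -1, 1) * artifact$drift_amplitude
      Y <- Y + outer(2 * (tt - 1) / (n_timepoints - 1) - 1, slope)
    }
    if (artifact$sine_amplitude != 0) {
      phase <- runif(C, 0, 2 * pi)
      freq <- 2 * pi * tr / artifact$sine_period_s
      Y <- Y + artifact$sine_amplitude *
        sin(outer(tt * freq, rep(1, C)) + matrix(phase, n_timepoints, C, byrow = TRUE))
    }
    if (artifact$spike_rate > 0 && artifact$spike_magnitude != 0) {
      for (cc in seq_len(C)) {
        hits <- which(runif(n_timepoints) < artifact$spike_rate)
        if (length(hits)) {
          mag <- artifact$spike_magnitude * mad(Y[, cc])
          Y[hits, cc] <- Y[hits, cc] +
            sample(c(-1, 1), length(hits), replace = TRUE) * mag
        }
      }
    }
    if (artifact$noise_sd > 0)
      Y <- Y + matrix(rnorm(n_timepoints * C, sd = artifact$noise_sd),
                      n_timepoints, C)
    colnames(Y) <- paste0("IC", seq_len(C))
    list(tc = Y, state_seq = st)
  })
}

#' Simulate a six-parameter rigid-body motion trace
#'
#' Mean-reverting random walk over 3 translations (mm) and 3 rotations
#' (degrees). `scale` multiplies the innovation SD, giving groups with
#' systematically different motion.
#'
#' @param n_timepoints TR count.
#' @param step_sd_trans,step_sd_rot innovation SDs (mm, deg per TR).
#' @param scale multiplier on both innovation SDs.
#' @param seed integer seed.
#' @return `motion_trace` object: list with `params` (T x 6 matrix,
#'   columns trans_x..rot_z), `fd` (per-TR framewise displacement, mm,
#'   first TR 0), `mean_fd`, and `rms_motion`.
#' @export
simulate_motion <- function(n_timepoints, step_sd_trans = 0.02,
                            step_sd_rot = 0.015, scale = 1, seed = NULL) {
  with_seed(seed, {
    sds <- c(rep(step_sd_trans, 3), rep(step_sd_rot, 3)) * scale
    M <- matrix(0, n_timepoints, 6)
    for (t in seq_len(n_timepoints - 1)) {
      M[t + 1, ] <- 0.95 * M[t, ] + rnorm(6, sd = sds)
    }
    colnames(M) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
    motion_trace(M)
  })
}

#' Construct a motion trace from a parameter matrix
#'
#' Framewise displacement follows the Power convention: the sum of absolute
#' frame-to-frame differences of the six parameters, with rotations
#' converted from degrees to mm of arc on a 50 mm sphere; FD at the first
#' TR is defined as 0. RMS motion is the root-mean-square Euclidean
#' translation displacement from the reference position.
#'
#' @param params T x 6 matrix (trans_x, trans_y, trans_z in mm; rot_x,
#'   rot_y, rot_z in degrees).
#' @return `motion_trace` object.
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  if (ncol(params) != 6) stop("motion parameters must have 6 columns")
  colnames(params) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  d <- abs(diff(params))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            rowSums(d[, 4:6, drop = FALSE]) * pi / 180 * 50)
  rms <- sqrt(mean(rowSums(params[, 1:3, drop = FALSE]^2)))
  structure(list(params = params, fd = fd,
                 mean_fd = mean(fd), rms_motion = rms),
            class = "motion_trace")
}

#' Cohort specification for the two-group simulator
#'
#' Defaults emulate an early-psychosis (EP) vs healthy-control (HC)
#' contrast: the EP transition model dwells longer in state 1 and the HC
#' model in the last state; EP motion innovations are scaled up so mean FD
#' is higher in EP; a symptom-like clinical score is a linear function of
#' each subject's true dynamism (hidden-chain transition count) plus
#' Gaussian noise; an antipsychotic dose column (chlorpromazine
#' equivalents) is nonzero for a fraction of EP subjects.
#'
#' @param n_ep,n_hc group sizes (>= 1).
#' @param states `planted_states`.
#' @param transition_ep,transition_hc per-group `transition_model`s.
#' @param n_timepoints,tr scan length (TRs) and repetition time (s).
#' @param artifact `artifact_spec` shared by all subjects.
#' @param score_intercept,score_coupling,score_noise_sd clinical score
#'   model: `score = intercept + coupling * zscore(true NT) + N(0, sd)`.
#'   The default coupling -1 with noise SD 1.33 gives a true
#'   score-dynamism correlation of about -0.6.
#' @param medicated_fraction fraction of EP subjects with nonzero dose.
#' @param stay_jitter SD (logit scale) of a subject-level shift applied to
#'   all self-transition probabilities: subjects genuinely differ in how
#'   fast they switch states, and this heterogeneity is what brain-behavior
#'   coupling acts on. 0 gives every subject the group transition model.
#' @param fd_scale_ep motion innovation multiplier for EP.
#' @param seed master seed; the full cohort is a pure function of this
#'   specification.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ep = 96, n_hc = 56,
                        states = make_planted_states(3, 20),
                        transition_ep = sticky_transition(c(0.995, 0.99, 0.97)),
                        transition_hc = sticky_transition(c(0.97, 0.99, 0.995)),
                        n_timepoints = 300, tr = 0.72,
                        artifact = artifact_spec(),
                        score_intercept = 15, score_coupling = -1,
                        score_noise_sd = 1.0,
                        medicated_fraction = 0.46,
                        stay_jitter = 1.0,
                        fd_scale_ep = 1.3, seed = 1L) {
  if (n_ep < 1 || n_hc < 1) stop("both group sizes must be >= 1")
  if (score_noise_sd < 0) stop("score_noise_sd must be non-negative")
  if (stay_jitter < 0) stop("stay_jitter must be non-negative")
  structure(list(n_ep = n_ep, n_hc = n_hc, states = states,
                 transition_ep = transition_ep, transition_hc = transition_hc,
                 n_timepoints = n_timepoints, tr = tr, artifact = artifact,
                 score_intercept = score_intercept,
                 score_coupling = score_coupling,
                 score_noise_sd = score_noise_sd,
                 medicated_fraction = medicated_fraction,
                 stay_jitter = stay_jitter,
                 fd_scale_ep = fd_scale_ep, seed = seed),
            class = "cohort_spec")
}

# shift all self-transition probabilities of P by delta on the logit
# scale, rescaling each row's off-diagonal mass proportionally
jitter_transition <- function(tm, delta) {
  P <- tm$transition_matrix
  d <- diag(P)
  ok <- d > 0 & d < 1
  dnew <- d
  dnew[ok] <- stats::plogis(stats::qlogis(d[ok]) + delta)
  for (s in which(ok)) {
    off <- P[s, ]
    off[s] <- 0
    P[s, ] <- off * (1 - dnew[s]) / sum(off)
    P[s, s] <- dnew[s]
  }
  transition_model(P, tm$initial_distribution)
}

#' Simulate a two-group cohort with known dynamics
#'
#' @param spec `cohort_spec`.
#' @return list with `data` (a [timecourse_set]) and `truth` (ground
#'   truth: per-subject true state sequences, true transition counts
#'   `true_nt`, true connectivity path lengths `true_path_length`
#'   (city-block distance through state-correlation space), the coupling
#'   coefficients, and the master seed).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_ep + spec$n_hc
  group <- rep(c("EP", "HC"), c(spec$n_ep, spec$n_hc))
  S <- length(spec$states$states)
  state_l1 <- matrix(0, S, S)
  for (a in seq_len(S)) for (b in seq_len(S))
    state_l1[a, b] <- sum(abs(vec_upper(spec$states$states[[a]]) -
                              vec_upper(spec$states$states[[b]])))

  with_seed(spec$seed, {
    sub_seeds <- sample.int(.Machine$integer.max, n)
    tcs <- vector("list", n)
    motions <- vector("list", n)
    seqs <- vector("list", n)
    deltas <- if (spec$stay_jitter > 0) rnorm(n, 0, spec$stay_jitter)
              else numeric(n)
    for (i in seq_len(n)) {
      tm <- if (group[i] == "EP") spec$transition_ep else spec$transition_hc
      if (deltas[i] != 0) tm <- jitter_transition(tm, deltas[i])
      sim <- simulate_subject(spec$states, tm, spec$n_timepoints, spec$tr,
                              spec$artifact, seed = sub_seeds[i])
      tcs[[i]] <- sim$tc
      seqs[[i]] <- sim$state_seq
      motions[[i]] <- simulate_motion(spec$n_timepoints,
                                      scale = if (group[i] == "EP")
                                        spec$fd_scale_ep else 1,
                                      seed = sub_seeds[i] %% 1000000L + i)
    }
    true_nt <- vapply(seqs, function(s) sum(diff(s) != 0), numeric(1))
    true_path <- vapply(seqs, function(s) {
      if (length(s) < 2) return(0)
      sum(state_l1[cbind(s[-length(s)], s[-1])])
    }, numeric(1))

    z_dyn <- as.numeric(scale(true_nt))
    if (sd(true_nt) == 0) z_dyn <- rep(0, n)
    score <- spec$score_intercept + spec$score_coupling * z_dyn +
      rnorm(n, sd = spec$score_noise_sd)

    cpz <- rep(0, n)
    ep_idx <- which(group == "EP")
    med <- ep_idx[runif(length(ep_idx)) < spec$medicated_fraction]
    cpz[med] <- rlnorm(length(med), meanlog = log(150), sdlog = 0.7)

    age <- ifelse(group == "EP", rnorm(n, 22.8, 3.9), rnorm(n, 24.8, 4.2))
    age <- pmin(pmax(age, 16), 35)

    subjects <- data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      group = group, age = round(age, 1), score = score, cpz_equiv = cpz,
      mean_fd = vapply(motions, function(m) m$mean_fd, numeric(1)),
      rms_motion = vapply(motions, function(m) m$rms_motion, numeric(1)),
      stringsAsFactors = FALSE)

    set <- timecourse_set(tcs, tr = spec$tr, subjects = subjects,
                          motion = motions)
    truth <- list(state_seq = seqs, true_nt = true_nt,
                  true_path_length = true_path,
                  score_coupling = spec$score_coupling,
                  score_noise_sd = spec$score_noise_sd,
                  seed = spec$seed)
    list(data = set, truth = truth)
  })
}
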