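# Synthetic multi-rate dFCN generator with planted discrete connectivity
# states. Every cohort (one per TR) is a downsampled view of ONE latent
# continuous-time state trajectory, so ground truth is shared across
# sampling rates — the property the clustering pipelines are meant to
# recover.

#' Configuration for the synthetic dFCN generator
#'
#' Bundles and validates the parameters of a synthetic multi-rate study:
#' a latent continuous-time Markov state trajectory over `n_states`
#' connectivity states, sampled at each period in `tr_list` to produce one
#' cohort per TR.
#'
#' @param n_regions Number of ROIs `R` (>= 2).
#' @param n_states Number of planted connectivity states `K` (>= 1).
#' @param tr_list Sampling periods in milliseconds, one cohort per entry.
#' @param total_duration Length of the latent trajectory in seconds.
#' @param mean_dwell Expected dwell time per state visit, seconds.
#' @param noise_sigma Entrywise perturbation scale applied to each FCN.
#' @param state_separation Value in (0, 1] controlling how distinct the
#'   state correlation matrices are (1 = fully independent factors).
#' @param seed Integer seed driving the whole study; cohort substreams are
#'   derived from it deterministically.
#' @param mode `"matrix"` (emit FCN stacks directly) or `"signal"` (emit ROI
#'   time series to be run through [sliding_window_pearson()]).
#' @return A validated `tempoph_config` list.
#' @export
#' @examples
#' cfg <- synthetic_config(n_regions = 10, n_states = 2, tr_list = c(1400, 2500),
#'                         total_duration = 60, seed = 1)
synthetic_config <- function(n_regions = 20, n_states = 3,
                             tr_list = c(645, 1400, 2500),
                             total_duration = 215, mean_dwell = 20,
                             noise_sigma = 0.05, state_separation = 0.8,
                             seed = 1, mode = c("matrix", "signal")) {
  mode <- match.arg(mode)
  cfg <- list(
    n_regions = check_count(n_regions, "n_regions", min = 2L),
    n_states = check_count(n_states, "n_states", min = 1L),
    tr_list = tr_list,
    total_duration = check_scalar(total_duration, "total_duration",
                                  min = 0, strict_min = TRUE),
    mean_dwell = check_scalar(mean_dwell, "mean_dwell",
                              min = 0, strict_min = TRUE),
    noise_sigma = check_scalar(noise_sigma, "noise_sigma", min = 0),
    state_separation = check_scalar(state_separation, "state_separation",
                                    min = 0, max = 1, strict_min = TRUE),
    seed = check_count(seed, "seed", min = 0L),
    mode = mode
  )
  if (!is.numeric(tr_list) || length(tr_list) < 1L || any(tr_list <= 0))
    stop_param("`tr_list` must be positive sampling periods in ms")
  cfg$tr_list <- as.double(tr_list)
  n_steps <- floor(cfg$total_duration * 1000 / cfg$tr_list)
  if (any(n_steps < 3))
    stop_param("every cohort needs >= 3 timepoints; TR = %g ms yields %d",
               cfg$tr_list[which.min(n_steps)], min(n_steps))
  class(cfg) <- "tempoph_config"
  cfg
}

#' Generate a set of planted state correlation matrices
#'
#' Each state's matrix is built from random low-rank factors
#' `W = sqrt(1 - separation) W0 + sqrt(separation) Wk`, sharing a common
#' component `W0` across states so that between-state Frobenius distances
#' grow with `separation`. On top of the pattern difference, states receive
#' distinct global coupling gains (spread scaled by `separation`), emulating
#' the canonical high-integration vs high-segregation contrast between
#' resting-state brain states: states differ both in which regions
#' correlate and in overall connectivity strength. The factor Gram matrix
#' plus a ridge is rescaled to a correlation matrix, which is positive
#' definite by construction.
#'
#' @param K Number of states (>= 1).
#' @param R Number of regions (>= 2).
#' @param separation Value in (0, 1].
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list of `K` symmetric positive-definite correlation matrices
#'   with unit diagonal.
#' @export
#' @examples
#' cs <- make_state_correlation_set(K = 2, R = 5, separation = 0.8, seed = 1)
make_state_correlation_set <- function(K, R, separation, seed) {
  K <- check_count(K, "K", min = 1L)
  R <- check_count(R, "R", min = 2L)
  separation <- check_scalar(separation, "separation", min = 0, max = 1,
                             strict_min = TRUE)
  seed <- check_count(seed, "seed", min = 0L)
  r <- max(2L, floor(R / 4))
  # Per-state global coupling gain. States are spaced evenly on the
  # filtration-distance scale d = sqrt((1 - rho)/2) (spread proportional to
  # `separation`), then mapped back to a factor gain via the strong-pair
  # correlation level rho ~ g^2 / (g^2 + 0.5); even spacing in d makes
  # neighboring states equally distinct to a connectivity-level summary,
  # and all gains collapse to a common value as separation -> 0.
  centered <- if (K == 1L) 0 else (seq_len(K) - 1) / (K - 1) - 0.5
  target_d <- 0.45 - 0.4 * separation * centered
  target_rho <- 1 - 2 * target_d^2
  gains <- sqrt(0.5 * target_rho / (1 - target_rho))
  with_seed(seed, {
    W0 <- matrix(rnorm(R * r), R, r)
    lapply(seq_len(K), function(k) {
      Wk <- matrix(rnorm(R * r), R, r)
      W <- sqrt(1 - separation) * W0 + sqrt(separation) * Wk
      S <- gains[k]^2 * tcrossprod(W) + diag(0.5 * r, R)
      C <- cov2cor(S)
      C[C > 1] <- 1
      C[C < -1] <- -1
      diag(C) <- 1
      (C + t(C)) / 2
    })
  })
}

# Latent continuous-time Markov trajectory: exponential dwell times with
# mean `mean_dwell`, uniform jumps to a *different* state. Returned as
# segment start times (seconds) and 0-based state ids; independent of any
# sampling period so all cohorts can share it.
simulate_latent_trajectory <- function(total_duration, mean_dwell, K, seed) {
  with_seed(seed, {
    starts <- 0
    state <- sample.int(K, 1L) - 1L
    states <- state
    t_now <- rexp(1, rate = 1 / mean_dwell)
    while (t_now < total_duration && K > 1L) {
      others <- setdiff(0:(K - 1L), state)
      state <- if (length(others) == 1L) others else sample(others, 1L)
      starts <- c(starts, t_now)
      states <- c(states, state)
      t_now <- t_now + rexp(1, rate = 1 / mean_dwell)
    }
    list(starts = starts, states = as.integer(states))
  })
}

#' Sample planted state labels at a given TR
#'
#' Simulates (deterministically from `seed`) a continuous-time Markov jump
#' trajectory with exponential dwell times and samples it at period `tr`.
#' Two calls with the same seed and duration but different TRs sample the
#' SAME latent trajectory, so labels agree wherever sampling times coincide.
#'
#' @param total_duration Trajectory length in seconds.
#' @param mean_dwell Mean dwell time per visit, seconds.
#' @param K Number of states.
#' @param tr Sampling period in milliseconds.
#' @param seed Integer seed.
#' @return Integer vector of 0-based state labels of length
#'   `floor(total_duration * 1000 / tr)`.
#' @export
#' @examples
#' simulate_state_labels(60, 10, K = 2, tr = 2500, seed = 1)
simulate_state_labels <- function(total_duration, mean_dwell, K, tr, seed) {
  total_duration <- check_scalar(total_duration, "total_duration",
                                 min = 0, strict_min = TRUE)
  mean_dwell <- check_scalar(mean_dwell, "mean_dwell", min = 0,
                             strict_min = TRUE)
  K <- check_count(K, "K", min = 1L)
  tr <- check_scalar(tr, "tr", min = 0, strict_min = TRUE)
  n <- floor(total_duration * 1000 / tr)
  if (n < 1)
    stop_param("TR = %g ms exceeds the trajectory duration (%g s)",
               tr, total_duration)
  traj <- simulate_latent_trajectory(total_duration, mean_dwell, K, seed)
  times <- (seq_len(n) - 1) * tr / 1000
  traj$states[findInterval(times, traj$starts)]
}

# Repair a perturbed matrix into a valid correlation matrix: symmetrize,
# unit diagonal, eigenvalue clipping at 0 (PSD projection), rescale back to
# unit diagonal, clip to [-1, 1]. Idempotent on valid inputs up to round-off.
repair_correlation <- function(M) {
  M <- (M + t(M)) / 2
  diag(M) <- 1
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  M <- e$vectors %*% (vals * t(e$vectors))
  d <- diag(M)
  d[d <= 0] <- 1
  M <- M / sqrt(outer(d, d))
  M[M > 1] <- 1
  M[M < -1] <- -1
  diag(M) <- 1
  (M + t(M)) / 2
}

# Shared set-up for both generator modes.
synthetic_ground_work <- function(config) {
  states <- make_state_correlation_set(config$n_states, config$n_regions,
                                       config$state_separation,
                                       seed_substream(config$seed, "states"))
  traj_seed <- seed_substream(config$seed, "trajectory")
  labels <- lapply(config$tr_list, function(tr) {
    simulate_state_labels(config$total_duration, config$mean_dwell,
                          config$n_states, tr, traj_seed)
  })
  names(labels) <- cohort_tag(config$tr_list)
  list(states = states, labels = labels)
}

cohort_tag <- function(tr) sprintf("tr%g", tr)

#' Simulate per-cohort FCN sequences with planted states
#'
#' For each TR cohort, the FCN at timepoint `t` is the active state's
#' correlation matrix plus symmetric Gaussian noise of scale `noise_sigma`,
#' repaired to a valid correlation matrix (with `noise_sigma = 0` the state
#' matrix is emitted unchanged). Ground truth (labels per cohort, state
#' matrices, planted K) is attached.
#'
#' @param config A [synthetic_config()] with `mode = "matrix"`.
#' @return A list with `cohorts` (named list of `tempoph_fcn` stacks, one per
#'   TR) and `ground_truth` (`labels`, `state_correlations`, `planted_k`).
#' @export
#' @examples
#' cfg <- synthetic_config(n_regions = 6, n_states = 2, tr_list = c(2500),
#'                         total_duration = 30, seed = 1)
#' sim <- simulate_fcn_sequence(cfg)
#' dim(sim$cohorts[[1]]$matrices)
simulate_fcn_sequence <- function(config) {
  stopifnot(inherits(config, "tempoph_config"))
  if (config$mode != "matrix")
    stop_param("simulate_fcn_sequence requires mode = \"matrix\"")
  gw <- synthetic_ground_work(config)
  R <- config$n_regions
  cohorts <- lapply(seq_along(config$tr_list), function(i) {
    tr <- config$tr_list[i]
    lab <- gw$labels[[i]]
    Tn <- length(lab)
    arr <- array(NA_real_, c(Tn, R, R))
    if (config$noise_sigma == 0) {
      for (t in seq_len(Tn)) arr[t, , ] <- gw$states[[lab[t] + 1L]]
    } else {
      with_seed(seed_substream(config$seed, paste0("noise:", cohort_tag(tr))), {
        for (t in seq_len(Tn)) {
          E <- matrix(rnorm(R * R, sd = config$noise_sigma), R, R)
          E <- (E + t(E)) / 2
          arr[t, , ] <- repair_correlation(gw$states[[lab[t] + 1L]] + E)
        }
      })
    }
    fcn_sequence(arr, tr_ms = tr)
  })
  names(cohorts) <- cohort_tag(config$tr_list)
  list(
    cohorts = cohorts,
    ground_truth = list(labels = gw$labels,
                        state_correlations = gw$states,
                        planted_k = config$n_states)
  )
}

#' Simulate per-cohort ROI time series with planted states
#'
#' Draws, for each timepoint, a multivariate normal observation whose
#' covariance is the active state's correlation matrix; suitable input for
#' [sliding_window_pearson()].
#'
#' @param config A [synthetic_config()] with `mode = "signal"`.
#' @return A list with `cohorts` (named list of `tempoph_ts` objects) and
#'   `ground_truth` as in [simulate_fcn_sequence()].
#' @export
simulate_roi_timeseries <- function(config) {
  stopifnot(inherits(config, "tempoph_config"))
  if (config$mode != "signal")
    stop_param("simulate_roi_timeseries requires mode = \"signal\"")
  gw <- synthetic_ground_work(config)
  R <- config$n_regions
  chols <- lapply(gw$states, function(C) {
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch))
      stop("internal error: planted state correlation is not positive definite")
    ch
  })
  cohorts <- lapply(seq_along(config$tr_list), function(i) {
    tr <- config$tr_list[i]
    lab <- gw$labels[[i]]
    Tn <- length(lab)
    with_seed(seed_substream(config$seed, paste0("signal:", cohort_tag(tr))), {
      Z <- matrix(rnorm(Tn * R), Tn, R)
      X <- matrix(NA_real_, Tn, R)
      for (t in seq_len(Tn)) X[t, ] <- Z[t, ] %*% chols[[lab[t] + 1L]]
      roi_timeseries(X, tr_ms = tr, subject_id = "synthetic")
    })
  })
  names(cohorts) <- cohort_tag(config$tr_list)
  list(
    cohorts = cohorts,
    ground_truth = list(labels = gw$labels,
                        state_correlations = gw$states,
                        planted_k = config$n_states)
  )
}
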