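#' Stimulus protocol
#'
#' Describes a putative task: which nodes receive an external excitatory
#' input, its amplitude, and when it is on.
#'
#' @param target_nodes Integer node indices receiving the input.
#' @param amplitude Input current in nA (>= 0).
#' @param onset,offset Stimulus window in seconds (offset may be `Inf` for a
#'   stationary task condition).
#' @return A list of class `"stimulus_protocol"`.
#' @export
stimulus_protocol <- function(target_nodes, amplitude = 0.02, onset = 0,
                              offset = Inf) {
  stopifnot(amplitude >= 0, onset < offset,
            all(target_nodes == as.integer(target_nodes)),
            all(target_nodes >= 1))
  structure(list(target_nodes = as.integer(target_nodes),
                 amplitude = amplitude, onset = onset, offset = offset),
            class = "stimulus_protocol")
}

#' Input vector of a protocol
#'
#' @param protocol A [stimulus_protocol] (or `NULL` for no input).
#' @param n Number of nodes.
#' @return Length-`n` vector of external currents (nA).
#' @export
protocol_input <- function(protocol, n) {
  I_ext <- numeric(n)
  if (!is.null(protocol)) {
    if (any(protocol$target_nodes > n)) stop("protocol targets out of range")
    I_ext[protocol$target_nodes] <- protocol$amplitude
  }
  I_ext
}

#' Simulate a trial ensemble of the stochastic model
#'
#' Euler-Maruyama integration of the gating equations (noise increment
#' `beta * sqrt(dt) * N(0,1)` per population per step) for `n_trials`
#' independent realizations. Each trial starts at the deterministic fixed
#' point and runs a spontaneous burn-in (default 2 s of model time) so that
#' recording starts from the stationary spontaneous distribution; the
#' stimulus window of `protocol` is applied relative to the start of the
#' recorded segment. Gating states are clamped to `[0, 1]` after each step.
#'
#' @param conn A [connectome].
#' @param params A FIC-calibrated [dmf_params].
#' @param protocol Optional [stimulus_protocol].
#' @param duration Recorded duration per trial (s).
#' @param n_trials Number of trials.
#' @param seed Optional RNG seed.
#' @param record `"current"` (synaptic input currents `u`, the model's
#'   synaptic activity) or `"gating"` (the state variables `S`).
#' @param subsample Record every `subsample`-th step (default 10, i.e. 1 ms
#'   at the default `dt`).
#' @param burn_in Burn-in time (s) before recording.
#' @return A list of class `"trial_ensemble"`: `trajectories` (array
#'   `n_time x 2N x n_trials`), `t` (seconds, 0 = recording start), `dt`
#'   (recording step), `record`, `protocol`, `n`.
#' @export
simulate_ensemble <- function(conn, params, protocol = NULL, duration = 1,
                              n_trials = 1L, seed = NULL,
                              record = c("current", "gating"),
                              subsample = 10L, burn_in = 2) {
  record <- match.arg(record)
  stopifnot(inherits(conn, "connectome"), params$n == conn$n)
  if (!is.null(seed)) set.seed(seed)
  n <- conn$n
  dt <- params$dt
  n_steps <- round(duration / dt)
  burn_steps <- round(burn_in / dt)
  I_ext <- protocol_input(protocol, n)
  if (is.null(protocol) || protocol$amplitude == 0) {
    onset_step <- n_steps + 1L
    offset_step <- n_steps + 1L
  } else {
    onset_step <- round(protocol$onset / dt)
    offset_step <- if (is.finite(protocol$offset))
      round(protocol$offset / dt) else n_steps
  }
  mu0 <- fixed_point(conn, params)
  S0 <- matrix(mu0, 2L * n, n_trials)
  GC <- params$G * params$w_net * conn$weights
  traj <- sim_dmf_cpp(GC, params$w_EI, unclass(params), I_ext,
                      burn_steps, n_steps, onset_step, offset_step,
                      as.integer(subsample), as.integer(n_trials), S0,
                      record == "current")
  n_rec <- dim(traj)[1]
  structure(list(trajectories = traj,
                 t = (seq_len(n_rec) - 1L) * dt * subsample,
                 dt = dt * subsample, record = record,
                 protocol = protocol, n = n, n_trials = n_trials),
            class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf(
    "trial_ensemble: %d trials x %d time points x %d series (%s), dt %.4g s\n",
    x$n_trials, length(x$t), 2L * x$n, x$record, x$dt))
  invisible(x)
}

#' Across-trial mean of an ensemble
#'
#' @param ens A [simulate_ensemble()] result.
#' @return A `n_time x 2N` matrix of trial-averaged values.
#' @export
ensemble_mean <- function(ens) {
  apply(ens$trajectories, c(1L, 2L), mean)
}

#' Trial-by-trial variance time course
#'
#' Unbiased variance across stochastic realizations at each time point, per
#' series (E currents/gatings first, then I).
#'
#' @param ens A [simulate_ensemble()] result with at least 2 trials.
#' @return A `n_time x 2N` matrix of variances.
#' @export
ensemble_variance <- function(ens) {
  if (ens$n_trials < 2L) stop("variance needs at least 2 trials")
  d <- dim(ens$trajectories)
  flat <- matrix(ens$trajectories, d[1] * d[2], d[3])
  m <- rowMeans(flat)
  v <- (rowSums(flat^2) - d[3] * m^2) / (d[3] - 1)
  matrix(pmax(v, 0), d[1], d[2])
}

#' Across-trial autocovariance at a reference time
#'
#' Covariance (across trials) between the value at `t_ref + lag` and at
#' `t_ref`, per series. At lag 0 this equals the ensemble variance at
#' `t_ref`.
#'
#' @param ens A [simulate_ensemble()] result.
#' @param t_ref Reference time (s, within the recorded window).
#' @param lags Vector of lags (s); `t_ref + max(lags)` must be recorded.
#' @return A `2N x n_lags` matrix of autocovariances.
#' @export
ensemble_autocovariance <- function(ens, t_ref, lags) {
  if (ens$n_trials < 2L) stop("autocovariance needs at least 2 trials")
  i_ref <- round(t_ref / ens$dt) + 1L
  i_lag <- round(lags / ens$dt)
  n_time <- dim(ens$trajectories)[1]
  if (i_ref < 1L || any(i_ref + i_lag < 1L) ||
      any(i_ref + i_lag > n_time)) {
    stop("t_ref + lag outside the recorded window")
  }
  n_series <- dim(ens$trajectories)[2]
  out <- matrix(NA_real_, n_series, length(lags))
  x0 <- ens$trajectories[i_ref, , , drop = TRUE]   # series x trials
  for (k in seq_along(lags)) {
    xk <- ens$trajectories[i_ref + i_lag[k], , , drop = TRUE]
    for (s in seq_len(n_series)) out[s, k] <- cov(xk[s, ], x0[s, ])
  }
  out
}

#' Percent-change time courses of mean and variance
#'
#' Per node and time point, `100 * (task / baseline - 1)` for the
#' trial-averaged mean and the trial-by-trial variance. The baseline is a
#' separate spontaneous ensemble when given (compared time point by time
#' point), otherwise the time average of the task ensemble over the
#' pre-onset window (the protocol's onset must then be positive). Time
#' points with zero baseline variance give `NaN` rather than an error.
#'
#' @param ens_task A stimulated [simulate_ensemble()] result.
#' @param ens_spont Optional spontaneous ensemble on the same time grid.
#' @return A list with `t`, `delta_m` and `delta_sigma2`
#'   (`n_time x 2N` matrices, percent).
#' @export
delta_timecourses <- function(ens_task, ens_spont = NULL) {
  m_t <- ensemble_mean(ens_task)
  v_t <- ensemble_variance(ens_task)
  if (!is.null(ens_spont)) {
    if (!isTRUE(all.equal(ens_task$t, ens_spont$t))) {
      stop("ensembles are not on the same time grid")
    }
    m_0 <- ensemble_mean(ens_spont)
    v_0 <- ensemble_variance(ens_spont)
    v_0[v_0 == 0] <- NA_real_
    delta_m <- 100 * (m_t / m_0 - 1)
    delta_s <- 100 * (v_t / v_0 - 1)
  } else {
    if (is.null(ens_task$protocol) || ens_task$protocol$onset <= 0) {
      stop("no spontaneous ensemble and no pre-onset baseline window")
    }
    pre <- ens_task$t < ens_task$protocol$onset
    m_0 <- colMeans(m_t[pre, , drop = FALSE])
    v_0 <- colMeans(v_t[pre, , drop = FALSE])
    v_0[v_0 == 0] <- NA_real_
    delta_m <- 100 * sweep(m_t, 2L, m_0, `/`) - 100
    delta_s <- 100 * sweep(v_t, 2L, v_0, `/`) - 100
  }
  list(t = ens_task$t, delta_m = delta_m, delta_sigma2 = delta_s)
}
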