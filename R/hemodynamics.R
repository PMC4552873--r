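#' Balloon-Windkessel hemodynamic parameters
#'
#' The canonical parameter set of the Balloon-Windkessel model: rate of
#' vasodilatory signal decay `kappa` (0.65 s^-1), rate of flow-dependent
#' elimination `gamma` (0.41 s^-1), hemodynamic transit time `tau`
#' (0.98 s), Grubb's vessel stiffness exponent `alpha` (0.32), resting
#' oxygen extraction fraction `rho` (0.34) and resting blood volume
#' fraction `V0` (0.02).
#'
#' @param ... Named overrides.
#' @return A list of class `"bold_params"`.
#' @export
bold_params <- function(...) {
  p <- list(kappa = 0.65, gamma = 0.41, tau = 0.98, alpha = 0.32,
            rho = 0.34, V0 = 0.02)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(all(unlist(p) > 0))
  class(p) <- "bold_params"
  p
}

#' Transform neural drive into BOLD signal
#'
#' Integrates the Balloon-Windkessel ODEs (vasodilatory signal, blood
#' inflow, blood volume, deoxyhemoglobin content) from the resting steady
#' state, driven by the given neural signal, and returns the BOLD
#' percent-change series. The model acts as a strong low-pass filter,
#' passing frequencies below about 1 Hz. If `dt > 1 ms` the drive is
#' internally sub-stepped (sample-and-hold) for integration accuracy.
#'
#' @param drive Numeric matrix `nodes x time` (or a vector for one node) of
#'   neural drive, in standardized units.
#' @param dt Sampling step of `drive`, seconds.
#' @param params A [bold_params] set.
#' @return BOLD percent-change matrix `nodes x time` (same sampling as the
#'   input).
#' @export
bold_transform <- function(drive, dt, params = bold_params()) {
  if (is.null(dim(drive))) drive <- matrix(drive, nrow = 1L)
  stopifnot(all(is.finite(drive)), dt > 0)
  sub <- max(1L, ceiling(dt / 1e-3))
  if (sub > 1L) {
    drive_i <- drive[, rep(seq_len(ncol(drive)), each = sub), drop = FALSE]
    dt_i <- dt / sub
  } else {
    drive_i <- drive
    dt_i <- dt
  }
  bold <- balloon_cpp(drive_i, dt_i, params$kappa, params$gamma,
                      params$tau, params$alpha, params$rho, params$V0)
  if (sub > 1L) bold <- bold[, seq(1L, ncol(bold), by = sub), drop = FALSE]
  bold
}

#' Amplitude response of the hemodynamic filter to a cosine drive
#'
#' Drives the Balloon model with `cos(2 pi f t)` and returns the
#' steady-state peak-to-peak amplitude per frequency, normalised to its
#' value at the lowest frequency. Characterises the low-pass behaviour.
#'
#' @param freq_hz Frequencies to probe.
#' @param amplitude Drive amplitude (kept small for linearity).
#' @param params A [bold_params] set.
#' @return A data frame with `freq_hz` and relative `gain`.
#' @export
bold_frequency_response <- function(freq_hz = c(0.01, 0.05, 0.1, 0.5, 1, 2),
                                    amplitude = 0.1,
                                    params = bold_params()) {
  dt <- 1e-3
  gains <- vapply(freq_hz, function(f) {
    t_end <- max(30, 5 / f)
    tt <- seq(0, t_end, by = dt)
    z <- amplitude * cos(2 * pi * f * tt)
    b <- drop(bold_transform(z, dt, params))
    tail_idx <- tt > t_end / 2
    diff(range(b[tail_idx]))
  }, numeric(1))
  data.frame(freq_hz = freq_hz, gain = gains / gains[1L])
}

#' Trial statistics of simulated BOLD responses
#'
#' Simulates stochastic trials of the whole-brain model under a stimulus
#' protocol, converts each trial's total synaptic activity (sum of E and I
#' synaptic currents per node, z-scored against the pre-onset baseline and
#' scaled by `drive_scale`) into BOLD through the Balloon-Windkessel model,
#' and summarises the trial-averaged BOLD change and trial-by-trial BOLD
#' variance change relative to the pre-onset baseline.
#'
#' @param conn A [connectome].
#' @param params A FIC-calibrated [dmf_params].
#' @param protocol A [stimulus_protocol] with a finite onset > 0.
#' @param duration Trial duration (s).
#' @param n_trials Number of trials (default 800).
#' @param seed RNG seed.
#' @param drive_scale Scale applied to the z-scored drive before the
#'   hemodynamic stage (default 0.2, keeping the Balloon model in its
#'   physiological range).
#' @param response_window Window (s) over which per-node changes are
#'   averaged (default `c(5, 23)`).
#' @param hemo A [bold_params] set.
#' @return A list of class `"bold_trial_stats"`: `t`, `mean_change` and
#'   `var_change` (percent, `n_time` long, node-averaged time courses),
#'   `node_delta_mean`, `node_delta_var` (per-node window averages),
#'   `cor_mean_var` (across-node correlation), `n_trials`.
#' @export
bold_trial_experiment <- function(conn, params, protocol, duration = 28,
                                  n_trials = 800L, seed = NULL,
                                  drive_scale = 0.2,
                                  response_window = c(5, 23),
                                  hemo = bold_params()) {
  stopifnot(protocol$onset > 0)
  ens <- simulate_ensemble(conn, params, protocol, duration = duration,
                           n_trials = n_trials, seed = seed,
                           record = "current", subsample = 10L)
  n <- conn$n
  iE <- seq_len(n)
  # total synaptic activity per node and trial
  d <- dim(ens$trajectories)
  total <- ens$trajectories[, iE, , drop = FALSE] +
    ens$trajectories[, n + iE, , drop = FALSE]
  pre <- ens$t < protocol$onset
  flat_pre <- matrix(aperm(total[pre, , , drop = FALSE], c(1L, 3L, 2L)),
                     ncol = n)
  m0 <- colMeans(flat_pre)
  s0 <- apply(flat_pre, 2L, sd)
  bold <- array(NA_real_, c(d[1], n, d[3]))
  for (tr in seq_len(d[3])) {
    z <- t((total[, , tr] - rep(m0, each = d[1])) /
             rep(s0, each = d[1])) * drive_scale
    bold[, , tr] <- t(bold_transform(z, ens$dt, hemo))
  }
  bens <- list(trajectories = bold, t = ens$t, dt = ens$dt,
               record = "bold", protocol = protocol, n = n,
               n_trials = n_trials)
  m_t <- apply(bold, c(1L, 2L), mean)
  v_t <- apply(bold, c(1L, 2L), var)
  m_base <- colMeans(m_t[pre, , drop = FALSE])
  v_base <- colMeans(v_t[pre, , drop = FALSE])
  # BOLD is a percent-change signal crossing zero, so mean changes are
  # reported as differences in percent-signal units; variance changes as
  # percent of baseline variance.
  mean_change <- sweep(m_t, 2L, m_base, `-`)
  var_change <- 100 * sweep(v_t, 2L, v_base, `/`) - 100
  win <- ens$t >= response_window[1] & ens$t <= response_window[2]
  node_dm <- colMeans(mean_change[win, , drop = FALSE])
  node_dv <- colMeans(var_change[win, , drop = FALSE])
  structure(list(t = ens$t, mean_change = rowMeans(mean_change),
                 var_change = rowMeans(var_change),
                 node_delta_mean = node_dm, node_delta_var = node_dv,
                 cor_mean_var = cor(node_dm, node_dv),
                 ensemble = bens, n_trials = n_trials),
            class = "bold_trial_stats")
}
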