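#' Solve a continuous-time Lyapunov equation
#'
#' Finds the symmetric `P` with `A P + P A' + Q = 0` for a stable (Hurwitz)
#' `A`, via the eigendecomposition of `A`: with `A = V L V^-1`, the
#' transformed equation is diagonal, `X[i,j] = -Qt[i,j] / (L[i] + L[j])`.
#'
#' @param A Square stable matrix.
#' @param Q Symmetric positive semidefinite matrix (same dimension).
#' @return The symmetric solution `P`.
#' @export
lyapunov_solve <- function(A, Q) {
  stopifnot(nrow(A) == ncol(A), all(dim(A) == dim(Q)))
  e <- eigen(A)
  if (max(Re(e$values)) >= 0) {
    stop("A is not stable (max Re eigenvalue = ",
         format(max(Re(e$values))), "); no stationary covariance exists")
  }
  V <- e$vectors
  Qt <- solve(V, t(solve(V, t(Q))))      # V^-1 Q V^-T
  X <- -Qt / outer(e$values, e$values, `+`)
  P <- Re(V %*% X %*% t(V))
  (P + t(P)) / 2
}

#' Stationary moments of the linear noise approximation
#'
#' Computes the stationary mean gating state `mu` (deterministic fixed
#' point), the Jacobian `A` there, and the gating covariance `P` solving
#' the Lyapunov equation `A P + P A' + Qn = 0`, where `Qn` is the
#' continuous-time noise covariance (default `beta^2 I_2N`, independent
#' noise of equal intensity at every population).
#'
#' @param conn A [connectome].
#' @param params A FIC-calibrated [dmf_params].
#' @param I_ext External input per node (nA) to the E populations; 0 for the
#'   spontaneous condition.
#' @param Qn Optional `2N x 2N` noise covariance.
#' @return A list of class `"moment_solution"`: `mu`, `P`, `A`, `Qn`,
#'   `I_ext`, `eig` (eigendecomposition of `A`), `W` (the coupling matrix),
#'   `mean_u` (stationary synaptic currents), `converged`.
#' @export
solve_moments <- function(conn, params, I_ext = 0, Qn = NULL) {
  n <- conn$n
  I_ext <- rep_len(I_ext, n)
  if (is.null(Qn)) Qn <- diag(params$beta^2, 2L * n)
  stopifnot(all(dim(Qn) == 2L * n))
  mu <- fixed_point(conn, params, I_ext)
  A <- dmf_jacobian(mu, conn, params, I_ext)
  e <- eigen(A)
  if (max(Re(e$values)) >= 0) {
    stop("fixed point is linearly unstable (max Re eigenvalue = ",
         format(max(Re(e$values))), ")")
  }
  V <- e$vectors
  Qt <- solve(V, t(solve(V, t(Qn))))
  X <- -Qt / outer(e$values, e$values, `+`)
  P <- Re(V %*% X %*% t(V))
  P <- (P + t(P)) / 2
  res <- norm(A %*% P + P %*% t(A) + Qn, "F") / norm(Qn, "F")
  if (res > 1e-8) {
    stop("Lyapunov solve failed (relative residual ", format(res), ")")
  }
  u <- synaptic_currents(mu[seq_len(n)], mu[n + seq_len(n)], conn, params,
                         I_ext)
  structure(list(mu = mu, P = P, A = A, Qn = Qn, I_ext = I_ext, eig = e,
                 W = coupling_matrix(conn, params),
                 mean_u = c(u$u_E, u$u_I), residual = res,
                 converged = TRUE, n = n),
            class = "moment_solution")
}

#' @export
print.moment_solution <- function(x, ...) {
  cat(sprintf(
    "LNA moment solution: %d nodes, %s, Lyapunov residual %.2e\n",
    x$n, if (any(x$I_ext != 0)) "stimulated" else "spontaneous", x$residual))
  invisible(x)
}

#' Covariance of synaptic currents
#'
#' The currents are the linear image `u = W S + const` of the gating state,
#' so their covariance is `Cv = W P W'`.
#'
#' @param sol A [solve_moments()] solution.
#' @param W Optional coupling matrix (defaults to the one stored in `sol`).
#' @return A symmetric `2N x 2N` covariance matrix.
#' @export
synaptic_covariance <- function(sol, W = NULL) {
  if (is.null(W)) W <- sol$W
  Cv <- W %*% sol$P %*% t(W)
  (Cv + t(Cv)) / 2
}

#' Stationary autocovariance, autocorrelation and decay timescale
#'
#' Propagates the stationary gating covariance with the matrix exponential,
#' `F_S(tau) = expm(tau A) P`, maps it to currents, `F_u = W F_S W'`, and
#' normalises per node, `ACF_i(tau) = F_u[i,i](tau) / F_u[i,i](0)`. The
#' characteristic timescale T95 is the lag at which the node-averaged ACF
#' of a population first decays to 0.05 (95% decorrelation), linearly
#' interpolated between grid points. `expm(dtau A)` is built once from the
#' stored eigendecomposition and reused along the uniform lag grid.
#'
#' @param sol A [solve_moments()] solution.
#' @param tau_grid Uniform, increasing lag grid starting at 0 (seconds).
#' @param W Optional coupling matrix override.
#' @param compute_t95 Find the 0.05 crossings (default `TRUE`; an error is
#'   raised if the grid does not bracket them).
#' @return A list of class `"lna_acf"`: `tau`, `F_u` (`2N x n_tau` diagonal
#'   autocovariances), `acf` (`2N x n_tau`), `t95_E`, `t95_I` (seconds,
#'   `NA` when not requested).
#' @export
lna_autocovariance <- function(sol, tau_grid = seq(0, 1.5, by = 0.002),
                               W = NULL, compute_t95 = TRUE) {
  stopifnot(tau_grid[1] == 0, length(tau_grid) > 2)
  dtau <- diff(tau_grid)
  if (max(abs(dtau - dtau[1])) > 1e-12) stop("tau_grid must be uniform")
  if (is.null(W)) W <- sol$W
  n <- sol$n
  V <- sol$eig$vectors
  E1 <- Re(V %*% (exp(dtau[1] * sol$eig$values) * solve(V)))
  n_tau <- length(tau_grid)
  F_u <- matrix(NA_real_, 2L * n, n_tau)
  Fs <- sol$P
  for (k in seq_len(n_tau)) {
    F_u[, k] <- rowSums((W %*% Fs) * W)   # diag(W Fs W')
    if (k < n_tau) Fs <- E1 %*% Fs
  }
  acf_mat <- F_u / F_u[, 1L]
  t95_E <- t95_I <- NA_real_
  if (compute_t95) {
    t95_E <- acf_crossing(colMeans(acf_mat[seq_len(n), , drop = FALSE]),
                          tau_grid)
    t95_I <- acf_crossing(colMeans(acf_mat[n + seq_len(n), , drop = FALSE]),
                          tau_grid)
  }
  structure(list(tau = tau_grid, F_u = F_u, acf = acf_mat,
                 t95_E = t95_E, t95_I = t95_I),
            class = "lna_acf")
}

## First downward crossing of `level` of an ACF curve, linear interpolation.
acf_crossing <- function(acf_curve, tau, level = 0.05) {
  below <- which(acf_curve <= level)
  if (!length(below)) {
    stop("ACF does not reach ", level, " within the lag grid; extend it")
  }
  k <- below[1L]
  if (k == 1L) return(tau[1L])
  # linear interpolation between k-1 and k
  tau[k - 1L] + (acf_curve[k - 1L] - level) /
    (acf_curve[k - 1L] - acf_curve[k]) * (tau[k] - tau[k - 1L])
}

#' Cross-spectra and power spectral density of synaptic activity
#'
#' For each angular frequency `w = 2 pi f`, the gating cross-spectrum is
#' `Pi_S(w) = (A + iw)^-1 Qn (A' - iw)^-1` and the current cross-spectrum is
#' `Pi_u(w) = W Pi_S(w) W^H`; the PSD is its real diagonal. The two-sided
#' angular-frequency convention is used, so that
#' `var = (1/2pi) integral Pi(w) dw` (Parseval); the frequency axis is
#' reported in Hz.
#'
#' @param sol A [solve_moments()] solution.
#' @param freq_hz Frequency grid in Hz (default logarithmic, 0.01-200 Hz).
#' @param W Optional coupling matrix override.
#' @return A list of class `"spectral_solution"`: `freq_hz` and `psd`
#'   (`2N x n_freq`, nonnegative).
#' @export
cross_spectrum <- function(sol,
                           freq_hz = 10^seq(log10(0.01), log10(200),
                                            length.out = 400L),
                           W = NULL) {
  if (is.null(W)) W <- sol$W
  n2 <- nrow(sol$A)
  psd <- matrix(NA_real_, n2, length(freq_hz))
  I2 <- diag(n2)
  for (k in seq_along(freq_hz)) {
    w <- 2 * pi * freq_hz[k]
    X <- solve(sol$A + 1i * w * I2)
    Y <- W %*% X
    psd[, k] <- Re(rowSums((Y %*% sol$Qn) * Conj(Y)))
  }
  structure(list(freq_hz = freq_hz, psd = psd), class = "spectral_solution")
}

## Frequency of the minimum of a spectral change curve, with parabolic
## interpolation of the three points around the discrete minimum (in log f).
psd_min_freq <- function(curve, freq_hz) {
  k <- which.min(curve)
  if (k == 1L || k == length(curve)) return(freq_hz[k])
  lf <- log(freq_hz[(k - 1L):(k + 1L)])
  y <- curve[(k - 1L):(k + 1L)]
  denom <- (y[1] - 2 * y[2] + y[3])
  if (abs(denom) < .Machine$double.eps) return(freq_hz[k])
  delta <- 0.5 * (y[1] - y[3]) / denom * (lf[3] - lf[1]) / 2
  exp(lf[2] + delta)
}

#' Stimulus-response metrics of the stationary network
#'
#' Compares a task (stimulated) stationary solution against the spontaneous
#' one: percent change of mean synaptic activity `Dm = 100 (m_task/m_spont
#' - 1)`, of trial-by-trial variance `Dsigma2` (on synaptic currents), and
#' of the power spectral density `DPSD`, per node; the across-node
#' correlation of `Dm` vs `Dsigma2` per population; the similarity
#' (correlation of upper triangles) of the spontaneous and task functional
#' connectivity of excitatory currents; and the pairwise covariance and
#' correlation change distributions.
#'
#' @param spont,task [solve_moments()] solutions on the same network.
#' @param freq_hz Frequency grid for the spectral comparison.
#' @param targets Indices of nodes receiving direct input (used to split
#'   `DPSD` into direct/indirect averages).
#' @return A list of class `"response_metrics"` with elements `delta_m`,
#'   `delta_sigma2` (length `2N`), `delta_psd` (`2N x n_freq`), `freq_hz`,
#'   `cor_dm_dsigma2_E`, `cor_dm_dsigma2_I`, `fc_similarity`,
#'   `cov_rel_change`, `corr_diff` (upper-triangle distributions, E block),
#'   `dpsd_min_freq_direct_E`, `dpsd_min_freq_indirect_E` (and I analogues),
#'   `targets`.
#' @export
response_metrics <- function(spont, task,
                             freq_hz = 10^seq(log10(0.01), log10(200),
                                              length.out = 400L),
                             targets = which(task$I_ext != 0)) {
  stopifnot(spont$n == task$n)
  n <- spont$n
  Cv_s <- synaptic_covariance(spont)
  Cv_t <- synaptic_covariance(task)
  delta_m <- 100 * (task$mean_u / spont$mean_u - 1)
  v_s <- diag(Cv_s)
  v_t <- diag(Cv_t)
  delta_sigma2 <- ifelse(v_s > 0, 100 * (v_t / v_s - 1), NA_real_)
  ps <- cross_spectrum(spont, freq_hz)
  pt <- cross_spectrum(task, freq_hz)
  delta_psd <- 100 * (pt$psd / ps$psd - 1)
  iE <- seq_len(n)
  iI <- n + seq_len(n)
  direct <- intersect(targets, iE)
  indirect <- setdiff(iE, direct)
  up <- upper.tri(Cv_s[iE, iE])
  R_s <- stats::cov2cor(Cv_s[iE, iE])
  R_t <- stats::cov2cor(Cv_t[iE, iE])
  # correlation is undefined (not a warning) for an all-zero contrast
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }
  structure(list(
    delta_m = delta_m, delta_sigma2 = delta_sigma2,
    delta_psd = delta_psd, freq_hz = freq_hz,
    cor_dm_dsigma2_E = safe_cor(delta_m[iE], delta_sigma2[iE]),
    cor_dm_dsigma2_I = safe_cor(delta_m[iI], delta_sigma2[iI]),
    fc_similarity = cor(R_s[up], R_t[up]),
    cov_rel_change = 100 * (Cv_t[iE, iE][up] / Cv_s[iE, iE][up] - 1),
    corr_diff = R_t[up] - R_s[up],
    dpsd_min_freq_direct_E =
      if (length(direct)) psd_min_freq(colMeans(delta_psd[direct, ,
        drop = FALSE]), freq_hz) else NA_real_,
    dpsd_min_freq_indirect_E =
      psd_min_freq(colMeans(delta_psd[indirect, , drop = FALSE]), freq_hz),
    dpsd_min_freq_direct_I =
      if (length(direct)) psd_min_freq(colMeans(delta_psd[n + direct, ,
        drop = FALSE]), freq_hz) else NA_real_,
    dpsd_min_freq_indirect_I =
      psd_min_freq(colMeans(delta_psd[n + indirect, , drop = FALSE]),
                   freq_hz),
    targets = targets), class = "response_metrics")
}

#' Transient moments under a stimulus protocol
#'
#' Joint Euler integration of the mean equations and of the covariance
#' equation `dP/dt = A P + P A' + Qn`, with the Jacobian re-evaluated at the
#' instantaneous mean, starting from the stationary spontaneous solution.
#' Used for the time courses of the mean and the trial-by-trial variance of
#' synaptic activity around stimulus onset.
#'
#' @param conn A [connectome].
#' @param params A FIC-calibrated [dmf_params].
#' @param protocol A [stimulus_protocol].
#' @param t_max End of the integration window (seconds; starts at 0, the
#'   protocol's own onset/offset select when the input is on).
#' @param dt_store Storage interval (s).
#' @param dt_int Internal Euler step (s).
#' @param Qn Optional noise covariance (default `beta^2 I`).
#' @return A list with `t`, `mean_u` and `var_u` (`2N x n_t` time courses of
#'   the mean and variance of synaptic currents), the starting `spont`
#'   solution, and the final integrated state `mu_final`, `P_final`.
#' @export
solve_moments_transient <- function(conn, params, protocol, t_max,
                                    dt_store = 0.02, dt_int = 5e-4,
                                    Qn = NULL) {
  n <- conn$n
  if (is.null(Qn)) Qn <- diag(params$beta^2, 2L * n)
  spont <- solve_moments(conn, params, 0, Qn)
  I_on <- numeric(n)
  I_on[protocol$target_nodes] <- protocol$amplitude
  t_grid <- seq(0, t_max, by = dt_store)
  mean_u <- matrix(NA_real_, 2L * n, length(t_grid))
  var_u <- matrix(NA_real_, 2L * n, length(t_grid))
  mu <- spont$mu
  P <- spont$P
  t <- 0
  k <- 1L
  W_base <- coupling_matrix(conn, params)
  store <- function(mu, P, I_ext, k) {
    u <- synaptic_currents(mu[seq_len(n)], mu[n + seq_len(n)], conn, params,
                           I_ext)
    mean_u[, k] <<- c(u$u_E, u$u_I)
    var_u[, k] <<- rowSums((W_base %*% P) * W_base)
  }
  n_steps <- round(t_max / dt_int)
  for (s in 0:n_steps) {
    stim_on <- t >= protocol$onset && t < protocol$offset
    I_ext <- if (stim_on) I_on else numeric(n)
    if (k <= length(t_grid) && t >= t_grid[k] - dt_int / 2) {
      store(mu, P, I_ext, k)
      k <- k + 1L
    }
    A <- dmf_jacobian(mu, conn, params, I_ext)
    mu <- mu + dt_int * dmf_drift(mu, conn, params, I_ext)
    P <- P + dt_int * (A %*% P + P %*% t(A) + Qn)
    t <- t + dt_int
  }
  list(t = t_grid, mean_u = mean_u, var_u = var_u, spont = spont,
       mu_final = mu, P_final = P)
}
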