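#' Parameters of the dynamic mean-field model
#'
#' Returns the full parameter set of the two-population (excitatory E,
#' inhibitory I) dynamic mean-field model. The state variables are synaptic
#' gating fractions `S_E`, `S_I` in `[0, 1]`; population firing rates are
#' sigmoidal functions of the input currents, and nodes are coupled through
#' the structural connectome scaled by the global coupling `G` and the
#' long-range synaptic efficacy `w_net` (the NMDA conductance that also
#' enters the local weights: `w_EE = 1.4 * w_net`, `w_IE = w_net`).
#'
#' Defaults are the canonical reduced Wong-Wang values: transfer-function
#' constants `a_E = 310` nC^-1, `b_E = 125` Hz, `d_E = 0.16` s,
#' `a_I = 615` nC^-1, `b_I = 177` Hz, `d_I = 0.087` s; gating time constants
#' `tau_E = 0.1` s (NMDA), `tau_I = 0.01` s (GABA); kinetic factor
#' `gamma = 0.641`; background currents `I0_E = 0.3438` nA,
#' `I0_I = 0.2674` nA; local weights `w_EE = 0.21`, `w_IE = 0.15`,
#' `w_II = 1`; noise amplitude `beta = 0.01` and integration step
#' `dt = 1e-4` s.
#'
#' @param n Number of nodes (used to size the per-node feedback-inhibition
#'   vector `w_EI`, initialised at 1 until calibrated).
#' @param G Global coupling (dimensionless; default 2.15).
#' @param ... Named overrides of any default.
#' @return A list of class `"dmf_params"`.
#' @export
dmf_params <- function(n, G = 2.15, ...) {
  p <- list(
    a_E = 310, b_E = 125, d_E = 0.16,
    a_I = 615, b_I = 177, d_I = 0.087,
    tau_E = 0.1, tau_I = 0.01, gamma = 0.641,
    I0_E = 0.3438, I0_I = 0.2674,
    w_EE = 0.21, w_IE = 0.15, w_II = 1, w_net = 0.15,
    G = G, beta = 0.01, dt = 1e-4,
    w_EI = rep(1, n), n = as.integer(n)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(p$tau_E > 0, p$tau_I > 0, p$dt > 0, p$beta >= 0,
            length(p$w_EI) == p$n)
  class(p) <- "dmf_params"
  p
}

## x / (1 - exp(-d x)) and its derivative, with the removable singularity at
## x = 0 handled by series expansion so the function and its derivative are
## smooth there.
phi_g <- function(x, d) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- 1 / d + x[small] / 2 + d * x[small]^2 / 12
  xl <- x[!small]
  out[!small] <- xl / (1 - exp(-d * xl))
  out
}

phi_g_prime <- function(x, d) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- 1 / 2 + d * x[small] / 6
  xl <- x[!small]
  e <- exp(-d * xl)
  out[!small] <- (1 - e * (1 + d * xl)) / (1 - e)^2
  out
}

#' Population transfer function (f-I curve)
#'
#' Firing rate of a population as a function of its input current:
#' `r = (a u - b) / (1 - exp(-d (a u - b)))`, a soft-rectifying sigmoid that
#' is strictly increasing, nonnegative, and smooth across the removable
#' singularity at `a u = b` (where it equals `1/d`).
#'
#' @param u Input current in nA (vectorised).
#' @param population `"E"` or `"I"`.
#' @param params A [dmf_params] object.
#' @return Firing rate(s) in Hz.
#' @export
transfer_rate <- function(u, population = c("E", "I"), params) {
  population <- match.arg(population)
  if (population == "E") phi_g(params$a_E * u - params$b_E, params$d_E)
  else phi_g(params$a_I * u - params$b_I, params$d_I)
}

#' Derivative of the transfer function with respect to the input current
#'
#' @inheritParams transfer_rate
#' @return d(rate)/d(u) in Hz/nA.
#' @export
transfer_rate_deriv <- function(u, population = c("E", "I"), params) {
  population <- match.arg(population)
  if (population == "E") {
    params$a_E * phi_g_prime(params$a_E * u - params$b_E, params$d_E)
  } else {
    params$a_I * phi_g_prime(params$a_I * u - params$b_I, params$d_I)
  }
}

## Current at which the E transfer function attains a given rate (Hz).
invert_transfer_E <- function(rate, params) {
  f <- function(u) transfer_rate(u, "E", params) - rate
  uniroot(f, interval = c(-1, 2), tol = 1e-14)$root
}

#' Block coupling matrix of the linearised synaptic map
#'
#' The synaptic currents are a linear map of the gating state,
#' `u = W S + I0 + I_ext`, with block layout
#' `W = [[w_EE I + G w_net C, -diag(w_EI)], [w_IE I, -w_II I]]`.
#' The state ordering is all E nodes first, then all I nodes, everywhere in
#' the package.
#'
#' @param conn A [connectome].
#' @param params A [dmf_params] with `n == conn$n`.
#' @return A `2N x 2N` matrix.
#' @export
coupling_matrix <- function(conn, params) {
  stopifnot(inherits(conn, "connectome"), params$n == conn$n)
  n <- conn$n
  In <- diag(n)
  rbind(
    cbind(params$w_EE * In + params$G * params$w_net * conn$weights,
          -diag(params$w_EI, n)),
    cbind(params$w_IE * In, -params$w_II * In)
  )
}

#' Synaptic input currents of every population
#'
#' `u_E[i] = I0_E + w_EE S_E[i] + G w_net sum_j C[i,j] S_E[j]
#'  - w_EI[i] S_I[i] + I_ext[i]` and
#' `u_I[i] = I0_I + w_IE S_E[i] - w_II S_I[i]`.
#'
#' @param S_E,S_I Gating fractions per node.
#' @param conn A [connectome].
#' @param params A [dmf_params].
#' @param I_ext External input per node in nA (scalar or length-N vector),
#'   applied to the excitatory populations.
#' @return A list with vectors `u_E` and `u_I` (nA).
#' @export
synaptic_currents <- function(S_E, S_I, conn, params, I_ext = 0) {
  n <- conn$n
  stopifnot(length(S_E) == n, length(S_I) == n)
  I_ext <- rep_len(I_ext, n)
  u_E <- params$I0_E + params$w_EE * S_E +
    params$G * params$w_net * drop(conn$weights %*% S_E) -
    params$w_EI * S_I + I_ext
  u_I <- params$I0_I + params$w_IE * S_E - params$w_II * S_I
  list(u_E = u_E, u_I = u_I)
}

#' Deterministic drift of the gating equations
#'
#' `dS_E/dt = -S_E/tau_E + (1 - S_E) gamma r_E` and
#' `dS_I/dt = -S_I/tau_I + r_I`, with rates from [transfer_rate()] applied
#' to [synaptic_currents()].
#'
#' @param state Length-`2N` state vector (E block then I block).
#' @inheritParams synaptic_currents
#' @return Length-`2N` drift vector.
#' @export
dmf_drift <- function(state, conn, params, I_ext = 0) {
  n <- conn$n
  stopifnot(length(state) == 2L * n)
  S_E <- state[seq_len(n)]
  S_I <- state[n + seq_len(n)]
  u <- synaptic_currents(S_E, S_I, conn, params, I_ext)
  r_E <- transfer_rate(u$u_E, "E", params)
  r_I <- transfer_rate(u$u_I, "I", params)
  c(-S_E / params$tau_E + (1 - S_E) * params$gamma * r_E,
    -S_I / params$tau_I + r_I)
}

#' Analytic Jacobian of the drift
#'
#' First-order partial derivatives of the deterministic drift with respect
#' to every gating variable, evaluated at the state `mu`, via the chain rule
#' through the transfer functions and the coupling blocks. Block layout
#' `A = [[A_EE, A_EI], [A_IE, A_II]]` in the all-E-then-all-I ordering.
#'
#' @param mu Length-`2N` state (typically a fixed point).
#' @inheritParams synaptic_currents
#' @return A `2N x 2N` matrix.
#' @export
dmf_jacobian <- function(mu, conn, params, I_ext = 0) {
  n <- conn$n
  stopifnot(length(mu) == 2L * n)
  S_E <- mu[seq_len(n)]
  S_I <- mu[n + seq_len(n)]
  u <- synaptic_currents(S_E, S_I, conn, params, I_ext)
  r_E <- transfer_rate(u$u_E, "E", params)
  dr_E <- transfer_rate_deriv(u$u_E, "E", params)
  dr_I <- transfer_rate_deriv(u$u_I, "I", params)
  gE <- (1 - S_E) * params$gamma   # gain of the E gating growth term
  # dU_E/dS_E = w_EE I + G w_net C ; dU_E/dS_I = -diag(w_EI)
  A_EE <- gE * dr_E * (params$w_EE * diag(n) +
                         params$G * params$w_net * conn$weights)
  diag(A_EE) <- diag(A_EE) - 1 / params$tau_E - params$gamma * r_E
  A_EI <- diag(-gE * dr_E * params$w_EI, n)
  A_IE <- diag(dr_I * params$w_IE, n)
  A_II <- diag(-1 / params$tau_I - dr_I * params$w_II, n)
  rbind(cbind(A_EE, A_EI), cbind(A_IE, A_II))
}

#' Deterministic fixed point of the network
#'
#' Damped Newton iteration on the drift, using the analytic Jacobian. The
#' model with calibrated feedback inhibition has a single stable low-rate
#' fixed point in its operating range, which this finds from a low-activity
#' start.
#'
#' @inheritParams synaptic_currents
#' @param init Optional length-`2N` starting state.
#' @param tol Convergence tolerance on the max drift norm (default 1e-12).
#' @param max_iter Maximum Newton iterations.
#' @return Length-`2N` fixed-point state.
#' @export
fixed_point <- function(conn, params, I_ext = 0, init = NULL,
                        tol = 1e-12, max_iter = 100L) {
  n <- conn$n
  if (is.null(init)) init <- c(rep(0.16, n), rep(0.04, n))
  I_ext <- rep_len(I_ext, n)
  if (any(I_ext != 0)) {
    # continuation in the external input: strong stimuli can move the
    # operating point far from the spontaneous state, so ramp the input
    # and track the branch
    x <- fixed_point(conn, params, 0, init, tol, max_iter)
    for (fr in c(0.25, 0.5, 0.75, 1)) {
      x <- newton_fp(x, conn, params, fr * I_ext, tol, max_iter)
    }
    return(x)
  }
  newton_fp(init, conn, params, I_ext, tol, max_iter)
}

newton_fp <- function(init, conn, params, I_ext, tol, max_iter) {
  x <- init
  for (it in seq_len(max_iter)) {
    f <- dmf_drift(x, conn, params, I_ext)
    nf <- max(abs(f))
    if (nf < tol) return(x)
    J <- dmf_jacobian(x, conn, params, I_ext)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) break
    # backtracking: accept the largest damped step that reduces the
    # residual and stays near the physical range
    lam <- 1
    repeat {
      xn <- x - lam * step
      ok <- all(xn > -0.2 & xn < 1.2) &&
        max(abs(dmf_drift(xn, conn, params, I_ext))) < nf
      if (ok || lam < 1e-6) break
      lam <- lam / 2
    }
    if (lam < 1e-6) break
    x <- xn
  }
  f <- dmf_drift(x, conn, params, I_ext)
  if (max(abs(f)) > 1e-8) {
    # fall back to relaxing the deterministic flow toward the attractor,
    # then polish with Newton (the I gating variables limit the step:
    # their relaxation rate is ~1/tau_I + w_II * Phi_I')
    x <- init
    dt <- 2e-3
    for (s in seq_len(30000L)) {
      f <- dmf_drift(x, conn, params, I_ext)
      x <- pmin(pmax(x + dt * f, 0), 1)
      if (s %% 500L == 0L && max(abs(f)) < 1e-5) break
    }
    for (it in seq_len(50L)) {
      f <- dmf_drift(x, conn, params, I_ext)
      if (max(abs(f)) < tol) return(x)
      J <- dmf_jacobian(x, conn, params, I_ext)
      x <- x - solve(J, f)
    }
    f <- dmf_drift(x, conn, params, I_ext)
    if (max(abs(f)) > 1e-8) {
      stop("fixed-point iteration did not converge (max |drift| = ",
           format(max(abs(f))), ")")
    }
  }
  x
}
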