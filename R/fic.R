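#' Feedback inhibition control (FIC) calibration
#'
#' Sets each node's inhibitory-to-excitatory weight `w_EI[i]` so that the
#' stationary firing rate of every excitatory population equals
#' `target_rate`, whether nodes are connected or not.
#'
#' Because the target pins every excitatory rate (and hence every `S_E`) to
#' the same value, the calibration has a closed-form solution: the E input
#' current `u_E*` is the inverse transfer function at the target rate, the
#' E gating level is `S_E* = gamma r* tau_E / (1 + gamma r* tau_E)`, the I
#' population's stationary state solves a scalar fixed-point equation that
#' does not involve `w_EI`, and the feedback weight of node `i` balances the
#' current budget:
#' `w_EI[i] = (I0_E + w_EE S_E* + G w_net rowsum_i(C) S_E* - u_E*) / S_I*`.
#' The result is verified by a Newton solve of the full network drift and a
#' stability check of the Jacobian.
#'
#' @param conn A [connectome].
#' @param params A [dmf_params]; its `w_EI` entries are ignored.
#' @param target_rate Target excitatory rate in Hz (default 3).
#' @param tol Verification tolerance on the achieved rates, Hz.
#' @param max_iter Maximum Newton iterations for the verification solve.
#' @return A list of class `"fic_result"`: `w_EI` (per-node weights),
#'   `achieved_rates` (Hz), `params` (the calibrated [dmf_params]),
#'   `fixed_point` (the `2N` stationary state), `iterations`, `converged`,
#'   and `stable` (all Jacobian eigenvalues in the left half-plane).
#' @export
calibrate_fic <- function(conn, params, target_rate = 3, tol = 0.05,
                          max_iter = 100L) {
  stopifnot(inherits(conn, "connectome"), params$n == conn$n)
  n <- conn$n
  u_E_star <- invert_transfer_E(target_rate, params)
  gr <- params$gamma * target_rate * params$tau_E
  S_E_star <- gr / (1 + gr)
  # I population: S_I = tau_I * Phi_I(I0_I + w_IE S_E* - w_II S_I)
  g <- function(S_I) {
    params$tau_I * transfer_rate(
      params$I0_I + params$w_IE * S_E_star - params$w_II * S_I,
      "I", params) - S_I
  }
  S_I_star <- uniroot(g, c(0, 1), tol = 1e-14)$root
  rowsum_C <- drop(conn$weights %*% rep(1, n))
  w_EI <- (params$I0_E + params$w_EE * S_E_star +
             params$G * params$w_net * rowsum_C * S_E_star - u_E_star) /
    S_I_star
  if (any(w_EI <= 0)) {
    stop("FIC infeasible: nonpositive feedback weight at node(s) ",
         paste(which(w_EI <= 0), collapse = ", "),
         " (target rate exceeds the uninhibited rate)")
  }
  params$w_EI <- w_EI
  mu <- fixed_point(conn, params,
                    init = c(rep(S_E_star, n), rep(S_I_star, n)),
                    max_iter = max_iter)
  u <- synaptic_currents(mu[seq_len(n)], mu[n + seq_len(n)], conn, params)
  achieved <- transfer_rate(u$u_E, "E", params)
  worst <- which.max(abs(achieved - target_rate))
  converged <- abs(achieved[worst] - target_rate) <= tol
  if (!converged) {
    stop("FIC verification failed: node ", worst, " at ",
         format(achieved[worst]), " Hz (target ", target_rate, " Hz)")
  }
  A <- dmf_jacobian(mu, conn, params)
  stable <- max(Re(eigen(A, only.values = TRUE)$values)) < 0
  structure(list(w_EI = w_EI, achieved_rates = achieved, params = params,
                 fixed_point = mu, iterations = 1L, converged = converged,
                 stable = stable, target_rate = target_rate),
            class = "fic_result")
}

#' @export
print.fic_result <- function(x, ...) {
  cat(sprintf(
    "FIC calibration: %d nodes, target %.3g Hz, max rate error %.2e Hz, %s\n",
    length(x$w_EI), x$target_rate,
    max(abs(x$achieved_rates - x$target_rate)),
    if (x$stable) "stable fixed point" else "UNSTABLE fixed point"))
  invisible(x)
}
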