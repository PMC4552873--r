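# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Small two-module network for simulator/LNA cross-checks.
tiny_conn <- function() {
  memo("tiny_conn", {
    spec <- modular_graph_spec(8L, 2L, q = 0.4, p = 0.5, scale = 0.03,
                               seed = 42L)
    generate_modular_connectome(spec)
  })
}

tiny_fic <- function(G = 1) {
  memo(paste0("tiny_fic_", G), {
    calibrate_fic(tiny_conn(), dmf_params(8L, G = G))
  })
}

# 66-node modular graph at the per-link weight scaling used for the
# whole-network experiments (binary graph, each link 0.025).
s2_conn <- function(p = 0.5, seed = 1L) {
  memo(paste0("s2_conn_", p, "_", seed), {
    spec <- modular_graph_spec(66L, 5L, q = 0.14, p = p, scale = 0.025,
                               seed = seed)
    generate_modular_connectome(spec)
  })
}

s2_experiment <- function() {
  memo("s2_experiment", {
    run_stimulation_experiment(s2_conn(), G = 1,
                               targets = default_stim_targets(s2_conn()),
                               tau_max = 8)
  })
}

# Paired surrogate rest/task study (the empirical-data stand-in).
surrogate_study <- function() {
  memo("surrogate_study", surrogate_rest_task(seed = 11L))
}

# Fake moment solution for analytic (scalar OU and small linear) systems,
# bypassing the model: exactly the fields the LNA operators read.
ou_solution <- function(A, Qn, W = diag(nrow(A))) {
  e <- eigen(A)
  P <- lyapunov_solve(A, Qn)
  structure(list(mu = rep(0, nrow(A)), P = P, A = A, Qn = Qn,
                 I_ext = rep(0, nrow(A) / 2), eig = e, W = W,
                 mean_u = rep(1, nrow(A)), residual = 0,
                 converged = TRUE, n = nrow(A) %/% 2L),
            class = "moment_solution")
}
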