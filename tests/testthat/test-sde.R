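test_that("noiseless simulation stays at the fixed point", {
  conn <- tiny_conn()
  fic <- tiny_fic()
  p <- fic$params
  p$beta <- 0
  ens <- simulate_ensemble(conn, p, duration = 0.2, n_trials = 1L,
                           seed = 1L, record = "gating", burn_in = 0.5)
  drift_span <- apply(ens$trajectories[, , 1L], 2L, function(x)
    diff(range(x)))
  expect_lt(max(drift_span), 1e-9)
  expect_equal(ens$trajectories[1L, , 1L], fic$fixed_point,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("simulation is reproducible given a seed and errors on one trial", {
  conn <- tiny_conn()
  p <- tiny_fic()$params
  e1 <- simulate_ensemble(conn, p, duration = 0.05, n_trials = 2L, seed = 3L)
  e2 <- simulate_ensemble(conn, p, duration = 0.05, n_trials = 2L, seed = 3L)
  expect_identical(e1$trajectories, e2$trajectories)
  expect_error(ensemble_variance(e1[c("trajectories", "n_trials")] |>
                                   (\(x) {x$n_trials <- 1L; x})()),
               "2 trials")
})

test_that("ensemble statistics behave on known inputs", {
  # identical trials: zero variance everywhere
  traj <- array(rep(matrix(1:20, 10L), 3L), c(10L, 2L, 3L))
  ens <- list(trajectories = traj, t = (0:9) * 0.01, dt = 0.01,
              n_trials = 3L, n = 1L)
  expect_true(all(ensemble_variance(ens) == 0))
  # i.i.d. unit-variance Gaussian trials: variance ~ 1, lag-0
  # autocovariance equals the variance, nonzero lags ~ 0
  set.seed(5)
  traj <- array(rnorm(50 * 2 * 4000), c(50L, 2L, 4000L))
  ens <- list(trajectories = traj, t = (0:49) * 0.01, dt = 0.01,
              n_trials = 4000L, n = 1L)
  v <- ensemble_variance(ens)
  expect_equal(mean(v), 1, tolerance = 0.05)
  ac <- ensemble_autocovariance(ens, t_ref = 0.2, lags = c(0, 0.05, 0.1))
  expect_equal(ac[, 1L], v[21L, ], tolerance = 1e-12)
  expect_lt(max(abs(ac[, 2:3])), 4 / sqrt(4000))
  expect_error(ensemble_autocovariance(ens, t_ref = 0.45, lags = 0.2),
               "window")
})

test_that("delta time courses are zero for identical ensembles", {
  conn <- tiny_conn()
  p <- tiny_fic()$params
  ens <- simulate_ensemble(conn, p, duration = 0.1, n_trials = 5L, seed = 9L)
  d <- delta_timecourses(ens, ens)
  expect_equal(max(abs(d$delta_m), na.rm = TRUE), 0)
  expect_equal(max(abs(d$delta_sigma2), na.rm = TRUE), 0)
})

test_that("stationary ensemble variance matches the Lyapunov covariance", {
  conn <- tiny_conn()
  p <- tiny_fic()$params
  sol <- solve_moments(conn, p)
  ens <- simulate_ensemble(conn, p, duration = 0.3, n_trials = 1000L,
                           seed = 21L, record = "gating", burn_in = 2)
  # across-trial variance at the last recorded time vs diag(P)
  v_mc <- ensemble_variance(ens)
  v_hat <- colMeans(v_mc[nrow(v_mc) - 0:4, ])   # small time average
  se <- diag(sol$P) * sqrt(2 / (1000 - 1))
  expect_true(all(abs(v_hat - diag(sol$P)) < 3.5 * se))
  # currents: variance vs diag(W P W')
  ens_u <- simulate_ensemble(conn, p, duration = 0.3, n_trials = 1000L,
                             seed = 22L, record = "current", burn_in = 2)
  Cv <- synaptic_covariance(sol)
  vu <- colMeans(ensemble_variance(ens_u)[296:300, ])
  expect_true(all(abs(vu - diag(Cv)) < 4 * diag(Cv) * sqrt(2 / 999)))
})

test_that("simulated autocorrelation follows the linear-noise prediction", {
  conn <- tiny_conn()
  p <- tiny_fic()$params
  sol <- solve_moments(conn, p)
  acf_th <- lna_autocovariance(sol, seq(0, 0.4, by = 0.005),
                               compute_t95 = FALSE)
  ens <- simulate_ensemble(conn, p, duration = 0.8, n_trials = 1500L,
                           seed = 23L, record = "current", subsample = 50L,
                           burn_in = 2)
  lags <- seq(0, 0.4, by = 0.05)
  ac <- ensemble_autocovariance(ens, t_ref = 0.2, lags = lags)
  acn <- ac / ac[, 1L]
  idx <- round(lags / 0.005) + 1L
  # node-averaged excitatory ACF within Monte-Carlo error
  mc <- colMeans(acn[1:8, ])
  th <- colMeans(acf_th$acf[1:8, idx])
  expect_lt(max(abs(mc - th)), 0.1)
})
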