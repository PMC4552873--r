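test_that("Lyapunov solver handles closed-form and random stable systems", {
  expect_equal(lyapunov_solve(-diag(2), 2 * diag(2)), diag(2),
               tolerance = 1e-12)
  set.seed(31)
  for (i in 1:5) {
    n <- 12L
    A <- matrix(rnorm(n^2), n) - 4 * diag(n)
    Q <- crossprod(matrix(rnorm(n^2), n)) / n
    P <- lyapunov_solve(A, Q)
    expect_lt(norm(A %*% P + P %*% t(A) + Q, "F") / norm(Q, "F"), 1e-10)
    expect_gte(min(eigen(P, symmetric = TRUE)$values), -1e-12)
  }
  expect_error(lyapunov_solve(diag(2), diag(2)), "not stable")
})

test_that("stationary moments satisfy the Lyapunov equation tightly", {
  conn <- tiny_conn()
  p <- tiny_fic()$params
  for (I in list(0, c(rep(0.02, 2L), rep(0, 6L)))) {
    sol <- solve_moments(conn, p, I)
    expect_lt(sol$residual, 1e-8)
    expect_equal(sol$P, t(sol$P), tolerance = 1e-12)
    Cv <- synaptic_covariance(sol)
    expect_true(all(diag(Cv) >= 0))
  }
  # W = identity gives Cv = P
  sol <- solve_moments(conn, p)
  expect_equal(synaptic_covariance(sol, diag(16L)), sol$P,
               tolerance = 1e-14)
})

test_that("scalar Ornstein-Uhlenbeck closed forms are reproduced", {
  a <- 20; q <- 3
  A <- matrix(-a, 1, 1)
  sol <- ou_solution(A, matrix(q, 1, 1))
  # stationary variance q / 2a
  expect_equal(sol$P[1, 1], q / (2 * a), tolerance = 1e-12)
  # ACF(tau) = exp(-a tau); T95 at log(20)/a
  tau <- seq(0, 0.4, by = 0.001)
  # 2x2 embedding (two independent OUs) so E and I blocks exist
  A2 <- diag(c(-a, -a))
  sol2 <- ou_solution(A2, diag(q, 2))
  acf <- lna_autocovariance(sol2, tau)
  expect_equal(acf$acf[1, ], exp(-a * tau), tolerance = 1e-9)
  expect_equal(acf$t95_E, log(20) / a, tolerance = 1e-3)
  # PSD is the Lorentzian q / (a^2 + w^2)
  f <- c(0.5, 2, 10, 40)
  sp <- cross_spectrum(sol2, f)
  expect_equal(sp$psd[1, ], q / (a^2 + (2 * pi * f)^2), tolerance = 1e-10)
})

test_that("integrating the PSD over frequency recovers the variance", {
  conn <- tiny_conn()
  p <- tiny_fic()$params
  sol <- solve_moments(conn, p)
  Cv <- synaptic_covariance(sol)
  # two-sided angular-frequency convention: var = (1/pi) int_0^inf S dw
  f <- exp(seq(log(1e-3), log(5e3), length.out = 3000L))
  sp <- cross_spectrum(sol, f)
  w <- 2 * pi * f
  var_hat <- apply(sp$psd, 1L, function(s)
    sum(diff(w) * (s[-1] + s[-length(s)]) / 2) / pi)
  expect_equal(unname(var_hat), unname(diag(Cv)), tolerance = 0.01)
})

test_that("autocovariance propagation starts at P and decays to zero", {
  conn <- tiny_conn()
  p <- tiny_fic()$params
  sol <- solve_moments(conn, p)
  acf <- lna_autocovariance(sol, seq(0, 10, by = 0.01))
  Cv <- synaptic_covariance(sol)
  expect_equal(unname(acf$F_u[, 1L]), unname(diag(Cv)), tolerance = 1e-10)
  expect_true(all(acf$acf[, 1L] == 1))
  expect_lt(max(abs(acf$F_u[, ncol(acf$F_u)])), 1e-3 * max(diag(Cv)))
  expect_true(is.finite(acf$t95_E) && acf$t95_E > 0)
  expect_error(lna_autocovariance(sol, seq(0, 0.001, by = 5e-4)), "extend")
})

test_that("response metrics are exactly zero without a stimulus", {
  conn <- tiny_conn()
  p <- tiny_fic()$params
  sol <- solve_moments(conn, p)
  m <- response_metrics(sol, sol, freq_hz = c(1, 10, 100), targets = 1:2)
  expect_equal(max(abs(m$delta_m)), 0)
  expect_equal(max(abs(m$delta_sigma2)), 0)
  expect_equal(max(abs(m$delta_psd)), 0)
  expect_equal(m$fc_similarity, 1, tolerance = 1e-12)
})

test_that("relative metrics are invariant to rescaling the noise", {
  conn <- tiny_conn()
  p <- tiny_fic()$params
  I_ext <- c(rep(0.02, 2L), rep(0, 6L))
  f <- 10^seq(-1, 2, length.out = 60L)
  tau <- seq(0, 10, by = 0.01)
  run <- function(c_scale) {
    Qn <- diag(c_scale * p$beta^2, 16L)
    spont <- solve_moments(conn, p, 0, Qn)
    task <- solve_moments(conn, p, I_ext, Qn)
    list(m = response_metrics(spont, task, f, targets = 1:2),
         t95 = lna_autocovariance(spont, tau)$t95_E,
         dH = gaussian_entropy(synaptic_covariance(spont)[1:8, 1:8]) -
           gaussian_entropy(synaptic_covariance(task)[1:8, 1:8]),
         kld = kld_gaussian(synaptic_covariance(spont), Qn))
  }
  r1 <- run(1); r4 <- run(4)
  expect_equal(r1$m$delta_sigma2, r4$m$delta_sigma2, tolerance = 1e-8)
  expect_equal(r1$m$delta_psd, r4$m$delta_psd, tolerance = 1e-8)
  expect_equal(r1$t95, r4$t95, tolerance = 1e-10)
  expect_equal(r1$dH, r4$dH, tolerance = 1e-8)
  expect_equal(r1$kld, r4$kld, tolerance = 1e-8)
})

test_that("transient moments relax from spontaneous to evoked and back", {
  conn <- tiny_conn()
  p <- tiny_fic()$params
  # the slowest relaxation of this weakly-coupled network is ~4 s, so
  # each phase spans several of those
  prot <- stimulus_protocol(1:2, 0.02, onset = 2, offset = 32)
  tr <- solve_moments_transient(conn, p, prot, t_max = 62, dt_store = 0.5,
                                dt_int = 2e-3)
  task <- solve_moments(conn, p, protocol_input(prot, 8L))
  # late in the stimulus the mean matches the evoked stationary state
  k_on <- which(tr$t > 30 & tr$t < 31.8)[1]
  expect_equal(tr$mean_u[1, k_on], unname(task$mean_u[1]),
               tolerance = 0.005)
  # variance of a directly stimulated node is quenched during the input
  v_task <- unname(diag(synaptic_covariance(task)))
  v_spont <- unname(diag(synaptic_covariance(tr$spont)))
  expect_lt(tr$var_u[1, k_on], v_spont[1])
  expect_equal(tr$var_u[1, k_on], v_task[1], tolerance = 0.02)
  # after the offset the integration settles on a genuine zero-input
  # attractor, and the integrated covariance agrees with the algebraic
  # Lyapunov solution evaluated there (this fixture is hysteretic: the
  # released network need not fall back into the spontaneous basin)
  expect_lt(max(abs(dmf_drift(tr$mu_final, conn, p))), 1e-5)
  A_end <- dmf_jacobian(tr$mu_final, conn, p)
  P_alg <- lyapunov_solve(A_end, diag(p$beta^2, 16L))
  expect_equal(tr$P_final, P_alg, tolerance = 0.01, ignore_attr = TRUE)
})
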