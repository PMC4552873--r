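test_that("modular generator hits the requested density and structure", {
  spec <- modular_graph_spec(66L, 5L, q = 0.14, p = 0.5, seed = 3L)
  conn <- generate_modular_connectome(spec)
  n <- 66L
  n_slots <- n * (n - 1L)
  # realized density equals round(q * slots) / slots by construction;
  # check it sits within 3 binomial standard errors of q
  se <- sqrt(0.14 * 0.86 / n_slots)
  expect_lt(abs(link_density(conn) - 0.14), 3 * se)
  # realized within-module fraction equals p (links placed by quota)
  mod <- conn$modules
  links <- which(conn$weights > 0, arr.ind = TRUE)
  within <- mod[links[, 1]] == mod[links[, 2]]
  expect_equal(mean(within), 0.5, tolerance = 2 / sum(conn$weights > 0))
  # determinism
  conn2 <- generate_modular_connectome(spec)
  expect_identical(conn$weights, conn2$weights)
})

test_that("modular generator limit cases and errors", {
  empty <- generate_modular_connectome(
    modular_graph_spec(20L, 4L, q = 0, p = 0.3, seed = 1L))
  expect_equal(sum(empty$weights), 0)
  allin <- generate_modular_connectome(
    modular_graph_spec(20L, 4L, q = 0.2, p = 1, seed = 1L))
  mod <- allin$modules
  links <- which(allin$weights > 0, arr.ind = TRUE)
  expect_true(all(mod[links[, 1]] == mod[links[, 2]]))
  # q so large that the within-module budget cannot be met
  expect_error(generate_modular_connectome(
    modular_graph_spec(20L, 4L, q = 0.9, p = 1, seed = 1L)), "infeasible")
})

test_that("mean-weight calibration gives the requested matrix mean", {
  conn <- synthetic_connectome_66(seed = 1L)
  expect_equal(mean(conn$weights), 0.025, tolerance = 1e-12)
  expect_equal(link_density(conn), 0.14, tolerance = 0.005)
  expect_identical(conn$n, 66L)
  sym <- generate_modular_connectome(
    modular_graph_spec(30L, 3L, q = 0.2, p = 0.5, seed = 2L),
    mean_weight = 0.01, symmetric = TRUE)
  expect_equal(mean(sym$weights), 0.01, tolerance = 1e-12)
  expect_identical(sym$weights, t(sym$weights))
})

test_that("surrogate fMRI frames carry the requested covariance", {
  Sigma <- diag(c(1, 2, 0.5))
  spec <- surrogate_fmri_spec(Sigma, n_frames = 4000L, n_runs = 1L,
                              n_subjects = 1L, seed = 5L)
  rest <- generate_surrogate_fmri(spec, "rest")
  X <- rest$series[[1]][[1]]
  expect_lt(norm(cov(X) - Sigma, "F") / norm(Sigma, "F"), 0.1)
  # Gaussian entropy of an identity covariance: (n/2) log2(2 pi e)
  spec_id <- surrogate_fmri_spec(diag(6), n_frames = 6000L, n_runs = 1L,
                                 n_subjects = 1L, seed = 6L)
  Xi <- generate_surrogate_fmri(spec_id, "rest")$series[[1]][[1]]
  H_hat <- gaussian_entropy(cov(Xi))
  expect_equal(H_hat, 3 * log2(2 * pi * exp(1)), tolerance = 0.1)
  # scaling law: cov -> alpha cov shifts entropy by (n/2) log2 alpha
  H4 <- gaussian_entropy(cov(2 * Xi))
  expect_equal(H4 - H_hat, 3 * log2(4), tolerance = 1e-9)
  # determinism
  again <- generate_surrogate_fmri(spec, "rest")
  expect_identical(again$series[[1]][[1]], X)
})

test_that("task surrogates place onsets with the requested ISI range", {
  spec <- surrogate_fmri_spec(diag(3), n_frames = 194L, n_runs = 4L,
                              n_subjects = 3L, seed = 9L)
  task <- generate_surrogate_fmri(spec, "task")
  for (s in seq_len(3L)) for (r in seq_len(4L)) {
    o <- task$onsets[[s]][[r]]
    expect_gt(length(o), 5L)
    isi <- diff(o) * spec$tr_seconds
    # onsets are rounded to frames: allow one TR of slack on each side
    expect_true(all(isi >= 17.3 - spec$tr_seconds))
    expect_true(all(isi <= 30.2 + spec$tr_seconds))
  }
})

test_that("finite-sample noise covariance converges to its diagonal base", {
  q1 <- generate_correlated_noise_covariance(10L, 100L, 2, seed = 1L)
  q2 <- generate_correlated_noise_covariance(10L, 20000L, 2, seed = 1L)
  expect_identical(q1, t(q1))
  expect_gte(min(eigen(q1, symmetric = TRUE)$values), 0)
  # off-diagonal mass shrinks roughly as 1/sqrt(n_samples)
  off <- function(S) mean(abs(S[upper.tri(S)]))
  expect_lt(off(q2), off(q1) / 5)
  expect_lt(norm(q2 - diag(2, 10L), "F") / norm(diag(2, 10L), "F"), 0.05)
  expect_identical(q1, generate_correlated_noise_covariance(10L, 100L, 2,
                                                            seed = 1L))
  # full-rank at the study size: 2N = 132 variables, 500 samples
  qq <- generate_correlated_noise_covariance(132L, 500L, 1e-4, seed = 2L)
  expect_identical(qr(qq)$rank, 132L)
})
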