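test_that("Gaussian entropy closed forms and block additivity hold", {
  expect_equal(gaussian_entropy(matrix(1, 1, 1)), 0.5 * log2(2 * pi * exp(1)),
               tolerance = 1e-12)
  set.seed(41)
  S <- crossprod(matrix(rnorm(36), 6)) + diag(6)
  # scaling law
  expect_equal(gaussian_entropy(3 * S) - gaussian_entropy(S), 3 * log2(3),
               tolerance = 1e-10)
  # block-diagonal additivity
  B <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  blockdiag <- rbind(cbind(S, matrix(0, 6, 4)),
                     cbind(matrix(0, 4, 6), B))
  expect_equal(gaussian_entropy(blockdiag),
               gaussian_entropy(S) + gaussian_entropy(B), tolerance = 1e-10)
  expect_error(gaussian_entropy(matrix(c(1, 2, 2, 1), 2)), "svd_entropy")
})

test_that("svd entropy truncates rank and matches the full-rank formula", {
  set.seed(42)
  X <- matrix(rnorm(500 * 6), 500)
  full <- svd_entropy(X)
  expect_identical(full$k, 6L)
  expect_equal(full$H, gaussian_entropy(cov(X)), tolerance = 1e-10)
  # rank-3 data: project onto a 3-dimensional subspace of 6 variables
  B <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:3]
  Xr <- (X[, 1:3] %*% t(B))
  red <- svd_entropy(Xr)
  expect_identical(red$k, 3L)
  # invariance to variable ordering
  perm <- sample(6)
  expect_equal(svd_entropy(Xr[, perm])$H, red$H, tolerance = 1e-10)
  expect_error(svd_entropy(matrix(1, 5, 3)), "degenerate")
})

test_that("nearest-neighbour entropy converges on Gaussian samples", {
  set.seed(43)
  d <- 3L
  H_true <- (d / 2) * log2(2 * pi * exp(1))
  err <- vapply(c(500L, 2000L, 8000L), function(n) {
    X <- matrix(rnorm(n * d), n)
    abs(knn_entropy(X) - H_true)
  }, numeric(1))
  expect_lt(err[3], 0.1)
  expect_lt(err[3], err[1])          # bias shrinks with sample size
  # affine transformation law: H(AX) = H(X) + log2|det A|
  X <- matrix(rnorm(4000 * d), 4000)
  A <- matrix(c(2, 0.5, 0, 0, 1.5, 0.3, 0, 0, 0.8), 3, byrow = TRUE)
  dH <- knn_entropy(X %*% t(A)) - knn_entropy(X)
  expect_equal(dH, log2(abs(det(A))), tolerance = 0.15)
  # exact ties are refused unless jittered
  Xd <- rbind(X[1:50, ], X[1:50, ])
  expect_error(knn_entropy(Xd), "duplicate")
  expect_true(is.finite(knn_entropy(Xd, jitter = 1e-8)))
})

test_that("Gaussian KLD closed forms, nonnegativity and zero at equality", {
  set.seed(44)
  Q <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  expect_equal(kld_gaussian(Q, Q), 0, tolerance = 1e-10)
  # commuting case Cv = 2 Qn in dimension d
  d <- 5
  expect_equal(kld_gaussian(2 * Q, Q), 0.5 * (2 * d - d * log(2) - d) / log(2),
               tolerance = 1e-10)
  for (i in 1:5) {
    C2 <- crossprod(matrix(rnorm(25), 5)) + diag(5)
    expect_gte(kld_gaussian(C2, Q), 0)
  }
  expect_error(kld_gaussian(Q, diag(4)), "dimension")
})

test_that("zero-amplitude stimulation leaves entropy untouched", {
  conn <- tiny_conn()
  p <- tiny_fic()$params
  rep0 <- random_stimulation_entropy(conn, p, n_stims = 3L, n_targets = 2L,
                                     amplitude = 0, seed = 2L)
  expect_equal(rep0$stimulations$H_task_E, rep(rep0$H_spont_E, 3L),
               tolerance = 1e-9)
  expect_equal(rep0$stimulations$KLD_task_E, rep(rep0$KLD_spont_E, 3L),
               tolerance = 1e-9)
})

test_that("stimulation reduces entropy under diagonal and common noise", {
  conn <- tiny_conn()
  p <- tiny_fic()$params
  for (mode in c("diagonal", "correlated")) {
    rep1 <- random_stimulation_entropy(conn, p, n_stims = 5L, n_targets = 2L,
                                       amplitude = 0.02, seed = 3L,
                                       qn_mode = mode)
    expect_true(all(rep1$stimulations$H_task_E < rep1$H_spont_E))
    expect_true(all(rep1$stimulations$H_task_I < rep1$H_spont_I))
    expect_true(all(is.finite(unlist(
      rep1$stimulations[c("KLD_task_E", "KLD_task_I")]))))
  }
  # deterministic given the seed
  a <- random_stimulation_entropy(conn, p, n_stims = 2L, n_targets = 2L,
                                  seed = 7L)
  b <- random_stimulation_entropy(conn, p, n_stims = 2L, n_targets = 2L,
                                  seed = 7L)
  expect_identical(a$stimulations$H_task_E, b$stimulations$H_task_E)
})
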