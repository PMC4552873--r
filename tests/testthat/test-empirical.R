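test_that("subject entropy recovers a constructed covariance halving", {
  Sigma <- diag(6)
  spec_r <- surrogate_fmri_spec(Sigma, n_frames = 2000L, n_runs = 2L,
                                n_subjects = 3L, seed = 61L)
  spec_t <- surrogate_fmri_spec(Sigma / 2, n_frames = 2000L, n_runs = 2L,
                                n_subjects = 3L, seed = 62L)
  rest <- generate_surrogate_fmri(spec_r, "rest")
  task <- generate_surrogate_fmri(spec_t, "rest")
  h_r <- subject_entropy(rest, "gaussian_svd")
  h_t <- subject_entropy(task, "gaussian_svd")
  # H difference for a halved covariance: (n/2) log2(2) = 3 bits
  expect_equal(mean(h_r$H - h_t$H), 3, tolerance = 0.15)
  h_k <- subject_entropy(rest, "knn")
  expect_true(all(is.finite(h_k$H)))
  expect_error(subject_entropy(
    fmri_dataset(list(list(matrix(rnorm(30), 10))), "rest")), "2 runs")
})

test_that("the paired Wilcoxon test matches exact and brute-force nulls", {
  # all 17 differences positive (distinct magnitudes so the exact null
  # applies): the two-sided extreme probability
  h_r <- 10 + (1:17) / 10
  h_t <- h_r - (1:17) / 40
  res <- entropy_difference_test(h_r, h_t)
  expect_equal(res$p_value, 2 / 2^17, tolerance = 1e-12)
  # rank-balanced signs: no evidence
  d <- c(1, -2, 3, -4, 5, -6, 7, -8) / 10
  res2 <- entropy_difference_test(10 + d, rep(10, 8L))
  expect_gt(res2$p_value, 0.7)
  # degenerate all-zero differences reported as no difference
  expect_equal(entropy_difference_test(1:10, 1:10)$p_value, 1)
  # brute-force enumeration oracle at n = 10: the exact distribution of
  # the signed-rank statistic under random sign flips
  set.seed(63)
  d10 <- rnorm(10)
  obs <- entropy_difference_test(d10 + 5, rep(5, 10))
  ranks <- rank(abs(d10))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 10)))
  V_null <- signs %*% ranks
  V_obs <- sum(ranks[d10 > 0])
  p_brute <- min(1, 2 * min(mean(V_null <= V_obs + 1e-9),
                            mean(V_null >= V_obs - 1e-9)))
  expect_equal(obs$p_value, p_brute, tolerance = 1e-9)
})

test_that("time-resolved entropy recovers an injected variance dip", {
  st <- surrogate_study()
  tc <- time_resolved_entropy(st$rest, st$task)
  w <- tc$windows
  # the dip peaks inside the first 8 s after onset (injection latency)
  post <- w$t >= 0 & w$t <= 8.64
  dH <- w$H_task - w$H_rest
  expect_true(which.min(dH) %in% which(post))
  expect_true(all(w$p_value[post] < 0.01))
  # windows count consistent with the +/- 17.3 s span at TR 2.16 s
  expect_identical(nrow(w), 17L)
  expect_equal(max(w$t), 17.28, tolerance = 1e-6)
})

test_that("a stationary null shows no excess significant windows", {
  Sigma <- diag(8)
  spec <- surrogate_fmri_spec(Sigma, n_frames = 194L, n_runs = 4L,
                              n_subjects = 10L, seed = 64L)
  rest <- generate_surrogate_fmri(spec, "rest")
  null_task <- generate_surrogate_fmri(spec, "task")  # onsets, no dip
  tc <- time_resolved_entropy(rest, null_task)
  # 17 windows at alpha = 0.01: more than 2 hits would be surprising
  expect_lte(sum(tc$windows$p_value < 0.01), 2L)
})

test_that("functional connectivity comparison behaves at both extremes", {
  st <- surrogate_study()
  fc0 <- fc_comparison(st$rest, st$rest)
  expect_equal(max(abs(fc0$diff)), 0)
  fc <- fc_comparison(st$rest, st$task)
  expect_identical(length(fc$diff), 528L)
  # the surrogate task rescales variance, leaving correlations intact:
  # differences stay within a small sampling envelope
  expect_lt(max(abs(fc$diff)), 0.06)
  # constant ROI flagged
  broken <- st$rest
  for (r in seq_len(broken$n_runs)) broken$series[[1]][[r]][, 1] <- 1
  expect_error(fc_comparison(broken, st$task), "constant")
})

test_that("the pipeline is invariant to run order within subjects", {
  st <- surrogate_study()
  shuffled <- st$rest
  for (s in seq_len(shuffled$n_subjects)) {
    shuffled$series[[s]] <- rev(shuffled$series[[s]])
  }
  a <- subject_entropy(st$rest, "gaussian_svd")
  b <- subject_entropy(shuffled, "gaussian_svd")
  expect_equal(a$H, b$H, tolerance = 1e-10)
  expect_identical(a$k, b$k)
})
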