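#' Differential entropy of a multivariate Gaussian
#'
#' `H = 1/2 log2((2 pi e)^n det(Sigma))` bits, computed through the
#' Cholesky log-determinant (never the raw determinant, which under- or
#' overflows in high dimension).
#'
#' @param cov Symmetric positive-definite covariance matrix.
#' @return Entropy in bits.
#' @export
gaussian_entropy <- function(cov) {
  cov <- as.matrix(cov)
  n <- nrow(cov)
  stopifnot(n == ncol(cov))
  R <- tryCatch(chol(cov), error = function(e)
    stop("covariance is not positive definite; for rank-deficient data ",
         "use svd_entropy()"))
  logdet2 <- 2 * sum(log2(diag(R)))
  0.5 * (n * log2(2 * pi * exp(1)) + logdet2)
}

#' Gaussian differential entropy of possibly rank-deficient data
#'
#' Estimates the sample covariance of `data`, takes its singular values,
#' keeps the `k` values above a rank tolerance, and computes
#' `H = k/(2 ln 2) (1 + ln(2 pi)) + 1/(2 ln 2) sum_j ln(lambda_j)` bits —
#' the Gaussian entropy restricted to the k-dimensional support, eluding
#' the singularity of the full determinant.
#'
#' @param data Numeric `samples x variables` matrix (>= 2 samples).
#' @param tol_factor Rank tolerance factor: singular values above
#'   `max(lambda) * n * .Machine$double.eps * tol_factor` count as nonzero
#'   (default 1e6, absorbing preprocessing round-off).
#' @return A list with `H` (bits), `k` (retained rank) and
#'   `singular_values`.
#' @export
svd_entropy <- function(data, tol_factor = 1e6) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("need at least 2 samples")
  S <- cov(data)
  lam <- svd(S, nu = 0, nv = 0)$d
  if (max(lam) <= 0) stop("degenerate data: zero variance everywhere")
  thr <- max(lam) * ncol(S) * .Machine$double.eps * tol_factor
  keep <- lam > thr
  k <- sum(keep)
  H <- k / (2 * log(2)) * (1 + log(2 * pi)) +
    sum(log(lam[keep])) / (2 * log(2))
  list(H = H, k = k, singular_values = lam)
}

#' Nonparametric differential entropy from nearest neighbours
#'
#' Nearest-neighbour estimator of differential entropy (the
#' Kozachenko-Leonenko construction underlying the Nilsson-Kleijn
#' estimator): with `eps_i` the distance of sample `i` to its `k`-th
#' nearest neighbour among `N` samples in `d` dimensions,
#' `H = psi(N) - psi(k) + ln(V_d) + (d/N) sum_i ln(eps_i)` nats, converted
#' to bits; `V_d` is the volume of the d-dimensional unit ball. Makes no
#' normality assumption.
#'
#' @param data Numeric `samples x variables` matrix.
#' @param k_neighbors Neighbour order (default 1).
#' @param jitter Optional standard deviation of Gaussian jitter added to
#'   break exact ties (default 0: duplicated points raise an error).
#' @return Entropy in bits.
#' @export
knn_entropy <- function(data, k_neighbors = 1L, jitter = 0) {
  data <- as.matrix(data)
  N <- nrow(data)
  d <- ncol(data)
  if (N <= k_neighbors) stop("need more samples than neighbours")
  if (jitter > 0) data <- data + rnorm(length(data), sd = jitter)
  eps <- knn_kth_dist_cpp(data, as.integer(k_neighbors))
  if (any(eps == 0)) {
    stop("duplicate points give zero nearest-neighbour distances; ",
         "use the jitter argument")
  }
  log_Vd <- (d / 2) * log(pi) - lgamma(d / 2 + 1)
  H_nats <- digamma(N) - digamma(k_neighbors) + log_Vd +
    d * mean(log(eps))
  H_nats / log(2)
}

#' Kullback-Leibler divergence between zero-mean Gaussians
#'
#' `KLD = 1/2 [trace(Qn^-1 Cv) - ln(det(Cv)/det(Qn)) - d] / ln 2` bits:
#' the relative entropy of the activity distribution (covariance `Cv`)
#' from the intrinsic-noise distribution (covariance `Qn`) — the amount of
#' uncertainty the dynamical system adds to its noise inputs. Computed with
#' linear solves and Cholesky log-determinants, no explicit inverses.
#'
#' @param Cv Covariance of the output process (symmetric PD).
#' @param Qn Covariance of the input noise process (symmetric PD, same
#'   dimension).
#' @return Divergence in bits (nonnegative; 0 iff `Cv == Qn`).
#' @export
kld_gaussian <- function(Cv, Qn) {
  Cv <- as.matrix(Cv)
  Qn <- as.matrix(Qn)
  d <- nrow(Cv)
  if (!all(dim(Qn) == d)) stop("dimension mismatch between Cv and Qn")
  Rc <- tryCatch(chol(Cv), error = function(e)
    stop("Cv is not positive definite"))
  Rq <- tryCatch(chol(Qn), error = function(e)
    stop("Qn is not positive definite"))
  tr <- sum(diag(solve(Qn, Cv)))
  logdet_ratio <- 2 * sum(log(diag(Rc))) - 2 * sum(log(diag(Rq)))
  0.5 * (tr - logdet_ratio - d) / log(2)
}

#' Entropy and relative entropy under many random stimulations
#'
#' Solves the stationary linear noise approximation in the spontaneous
#' condition and under `n_stims` random stimulation patterns (an external
#' input of `amplitude` nA to the excitatory populations of `n_targets`
#' randomly selected regions), and for each condition computes the
#' differential entropy of the excitatory-block and inhibitory-block
#' synaptic-current covariance and the Kullback-Leibler divergence of each
#' block from the corresponding intrinsic-noise block.
#'
#' @param conn A [connectome].
#' @param params A FIC-calibrated [dmf_params].
#' @param n_stims Number of random stimulation patterns (default 500).
#' @param n_targets Regions per pattern (default 8).
#' @param amplitude Input per target, nA (default 0.02).
#' @param seed RNG seed.
#' @param qn_mode `"diagonal"` (independent intrinsic noise,
#'   `Qn = beta^2 I`) or `"correlated"` (a random non-diagonal noise
#'   covariance from [generate_correlated_noise_covariance()]).
#' @param n_noise_samples Samples behind the correlated-noise covariance
#'   (default 500).
#' @return A list of class `"entropy_report"`: `H_spont_E/I`,
#'   `KLD_spont_E/I` (scalars, bits), and a data frame `stimulations` with
#'   per-pattern `H_task_E/I`, `KLD_task_E/I` and the target lists.
#' @export
random_stimulation_entropy <- function(conn, params, n_stims = 500L,
                                       n_targets = 8L, amplitude = 0.02,
                                       seed = 1L,
                                       qn_mode = c("diagonal", "correlated"),
                                       n_noise_samples = 500L) {
  qn_mode <- match.arg(qn_mode)
  n <- conn$n
  set.seed(seed)
  Qn <- if (qn_mode == "diagonal") diag(params$beta^2, 2L * n) else
    generate_correlated_noise_covariance(2L * n, n_noise_samples,
                                         params$beta^2,
                                         seed = sample.int(2^30, 1L))
  iE <- seq_len(n)
  iI <- n + iE
  Qn_E <- Qn[iE, iE]
  Qn_I <- Qn[iI, iI]
  block_stats <- function(sol) {
    Cv <- synaptic_covariance(sol)
    c(H_E = gaussian_entropy(Cv[iE, iE]),
      H_I = gaussian_entropy(Cv[iI, iI]),
      KLD_E = kld_gaussian(Cv[iE, iE], Qn_E),
      KLD_I = kld_gaussian(Cv[iI, iI], Qn_I))
  }
  spont <- solve_moments(conn, params, 0, Qn)
  s0 <- block_stats(spont)
  targets <- lapply(seq_len(n_stims), function(i) sample.int(n, n_targets))
  rows <- vapply(targets, function(tg) {
    I_ext <- numeric(n)
    I_ext[tg] <- amplitude
    block_stats(solve_moments(conn, params, I_ext, Qn))
  }, numeric(4))
  stim <- data.frame(stim = seq_len(n_stims),
                     H_task_E = rows["H_E", ], H_task_I = rows["H_I", ],
                     KLD_task_E = rows["KLD_E", ],
                     KLD_task_I = rows["KLD_I", ])
  stim$targets <- I(targets)
  structure(list(H_spont_E = unname(s0["H_E"]),
                 H_spont_I = unname(s0["H_I"]),
                 KLD_spont_E = unname(s0["KLD_E"]),
                 KLD_spont_I = unname(s0["KLD_I"]),
                 stimulations = stim, qn_mode = qn_mode,
                 amplitude = amplitude, n_targets = n_targets),
            class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  dE <- x$H_spont_E - x$stimulations$H_task_E
  cat(sprintf(
    paste0("entropy report (%s noise): %d stimulations; ",
           "H_spont - H_task (E) in [%.2f, %.2f] bits; ",
           "KLD_spont > KLD_task (E) in %.1f%% of stimulations\n"),
    x$qn_mode, nrow(x$stimulations), min(dE), max(dE),
    100 * mean(x$KLD_spont_E > x$stimulations$KLD_task_E)))
  invisible(x)
}
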