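#' Specification of a modular random connectome
#'
#' Parameterises a random binary directed graph with `n_nodes` split into
#' `n_modules` contiguous blocks (as evenly as possible), overall link
#' density `q` and a proportion `p` of links placed within modules.
#'
#' @param n_nodes Number of nodes.
#' @param n_modules Number of modules (default 5).
#' @param q Overall link density in `[0, 1]`.
#' @param p Proportion of links within modules in `[0, 1]`.
#' @param scale Weight given to every link (default 1).
#' @param seed RNG seed.
#' @return A list of class `"modular_graph_spec"`.
#' @export
modular_graph_spec <- function(n_nodes, n_modules = 5L, q, p, scale = 1,
                               seed = 1L) {
  stopifnot(n_nodes >= 2, n_modules >= 1, n_modules <= n_nodes,
            q >= 0, q <= 1, p >= 0, p <= 1, scale > 0)
  structure(list(n_nodes = as.integer(n_nodes),
                 n_modules = as.integer(n_modules),
                 q = q, p = p, scale = scale, seed = as.integer(seed)),
            class = "modular_graph_spec")
}

## Contiguous module assignment, sizes as even as possible.
module_assignment <- function(n_nodes, n_modules) {
  sizes <- rep(n_nodes %/% n_modules, n_modules)
  extra <- n_nodes %% n_modules
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(n_modules), times = sizes)
}

#' Generate a modular random connectome
#'
#' Places `round(q N (N-1))` directed links (zero diagonal): a fraction `p`
#' uniformly at random among within-module ordered pairs, the rest among
#' between-module pairs, both without replacement. Each link carries weight
#' `spec$scale`, unless `mean_weight` is given, in which case the per-link
#' weight is set so the mean over all `N^2` matrix entries equals
#' `mean_weight`. An optional symmetric mode places unordered pairs and
#' mirrors them.
#'
#' @param spec A [modular_graph_spec].
#' @param mean_weight Optional target mean of the full weight matrix.
#' @param symmetric If `TRUE`, generate an undirected (symmetric) graph
#'   with `round(q N (N-1) / 2)` unordered links.
#' @return A [connectome]; module assignment is stored in `$modules`.
#' @export
generate_modular_connectome <- function(spec, mean_weight = NULL,
                                        symmetric = FALSE) {
  stopifnot(inherits(spec, "modular_graph_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes
  mod <- module_assignment(n, spec$n_modules)
  idx <- which(diag(n) == 0)                 # off-diagonal linear indices
  rows <- (idx - 1L) %% n + 1L
  cols <- (idx - 1L) %/% n + 1L
  if (symmetric) {
    keep <- rows < cols
    idx <- idx[keep]; rows <- rows[keep]; cols <- cols[keep]
  }
  within <- mod[rows] == mod[cols]
  n_slots <- length(idx)
  n_links <- round(spec$q * n_slots)
  n_w <- round(spec$p * n_links)
  n_b <- n_links - n_w
  if (n_w > sum(within) || n_b > sum(!within)) {
    stop("infeasible (q, p): need ", n_w, " within-module and ", n_b,
         " between-module links but only ", sum(within), " / ",
         sum(!within), " slots exist")
  }
  chosen <- c(
    if (n_w > 0) sample(idx[within], n_w),
    if (n_b > 0) sample(idx[!within], n_b)
  )
  w_link <- spec$scale
  if (!is.null(mean_weight)) {
    n_placed <- if (symmetric) 2L * n_links else n_links
    if (n_placed == 0) stop("cannot match a mean weight with zero links")
    w_link <- mean_weight * n^2 / n_placed
  }
  W <- matrix(0, n, n)
  W[chosen] <- w_link
  if (symmetric) W <- W + t(W)
  conn <- connectome(W)
  conn$modules <- mod
  conn$synthetic <- TRUE
  conn
}

#' Synthetic 66-region connectome stand-in
#'
#' A synthetic substitute for a DSI-derived 66-region cortical connectivity
#' matrix, generated (not measured) with the summary statistics of such
#' matrices: 66 nodes, link density `q = 0.14`, five modules with a
#' moderate within-module link proportion `p = 0.5` (human connectomes are
#' low-to-intermediately clustered), directed (non-symmetric), and per-link
#' weights calibrated so the mean of the full matrix is `m = 0.025`.
#'
#' @param seed RNG seed (default 1).
#' @param p Within-module link proportion (default 0.5).
#' @return A [connectome] with 66 regions.
#' @export
synthetic_connectome_66 <- function(seed = 1L, p = 0.5) {
  spec <- modular_graph_spec(66L, 5L, q = 0.14, p = p, seed = seed)
  generate_modular_connectome(spec, mean_weight = 0.025)
}

#' Specification of a surrogate ROI fMRI dataset
#'
#' @param covariance Target ROI covariance matrix (symmetric positive
#'   semidefinite); its dimension sets the ROI count.
#' @param n_frames Frames per run (default 194).
#' @param n_runs Runs per subject per condition (default 4).
#' @param n_subjects Number of subjects (default 17).
#' @param tr_seconds Sampling period (default 2.16 s).
#' @param isi_range Min/max inter-stimulus interval in seconds (default
#'   `c(17.3, 30.2)`).
#' @param seed RNG seed.
#' @return A list of class `"surrogate_fmri_spec"`.
#' @export
surrogate_fmri_spec <- function(covariance, n_frames = 194L, n_runs = 4L,
                                n_subjects = 17L, tr_seconds = 2.16,
                                isi_range = c(17.3, 30.2), seed = 1L) {
  covariance <- as.matrix(covariance)
  check_psd(covariance, "covariance")
  stopifnot(n_frames >= 2, n_runs >= 1, n_subjects >= 1,
            isi_range[1] <= isi_range[2], isi_range[1] > 0)
  structure(list(covariance = covariance, n_frames = as.integer(n_frames),
                 n_runs = as.integer(n_runs),
                 n_subjects = as.integer(n_subjects),
                 tr_seconds = tr_seconds, isi_range = isi_range,
                 seed = as.integer(seed)),
            class = "surrogate_fmri_spec")
}

check_psd <- function(S, what) {
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
    stop(what, " must be symmetric")
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop(what, " is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  }
  invisible(TRUE)
}

## Square root factor of a PSD matrix (rank-revealing, for sampling).
psd_factor <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(ev), length(ev))
}

## Stimulus-onset times for one run: first onset after a start-up delay,
## then inter-stimulus intervals uniform in isi_range, until the run ends.
draw_onsets <- function(run_seconds, isi_range, tr) {
  t <- runif(1, isi_range[1] / 2, isi_range[1])
  times <- numeric(0)
  while (t < run_seconds - 2 * tr) {
    times <- c(times, t)
    t <- t + runif(1, isi_range[1], isi_range[2])
  }
  unique(as.integer(pmax(1, round(times / tr) + 1)))
}

#' Generate a surrogate ROI fMRI dataset
#'
#' Frames are drawn i.i.d. from a zero-mean multivariate normal with the
#' spec covariance (or per-subject covariances when given). For the task
#' condition, stimulus onsets are placed with inter-stimulus intervals
#' uniform in `isi_range`, and the frame covariance may be modulated
#' peristimulus: a sustained variance scaling `task_scale` plus a transient
#' dip of depth `dip_depth` following each onset (raised-sine profile over
#' `dip_duration` seconds, emulating the stimulus-driven variance quench
#' seen through the hemodynamic delay).
#'
#' @param spec A [surrogate_fmri_spec].
#' @param condition `"rest"` or `"task"`.
#' @param subject_covariances Optional list of per-subject covariance
#'   matrices (length `n_subjects`), to model inter-subject variability.
#' @param task_scale Sustained variance multiplier in the task condition
#'   (default 1: no sustained change).
#' @param dip_depth Peak fractional variance reduction after each onset
#'   (default 0: no transient).
#' @param dip_duration Duration of the transient dip (s, default 8).
#' @return An [fmri_dataset].
#' @export
generate_surrogate_fmri <- function(spec, condition = c("rest", "task"),
                                    subject_covariances = NULL,
                                    task_scale = 1, dip_depth = 0,
                                    dip_duration = 8) {
  stopifnot(inherits(spec, "surrogate_fmri_spec"))
  condition <- match.arg(condition)
  set.seed(spec$seed + if (condition == "task") 10000L else 0L)
  n_rois <- ncol(spec$covariance)
  run_seconds <- spec$n_frames * spec$tr_seconds
  if (!is.null(subject_covariances)) {
    stopifnot(length(subject_covariances) == spec$n_subjects)
    lapply(subject_covariances, check_psd, what = "subject covariance")
  }
  series <- vector("list", spec$n_subjects)
  onsets <- if (condition == "task") vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    Sigma <- if (is.null(subject_covariances)) spec$covariance
             else subject_covariances[[s]]
    L <- psd_factor(Sigma)
    runs <- vector("list", spec$n_runs)
    run_onsets <- vector("list", spec$n_runs)
    for (r in seq_len(spec$n_runs)) {
      X <- matrix(rnorm(spec$n_frames * n_rois), spec$n_frames) %*% t(L)
      if (condition == "task") {
        o <- draw_onsets(run_seconds, spec$isi_range, spec$tr_seconds)
        run_onsets[[r]] <- o
        scale_t <- rep(task_scale, spec$n_frames)
        if (dip_depth > 0 && length(o)) {
          t_frames <- (seq_len(spec$n_frames) - 1L) * spec$tr_seconds
          for (ot in (o - 1L) * spec$tr_seconds) {
            dt <- t_frames - ot
            in_dip <- dt >= 0 & dt < dip_duration
            scale_t[in_dip] <- scale_t[in_dip] *
              (1 - dip_depth * sin(pi * dt[in_dip] / dip_duration)^2)
          }
        }
        X <- X * sqrt(scale_t)
      }
      runs[[r]] <- X
    }
    series[[s]] <- runs
    if (condition == "task") onsets[[s]] <- run_onsets
  }
  fmri_dataset(series, condition, spec$tr_seconds, onsets = onsets)
}

#' Random non-diagonal noise covariance from finite sampling
#'
#' Draws `n_samples` i.i.d. samples of an `n_vars`-dimensional Gaussian with
#' isotropic diagonal covariance `base_intensity * I` and returns their
#' sample covariance: symmetric, positive semidefinite, and non-diagonal in
#' general purely through sampling error. Converges to the diagonal base as
#' `n_samples` grows. Used to model common (correlated) intrinsic noise
#' across populations.
#'
#' @param n_vars Dimension (e.g. `2N` populations).
#' @param n_samples Number of samples (default 500).
#' @param base_intensity Diagonal intensity of the base covariance.
#' @param seed RNG seed.
#' @return An `n_vars x n_vars` covariance matrix.
#' @export
generate_correlated_noise_covariance <- function(n_vars, n_samples = 500L,
                                                 base_intensity = 1e-4,
                                                 seed = 1L) {
  stopifnot(n_samples > 1)
  set.seed(seed)
  X <- matrix(rnorm(n_samples * n_vars, sd = sqrt(base_intensity)),
              n_samples, n_vars)
  cov(X)
}

#' Paired rest/task surrogate fMRI study
#'
#' Builds a complete synthetic stand-in for a rest-versus-task ROI fMRI
#' study: a 33-ROI population covariance with a functional-network block
#' structure (five networks plus three subcortical regions), rank-reduced
#' to 29 by projecting out four directions (emulating the removal of four
#' nuisance regressors during preprocessing); per-subject covariances drawn
#' from a Wishart distribution around it (inter-subject variability); rest
#' runs sampled from each subject's covariance; task runs sampled with a
#' sustained variance quench (`task_scale`) plus a peristimulus transient
#' dip, and stimulus onsets at inter-stimulus intervals uniform in
#' `isi_range`.
#'
#' @param n_subjects,n_runs,n_frames Study dimensions (defaults 17, 4, 194).
#' @param tr_seconds Repetition time (default 2.16 s).
#' @param isi_range Inter-stimulus interval range (default `c(17.3, 30.2)`).
#' @param task_scale Sustained task variance multiplier (default 0.9).
#' @param dip_depth Peristimulus transient dip depth (default 0.3).
#' @param wishart_df Degrees of freedom of the inter-subject Wishart
#'   (default 100; smaller = more heterogeneous subjects).
#' @param rank ROI covariance rank after nuisance projection (default 29).
#' @param seed RNG seed.
#' @return A list with `rest` and `task` ([fmri_dataset]s),
#'   `population_cov`, and `subject_covs`.
#' @export
surrogate_rest_task <- function(n_subjects = 17L, n_runs = 4L,
                                n_frames = 194L, tr_seconds = 2.16,
                                isi_range = c(17.3, 30.2),
                                task_scale = 0.9, dip_depth = 0.3,
                                wishart_df = 100L, rank = 29L, seed = 1L) {
  set.seed(seed)
  n_rois <- 33L
  # network block structure: five cortical networks + 3 subcortical ROIs
  blocks <- rep(seq_len(6L), times = c(7L, 7L, 6L, 5L, 5L, 3L))
  R <- outer(blocks, blocks, function(a, b)
    ifelse(a == b & a < 6L, 0.45, 0.08))
  diag(R) <- 1
  sds <- exp(rnorm(n_rois, 0, 0.25))
  Sigma <- R * tcrossprod(sds)
  # project out (n_rois - rank) directions: nuisance-regressor removal
  U <- matrix(rnorm(n_rois * (n_rois - rank)), n_rois)
  Q <- diag(n_rois) - U %*% solve(crossprod(U), t(U))
  Sigma <- Q %*% Sigma %*% t(Q)
  Sigma <- (Sigma + t(Sigma)) / 2
  # Wishart sampling restricted to the rank-deficient support of Sigma
  e <- eigen(Sigma, symmetric = TRUE)
  r_eff <- sum(e$values > max(e$values) * 1e-10)
  L <- e$vectors[, seq_len(r_eff)] %*%
    diag(sqrt(e$values[seq_len(r_eff)]), r_eff)
  subject_covs <- lapply(seq_len(n_subjects), function(s) {
    X <- matrix(rnorm(wishart_df * r_eff), wishart_df, r_eff)
    S <- L %*% (crossprod(X) / wishart_df) %*% t(L)
    (S + t(S)) / 2
  })
  spec <- surrogate_fmri_spec(Sigma, n_frames, n_runs, n_subjects,
                              tr_seconds, isi_range, seed = seed + 1L)
  rest <- generate_surrogate_fmri(spec, "rest",
                                  subject_covariances = subject_covs)
  task <- generate_surrogate_fmri(spec, "task",
                                  subject_covariances = subject_covs,
                                  task_scale = task_scale,
                                  dip_depth = dip_depth)
  list(rest = rest, task = task, population_cov = Sigma,
       subject_covs = subject_covs)
}
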