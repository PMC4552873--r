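#' Per-subject differential entropy of ROI time series
#'
#' Concatenates each subject's runs and estimates the differential entropy
#' of the frames x ROIs matrix, either parametrically (Gaussian entropy on
#' the sample covariance with singular-value rank truncation,
#' [svd_entropy()]) or nonparametrically ([knn_entropy()]).
#'
#' @param data An [fmri_dataset].
#' @param method `"gaussian_svd"` or `"knn"`.
#' @param k_neighbors Neighbour order for the kNN estimator.
#' @return A data frame with `subject`, `H` (bits) and, for the parametric
#'   method, `k` (retained rank).
#' @export
subject_entropy <- function(data, method = c("gaussian_svd", "knn"),
                            k_neighbors = 1L) {
  stopifnot(inherits(data, "fmri_dataset"))
  method <- match.arg(method)
  if (data$n_runs < 2L) stop("subject entropy expects >= 2 runs; subject(s) ",
                             "have ", data$n_runs)
  out <- lapply(seq_len(data$n_subjects), function(s) {
    X <- concat_runs(data, s)
    if (method == "gaussian_svd") {
      e <- svd_entropy(X)
      data.frame(subject = s, H = e$H, k = e$k)
    } else {
      data.frame(subject = s, H = knn_entropy(X, k_neighbors), k = NA_integer_)
    }
  })
  do.call(rbind, out)
}

#' Paired test for an entropy difference between conditions
#'
#' Two-sided Wilcoxon signed-rank test on paired per-subject entropies,
#' using the exact null distribution (appropriate at n = 17). Degenerate
#' all-zero differences are reported as "no difference" (p = 1) rather
#' than an error.
#'
#' @param h_rest,h_task Paired numeric vectors of per-subject entropies.
#' @return A list with `statistic`, `p_value`, `median_difference` and
#'   `n`.
#' @export
entropy_difference_test <- function(h_rest, h_task) {
  stopifnot(length(h_rest) == length(h_task), length(h_rest) >= 6L)
  d <- h_rest - h_task
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p_value = 1,
                median_difference = 0, n = length(d)))
  }
  wt <- wilcox.test(h_rest, h_task, paired = TRUE, exact = TRUE,
                    correct = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_difference = median(d), n = length(d))
}

## Sliding-window entropies of one run: H of each window_frames x ROIs
## block, windows advanced by step_frames.
run_window_entropy <- function(run, window_frames, step_frames) {
  starts <- seq(1L, nrow(run) - window_frames + 1L, by = step_frames)
  vapply(starts, function(s)
    svd_entropy(run[s:(s + window_frames - 1L), , drop = FALSE])$H,
    numeric(1))
}

#' Peristimulus time-resolved entropy
#'
#' Computes the differential entropy in sliding windows of `window_frames`
#' frames shifted by `step_frames`, aligned to each stimulus onset of the
#' task runs and averaged over presentations, per subject; rest runs are
#' analysed over equivalent periods (the task onsets of the same-index run
#' mapped onto the paired rest run). Presentations whose full
#' `+/- span_s` peristimulus span crosses a run boundary are excluded.
#' Entropies are referenced to `H0`, the rest entropy averaged across all
#' sliding windows and subjects, and each peristimulus window gets a paired
#' t-test of task vs rest across subjects.
#'
#' @param data_rest,data_task Paired [fmri_dataset]s (same subjects, same
#'   run count).
#' @param window_frames Window length in frames (default 5).
#' @param step_frames Window step in frames (default 1).
#' @param span_s Peristimulus half-span in seconds (default 17.3).
#' @param bonferroni Apply a Bonferroni correction across windows
#'   (default `FALSE`: per-window uncorrected p-values).
#' @return A list of class `"entropy_timecourse"`: data frame `windows`
#'   with `t` (window-centre seconds from onset), `H_rest`, `H_task`
#'   (across-subject means, bits), `p_value`, plus `H0`, `n_subjects`, and
#'   the per-subject matrices `H_rest_subj`, `H_task_subj`.
#' @export
time_resolved_entropy <- function(data_rest, data_task, window_frames = 5L,
                                  step_frames = 1L, span_s = 17.3,
                                  bonferroni = FALSE) {
  stopifnot(inherits(data_rest, "fmri_dataset"),
            inherits(data_task, "fmri_dataset"),
            data_task$condition == "task",
            data_rest$n_subjects == data_task$n_subjects,
            data_rest$n_runs == data_task$n_runs)
  tr <- data_task$tr_seconds
  span_frames <- round(span_s / tr)
  offsets <- seq(-span_frames, span_frames, by = step_frames)
  half <- window_frames %/% 2L
  n_sub <- data_task$n_subjects
  n_frames <- data_task$n_frames
  H_task_subj <- matrix(NA_real_, n_sub, length(offsets))
  H_rest_subj <- matrix(NA_real_, n_sub, length(offsets))
  H0_subj <- numeric(n_sub)
  for (s in seq_len(n_sub)) {
    H0_subj[s] <- mean(vapply(data_rest$series[[s]], function(run)
      mean(run_window_entropy(run, window_frames, step_frames)),
      numeric(1)))
    acc_t <- matrix(0, 0, length(offsets))
    acc_r <- matrix(0, 0, length(offsets))
    for (r in seq_len(data_task$n_runs)) {
      run_t <- data_task$series[[s]][[r]]
      run_r <- data_rest$series[[s]][[r]]
      for (o in data_task$onsets[[s]][[r]]) {
        lo <- o - span_frames - half
        hi <- o + span_frames + half
        if (lo < 1L || hi > n_frames) next   # span crosses the run edge
        Ht <- vapply(offsets, function(c0)
          svd_entropy(run_t[(o + c0 - half):(o + c0 + half), ,
                            drop = FALSE])$H, numeric(1))
        Hr <- vapply(offsets, function(c0)
          svd_entropy(run_r[(o + c0 - half):(o + c0 + half), ,
                            drop = FALSE])$H, numeric(1))
        acc_t <- rbind(acc_t, Ht)
        acc_r <- rbind(acc_r, Hr)
      }
    }
    if (nrow(acc_t) == 0L) {
      stop("subject ", s, " has no presentation with a full peristimulus span")
    }
    H_task_subj[s, ] <- colMeans(acc_t)
    H_rest_subj[s, ] <- colMeans(acc_r)
  }
  H0 <- mean(H0_subj)
  p <- vapply(seq_along(offsets), function(k)
    t.test(H_task_subj[, k], H_rest_subj[, k], paired = TRUE)$p.value,
    numeric(1))
  if (bonferroni) p <- pmin(1, p * length(offsets))
  windows <- data.frame(t = offsets * tr,
                        H_rest = colMeans(H_rest_subj),
                        H_task = colMeans(H_task_subj),
                        p_value = p)
  structure(list(windows = windows, H0 = H0, n_subjects = n_sub,
                 H_rest_subj = H_rest_subj, H_task_subj = H_task_subj),
            class = "entropy_timecourse")
}

#' Rest-versus-task functional connectivity comparison
#'
#' Per subject and condition, the Pearson correlation matrix of the
#' concatenated runs; matrices are averaged across subjects per condition
#' and the element-wise difference of the upper triangles is returned.
#'
#' @param data_rest,data_task Paired [fmri_dataset]s.
#' @return A list with `diff` (upper-triangle FC differences,
#'   rest - task), `fc_rest`, `fc_task` (mean matrices), and `range`.
#' @export
fc_comparison <- function(data_rest, data_task) {
  mean_fc <- function(data) {
    mats <- lapply(seq_len(data$n_subjects), function(s) {
      X <- concat_runs(data, s)
      if (any(apply(X, 2L, sd) == 0)) {
        stop("constant ROI series: correlation undefined")
      }
      cor(X)
    })
    Reduce(`+`, mats) / length(mats)
  }
  fc_r <- mean_fc(data_rest)
  fc_t <- mean_fc(data_task)
  up <- upper.tri(fc_r)
  d <- fc_r[up] - fc_t[up]
  list(diff = d, fc_rest = fc_r, fc_task = fc_t, range = range(d))
}
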