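#' Construct an ROI fMRI dataset
#'
#' Container for preprocessed BOLD region-of-interest time series organised
#' as subjects x runs x frames x ROIs, with a condition tag and, for task
#' data, per-run stimulus-onset frame indices.
#'
#' @param series List over subjects; each element a list over runs; each run
#'   a numeric frames x ROIs matrix. All runs must share frame and ROI
#'   counts.
#' @param condition `"rest"` or `"task"`.
#' @param tr_seconds Repetition time in seconds (default 2.16).
#' @param roi_labels Optional ROI names.
#' @param onsets For task data, a list parallel to `series`: per subject a
#'   list of integer vectors of onset frame indices (strictly increasing
#'   within a run). Must be `NULL` for rest data.
#' @return An object of class `"fmri_dataset"`.
#' @export
fmri_dataset <- function(series, condition = c("rest", "task"),
                         tr_seconds = 2.16, roi_labels = NULL,
                         onsets = NULL) {
  condition <- match.arg(condition)
  if (!length(series)) stop("empty fMRI dataset")
  dims <- unique(do.call(rbind, lapply(series, function(subj)
    do.call(rbind, lapply(subj, dim)))))
  if (nrow(dims) != 1L) {
    stop("all runs must have identical frame and ROI counts")
  }
  n_frames <- dims[1L, 1L]
  n_rois <- dims[1L, 2L]
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI%02d", seq_len(n_rois))
  if (length(roi_labels) != n_rois) stop("wrong number of ROI labels")
  if (condition == "rest" && !is.null(onsets)) {
    stop("onsets are only meaningful for task data")
  }
  if (condition == "task") {
    if (is.null(onsets)) stop("task data require onsets")
    ok <- vapply(unlist(onsets, recursive = FALSE), function(o) {
      length(o) == 0L || (all(o >= 1L & o <= n_frames) && !is.unsorted(o, strictly = TRUE))
    }, logical(1))
    if (!all(ok)) stop("onsets must be strictly increasing frame indices")
  }
  structure(list(series = series, condition = condition,
                 tr_seconds = tr_seconds, roi_labels = roi_labels,
                 onsets = onsets,
                 n_subjects = length(series),
                 n_runs = length(series[[1L]]),
                 n_frames = n_frames, n_rois = n_rois),
            class = "fmri_dataset")
}

#' @export
print.fmri_dataset <- function(x, ...) {
  cat(sprintf(
    "fmri_dataset (%s): %d subjects x %d runs x %d frames x %d ROIs, TR %.2f s\n",
    x$condition, x$n_subjects, x$n_runs, x$n_frames, x$n_rois, x$tr_seconds))
  invisible(x)
}

#' Read ROI fMRI time series from an ASCII table
#'
#' Reads the plain-text dialect in which each row is one frame: the first
#' `n_rois` columns hold BOLD values, the next column the subject number,
#' and (task condition only) a final column holding 1 at stimulus-onset
#' frames and 0 elsewhere. Frames of a subject are split into consecutive
#' runs of `frames_per_run` rows in file order.
#'
#' @param path Path to the ASCII table.
#' @param condition `"rest"` or `"task"`.
#' @param n_rois Number of ROI columns (default 33).
#' @param frames_per_run Frames per run (default 194).
#' @param tr_seconds Repetition time in seconds.
#' @param roi_labels Optional ROI labels (or path to a label file).
#' @return An [fmri_dataset].
#' @export
read_fmri <- function(path, condition = c("rest", "task"), n_rois = 33L,
                      frames_per_run = 194L, tr_seconds = 2.16,
                      roi_labels = NULL) {
  condition <- match.arg(condition)
  if (!file.exists(path)) stop("fMRI file not found: ", path)
  tab <- tryCatch(as.matrix(read.table(path, header = FALSE)),
                  error = function(e) stop("cannot parse fMRI table: ",
                                           conditionMessage(e)))
  if (!nrow(tab)) stop("fMRI file is empty: ", path)
  want <- n_rois + if (condition == "task") 2L else 1L
  if (ncol(tab) != want) {
    stop("expected ", want, " columns for ", condition, " data, found ",
         ncol(tab))
  }
  if (length(roi_labels) == 1L && file.exists(roi_labels)) {
    roi_labels <- trimws(readLines(roi_labels, warn = FALSE))
    roi_labels <- roi_labels[nzchar(roi_labels)]
  }
  subj_col <- tab[, n_rois + 1L]
  subjects <- unique(subj_col)
  series <- list()
  onsets <- if (condition == "task") list() else NULL
  for (s in seq_along(subjects)) {
    idx <- which(subj_col == subjects[s])
    if (length(idx) %% frames_per_run != 0L) {
      stop("subject ", subjects[s], " has ", length(idx),
           " rows, not divisible by frames_per_run = ", frames_per_run)
    }
    n_runs <- length(idx) %/% frames_per_run
    runs <- vector("list", n_runs)
    run_onsets <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      rows <- idx[((r - 1L) * frames_per_run + 1L):(r * frames_per_run)]
      runs[[r]] <- unname(tab[rows, seq_len(n_rois), drop = FALSE])
      if (condition == "task") {
        run_onsets[[r]] <- which(tab[rows, n_rois + 2L] == 1)
      }
    }
    series[[s]] <- runs
    if (condition == "task") onsets[[s]] <- run_onsets
  }
  fmri_dataset(series, condition, tr_seconds, roi_labels, onsets)
}

#' Write an ROI fMRI dataset to an ASCII table
#'
#' Inverse of [read_fmri()]: one row per frame, ROI columns first, then the
#' subject number, then (task only) the stimulus-onset flag.
#'
#' @param data An [fmri_dataset].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fmri <- function(data, path) {
  stopifnot(inherits(data, "fmri_dataset"))
  rows <- list()
  for (s in seq_len(data$n_subjects)) {
    for (r in seq_len(data$n_runs)) {
      block <- cbind(data$series[[s]][[r]], s)
      if (data$condition == "task") {
        flag <- integer(data$n_frames)
        flag[data$onsets[[s]][[r]]] <- 1L
        block <- cbind(block, flag)
      }
      rows[[length(rows) + 1L]] <- block
    }
  }
  write.table(do.call(rbind, rows), path, sep = " ",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Concatenate the runs of one subject into a single frames x ROIs matrix
#'
#' @param data An [fmri_dataset].
#' @param subject Subject index.
#' @return A (frames * runs) x ROIs matrix.
#' @export
concat_runs <- function(data, subject) {
  stopifnot(inherits(data, "fmri_dataset"))
  do.call(rbind, data$series[[subject]])
}
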