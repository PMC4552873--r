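#' Construct a connectome object
#'
#' A connectome is an `N x N` matrix of nonnegative inter-regional coupling
#' strengths (dimensionless fiber densities) with region labels. Self
#' connections are not part of the model (each node's internal connectivity
#' is described by its local E-I dynamics), so the diagonal is forced to
#' zero.
#'
#' @param weights Square numeric matrix of nonnegative coupling strengths.
#' @param labels Optional character vector of region labels, one per row.
#'   Defaults to `R001 ... RNNN`.
#' @return An object of class `"connectome"`: a list with elements
#'   `weights` (matrix, zero diagonal), `labels` and `n`.
#' @export
connectome <- function(weights, labels = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("connectome weights must be a square matrix, got ",
         nrow(weights), " x ", ncol(weights))
  }
  if (nrow(weights) < 2L) stop("a connectome needs at least 2 regions")
  if (!is.numeric(weights) || anyNA(weights)) {
    stop("connectome weights must be numeric and non-missing")
  }
  if (any(weights < 0)) stop("connectome weights must be nonnegative")
  diag(weights) <- 0
  n <- nrow(weights)
  if (is.null(labels)) labels <- sprintf("R%03d", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("expected ", n, " labels, got ", length(labels))
  }
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels, n = n),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d regions, link density %.3f, mean weight %.4g\n",
              x$n, link_density(x), mean(x$weights)))
  invisible(x)
}

#' Read a structural connectivity matrix from an ASCII file
#'
#' Reads a whitespace-delimited square numeric matrix (the plain-text dialect
#' used for DSI-derived fiber-density matrices). The diagonal is forced to
#' zero after loading. Labels are read from a companion file (one label per
#' line) when given, otherwise synthesized.
#'
#' @param path Path to the whitespace-delimited matrix file.
#' @param labels_path Optional path to a label file, one region label per
#'   line, in matrix row order.
#' @return A [connectome] object.
#' @export
read_connectome <- function(path, labels_path = NULL) {
  if (!file.exists(path)) stop("connectome file not found: ", path)
  rows <- readLines(path, warn = FALSE)
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) == 0L) stop("connectome file is empty: ", path)
  parsed <- lapply(strsplit(trimws(rows), "[[:space:]]+"), as.numeric)
  ncols <- lengths(parsed)
  if (length(unique(ncols)) != 1L || unique(ncols) != length(parsed)) {
    stop("connectome file is not a square numeric matrix: ", path)
  }
  w <- do.call(rbind, parsed)
  if (anyNA(w)) stop("non-numeric entries in connectome file: ", path)
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- trimws(readLines(labels_path, warn = FALSE))
    labels <- labels[nzchar(labels)]
  }
  connectome(w, labels)
}

#' Write a connectome to a whitespace-delimited ASCII file
#'
#' Inverse of [read_connectome()]; the label file is written alongside when
#' `labels_path` is given.
#'
#' @param conn A [connectome] object.
#' @param path Output path for the matrix.
#' @param labels_path Optional output path for the labels.
#' @return Invisibly, `path`.
#' @export
write_connectome <- function(conn, path, labels_path = NULL) {
  stopifnot(inherits(conn, "connectome"))
  lines <- apply(conn$weights, 1L, function(r)
    paste(format(r, digits = 15, scientific = TRUE, trim = TRUE),
          collapse = " "))
  writeLines(lines, path)
  if (!is.null(labels_path)) writeLines(conn$labels, labels_path)
  invisible(path)
}

#' Link density of a connectome
#'
#' Fraction of off-diagonal entries that are strictly positive (the overall
#' attachment probability of the underlying graph). No weight thresholding
#' is applied: any positive weight counts as a link.
#'
#' @param conn A [connectome] object.
#' @return A fraction in `[0, 1]`.
#' @export
link_density <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  n <- conn$n
  w <- conn$weights
  diag(w) <- 0
  sum(w > 0) / (n * (n - 1))
}
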