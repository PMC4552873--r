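#' Write a tabular report as TSV
#'
#' All tabular outputs of the package go through this writer: a
#' tab-separated file whose first line holds the column names, in the order
#' of the input data frame. Numbers are written with enough digits to
#' round-trip through [read_report()].
#'
#' @param table A data frame (may have zero rows).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(table, path) {
  table <- as.data.frame(table)
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x)
    format(x, digits = 15, scientific = TRUE, trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a TSV report written by [write_report()]
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report not found: ", path)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
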