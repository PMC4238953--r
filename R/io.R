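#' Write a labelled numeric matrix to a tab-separated file
#'
#' Values are written with full `repr`-roundtrip precision (17 significant
#' digits), so [read_result_matrix()] recovers them bitwise. The header row
#' holds the column labels; the first column holds row labels.
#'
#' @param matrix A numeric matrix (or 2-d array).
#' @param row_labels,col_labels Character labels matching the dimensions.
#' @param path Output path.
#' @export
write_result_matrix <- function(matrix, row_labels, col_labels, path) {
  matrix <- as.matrix(matrix)
  if (length(row_labels) != nrow(matrix) ||
      length(col_labels) != ncol(matrix)) {
    stop_usage(sprintf(
      "label lengths (%d, %d) do not match matrix dimensions (%d x %d)",
      length(row_labels), length(col_labels), nrow(matrix), ncol(matrix)))
  }
  body <- apply(matrix, 1L, function(row) {
    paste(formatC(row, digits = 17, format = "g"), collapse = "\t")
  })
  lines <- c(paste(c("", as.character(col_labels)), collapse = "\t"),
             paste(as.character(row_labels), body, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(NULL)
}

#' Read a matrix written by [write_result_matrix()]
#'
#' @param path Path to the file.
#' @return A numeric matrix with dimnames taken from the file.
#' @export
read_result_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop_format(sprintf("empty matrix file '%s'", path))
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  col_labels <- header[-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  row_labels <- vapply(rows, `[[`, "", 1L)
  m <- matrix(NA_real_, nrow = length(rows), ncol = length(col_labels),
              dimnames = list(row_labels, col_labels))
  for (i in seq_along(rows)) {
    v <- as.numeric(rows[[i]][-1])
    if (length(v) != length(col_labels)) {
      stop_format(sprintf("%s line %d: ragged row", path, i + 1L))
    }
    m[i, ] <- v
  }
  m
}
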