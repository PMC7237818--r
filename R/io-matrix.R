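# Named-matrix readers and writers (TSV and MatrixMarket with id sidecars).

#' Read a named matrix
#'
#' Two formats are supported: a TSV with a header row and row ids in the first
#' column, and MatrixMarket (`mtx`) with two sidecar files carrying the row and
#' column ids (one id per line; defaults are `<path>.rows` / `<path>.cols`).
#' Write/read pairs round-trip values to better than 1e-12.
#'
#' @param path Path to the matrix file.
#' @param format `"tsv"` or `"mtx"`.
#' @param row_ids_path,col_ids_path Sidecar id files for `mtx`.
#' @return A dense numeric matrix with unique row and column names.
#' @export
read_matrix <- function(path, format = c("tsv", "mtx"),
                        row_ids_path = paste0(path, ".rows"),
                        col_ids_path = paste0(path, ".cols")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    row_ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- row_ids
  } else {
    if (!file.exists(row_ids_path)) stopf("missing row-id sidecar: %s", row_ids_path)
    if (!file.exists(col_ids_path)) stopf("missing col-id sidecar: %s", col_ids_path)
    m <- as.matrix(Matrix::readMM(path))
    row_ids <- readLines(row_ids_path)
    col_ids <- readLines(col_ids_path)
    if (nrow(m) != length(row_ids) || ncol(m) != length(col_ids))
      stopf("mtx dimensions (%d x %d) do not match sidecar ids (%d x %d)",
            nrow(m), ncol(m), length(row_ids), length(col_ids))
    dimnames(m) <- list(row_ids, col_ids)
  }
  check_named_matrix(m, path)
  m
}

#' Write a named matrix
#'
#' @param x A numeric matrix with row and column names.
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"`.
#' @param row_ids_path,col_ids_path Sidecar id files for `mtx`.
#' @export
write_matrix <- function(x, path, format = c("tsv", "mtx"),
                         row_ids_path = paste0(path, ".rows"),
                         col_ids_path = paste0(path, ".cols")) {
  format <- match.arg(format)
  check_named_matrix(x)
  if (format == "tsv") {
    header <- paste(c("id", colnames(x)), collapse = "\t")
    body <- vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], format(x[i, ], digits = 17, trim = TRUE, scientific = NA)),
            collapse = "\t")
    }, character(1))
    writeLines(c(header, body), path)
  } else {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(x), "generalMatrix"), "CsparseMatrix"), path)
    writeLines(rownames(x), row_ids_path)
    writeLines(colnames(x), col_ids_path)
  }
  invisible(path)
}
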