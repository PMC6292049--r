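# Count matrix I/O. Canonical on-disk layouts:
#   * TSV/CSV: header row of gene ids, first column of sample ids
#     (or the transpose, declared via `orientation`).
#   * MatrixMarket: .mtx file plus two sidecar id files (<path>.rownames,
#     <path>.colnames), one id per line.
# Writers mirror readers so matrices round-trip exactly.

#' Read a count matrix
#'
#' Loads a delimited or MatrixMarket count file into the canonical
#' samples-by-genes numeric matrix. Negative, missing, or non-numeric entries
#' are load errors that name the offending cell.
#'
#' @param path Input file. `.mtx` files need sidecar `<path>.rownames` and
#'   `<path>.colnames` id files.
#' @param format `"tsv"`, `"csv"`, or `"mtx"`; default guesses from the file
#'   extension.
#' @param orientation `"samples_in_rows"` (canonical) or `"genes_in_rows"`
#'   (the matrix is transposed after reading).
#'
#' @return Samples-by-genes numeric matrix with sample ids as rownames and
#'   gene ids as colnames.
#' @export
read_counts <- function(path,
                        format = c("auto", "tsv", "csv", "mtx"),
                        orientation = c("samples_in_rows", "genes_in_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop("Cannot guess format from extension of ", path,
                          call. = FALSE))
  }

  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    rn_file <- paste0(path, ".rownames")
    cn_file <- paste0(path, ".colnames")
    if (!file.exists(rn_file) || !file.exists(cn_file)) {
      stop("MTX sidecar id files missing: expected ", rn_file, " and ",
           cn_file, call. = FALSE)
    }
    rownames(m) <- readLines(rn_file)
    colnames(m) <- readLines(cn_file)
  } else {
    delim <- if (format == "tsv") "\t" else ","
    df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
      readr::col_character(), .default = readr::col_double()))
    ids <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
  }

  bad <- which(is.na(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "Invalid (negative or non-numeric) entry at row '%s', column '%s' in %s.",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], path), call. = FALSE)
  }
  if (orientation == "genes_in_rows") m <- t(m)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("Sample and gene ids must be unique in ", path, call. = FALSE)
  }
  as_count_matrix(m)
}

#' Write a count matrix
#'
#' Mirror of [read_counts()]: writes the canonical samples-by-genes matrix as
#' TSV/CSV (ids in the first column and header) or MatrixMarket with sidecar
#' id files.
#'
#' @param x Samples-by-genes numeric matrix.
#' @param path Output file.
#' @param format `"tsv"`, `"csv"`, or `"mtx"`; default guesses from the
#'   extension.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  x <- as_count_matrix(x)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop("Cannot guess format from extension of ", path,
                          call. = FALSE))
  }
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), path)
    writeLines(rownames(x), paste0(path, ".rownames"))
    writeLines(colnames(x), paste0(path, ".colnames"))
  } else {
    df <- tibble::as_tibble(x, rownames = "sample_id")
    readr::write_delim(df, path, delim = if (format == "tsv") "\t" else ",")
  }
  invisible(path)
}

#' Read a label vector
#'
#' Reads cluster or group labels from a one-column plain-text file or a
#' two-column CSV (`sample_id`, label).
#'
#' @param path Input file.
#' @return Integer-coded label vector (named when sample ids are present).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  if (grepl(",", first, fixed = TRUE)) {
    df <- readr::read_csv(path, col_types = readr::cols())
    stats::setNames(as.integer(as.factor(df[[2]])), as.character(df[[1]]))
  } else {
    v <- readLines(path)
    v <- v[nzchar(v)]
    if (tolower(v[1]) %in% c("label", "cluster")) v <- v[-1]
    as.integer(as.factor(v))
  }
}
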