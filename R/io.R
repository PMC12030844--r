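#' Read a numeric data matrix from delimited text
#'
#' Reads a CSV or TSV file with one instance per row and no header.  Lines
#' starting with `#` are skipped.  Ragged rows and non-numeric cells are
#' rejected with the offending line number.
#'
#' @param path file path.
#' @param format `"auto"` (by extension; `.tsv`/`.tab` are tab-delimited,
#'   anything else comma), `"csv"` or `"tsv"`.
#' @return A numeric matrix.
#' @export
read_matrix <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "tsv"
              else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  fields <- utils::count.fields(path, sep = sep, comment.char = "#",
                                quote = "")
  fields <- fields[!is.na(fields)]          # NA = line inside a quote; none
  if (length(fields) == 0L) stop("empty matrix file: ", path, call. = FALSE)
  if (length(unique(fields)) > 1L) {
    bad <- which(fields != fields[1L])[1L]
    # report the physical line number, counting skipped comment lines
    lines <- readLines(path)
    data_lines <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, data_lines[bad], fields[bad], fields[1L]),
         call. = FALSE)
  }
  df <- utils::read.table(path, sep = sep, comment.char = "#", header = FALSE,
                          colClasses = "character", quote = "")
  M <- suppressWarnings(matrix(as.numeric(as.matrix(df)), nrow(df), ncol(df)))
  if (anyNA(M)) {
    bad_row <- which(rowSums(is.na(M)) > 0)[1L]
    stop(sprintf("non-numeric cell in %s at data row %d", path, bad_row),
         call. = FALSE)
  }
  M
}

#' Write a numeric matrix as delimited text
#'
#' Inverse of [read_matrix()]: no header, full double precision, so a
#' write/read round trip reproduces the matrix to better than 1e-12 relative.
#'
#' @param X numeric matrix.
#' @param path file path.
#' @param format `"csv"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(X, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  X <- as_numeric_matrix(X)
  sep <- if (format == "tsv") "\t" else ","
  lines <- apply(X, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

read_label_vector <- function(path) {
  M <- read_matrix(path, format = "csv")
  if (ncol(M) != 1L) stop("label file must have a single column", call. = FALSE)
  as.integer(M[, 1L])
}
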