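#' Read and write influence matrices as CSV
#'
#' One canonical dialect: comma-separated UTF-8, factor codes as the first
#' row and first column, identical ordered code sets on both axes. Integer
#' matrices round-trip losslessly; real matrices are written at a fixed
#' number of decimals.
#'
#' @param path file path.
#' @param integer if `TRUE`, require and return integer entries.
#' @return `read_matrix_csv()`: a matrix with factor-code dimnames.
#' @export
read_matrix_csv <- function(path, integer = FALSE) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(raw) < 2 || ncol(raw) < 2)
    stop("matrix CSV needs a header row/column plus data: ", path,
         call. = FALSE)
  col_codes <- as.character(raw[1, -1])
  row_codes <- as.character(raw[-1, 1])
  if (anyDuplicated(col_codes) || anyDuplicated(row_codes))
    stop("duplicated factor code in CSV header: ",
         paste(unique(c(col_codes[duplicated(col_codes)],
                        row_codes[duplicated(row_codes)])), collapse = ", "),
         call. = FALSE)
  if (!identical(col_codes, row_codes))
    stop("row and column factor codes differ in ", path, call. = FALSE)
  body <- as.matrix(raw[-1, -1, drop = FALSE])
  vals <- suppressWarnings(as.numeric(body))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = FALSE)[1]
    ij <- arrayInd(bad, dim(body))
    stop(sprintf("non-numeric cell at row %s, column %s in %s",
                 row_codes[ij[1]], col_codes[ij[2]], path), call. = FALSE)
  }
  m <- matrix(vals, nrow = length(row_codes),
              dimnames = list(row_codes, col_codes))
  if (integer) {
    if (any(m != round(m)))
      stop("expected integer matrix in ", path, call. = FALSE)
    storage.mode(m) <- "integer"
  }
  m
}

#' @rdname read_matrix_csv
#' @param m matrix with factor-code dimnames.
#' @param precision decimal places for real matrices; `NULL` writes values
#'   unrounded (and integers as integers).
#' @export
write_matrix_csv <- function(m, path, precision = NULL) {
  check_system_matrix(m, what = "matrix")
  body <- if (is.null(precision)) m else round(m, precision)
  fmt <- if (is.null(precision)) format(body, trim = TRUE, scientific = FALSE)
         else formatC(body, format = "f", digits = precision)
  fmt <- matrix(as.character(fmt), nrow = nrow(m))
  lines <- c(paste(c("", colnames(m)), collapse = ","),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], fmt[i, ]), collapse = ","), ""))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a factor label table
#'
#' CSV with columns `code`, `name` and optionally `dimension`,
#' `description`.
#'
#' @param path file path.
#' @param codes optional expected factor codes (order enforced).
#' @return A [factor_system] carrying the labels.
#' @export
read_factor_labels <- function(path, codes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!all(c("code", "name") %in% names(df)))
    stop("label table needs columns 'code' and 'name': ", path,
         call. = FALSE)
  factor_system(if (is.null(codes)) df$code else codes, df)
}
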