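#' Define the ordered factor set of an influence system
#'
#' A factor system fixes the ordered set of factor codes that indexes every
#' matrix in the DEMATEL-TAISM pipeline, optionally together with a label
#' table (name, dimension, description per code).
#'
#' @param codes character vector of unique, non-empty factor codes
#'   (at least two).
#' @param labels optional `data.frame` with columns `code`, `name`, and
#'   optionally `dimension` and `description`; every factor code must appear
#'   exactly once.
#' @return An object of class `factor_system` with elements `codes` and
#'   `labels`.
#' @examples
#' fs <- factor_system(c("X1", "X2", "X3"))
#' n_factors(fs)
#' @export
factor_system <- function(codes, labels = NULL) {
  codes <- as.character(codes)
  if (length(codes) < 2)
    stop("a factor system needs at least two factors", call. = FALSE)
  if (anyDuplicated(codes))
    stop("factor codes must be unique; duplicated: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(codes)) || anyNA(codes))
    stop("factor codes must be non-empty strings", call. = FALSE)
  if (!is.null(labels)) {
    if (!is.data.frame(labels) || !all(c("code", "name") %in% names(labels)))
      stop("labels must be a data.frame with at least columns 'code' and 'name'",
           call. = FALSE)
    if (!setequal(labels$code, codes) || anyDuplicated(labels$code))
      stop("labels must contain each factor code exactly once", call. = FALSE)
    labels <- labels[match(codes, labels$code), , drop = FALSE]
    rownames(labels) <- NULL
  }
  structure(list(codes = codes, labels = labels), class = "factor_system")
}

#' Number of factors in a system
#'
#' @param system a `factor_system`.
#' @return Integer count of factors.
#' @export
n_factors <- function(system) {
  stopifnot(inherits(system, "factor_system"))
  length(system$codes)
}

#' @export
print.factor_system <- function(x, ...) {
  cat("Factor system with", length(x$codes), "factors:\n ",
      paste(x$codes, collapse = ", "), "\n")
  if (!is.null(x$labels)) {
    nm <- paste0(x$labels$code, " = ", x$labels$name)
    cat(strwrap(paste(nm, collapse = "; "), indent = 2, exdent = 2), sep = "\n")
  }
  invisible(x)
}

# internal: check a matrix is square, numeric and indexed by the system order
check_system_matrix <- function(m, system = NULL, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    stop(what, " must be a square numeric matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must carry factor codes as dimnames", call. = FALSE)
  if (!identical(rownames(m), colnames(m)))
    stop(what, " row and column codes differ", call. = FALSE)
  if (!is.null(system) && !identical(rownames(m), system$codes))
    stop(what, " is not indexed by the factor system order", call. = FALSE)
  invisible(m)
}

# internal: system implied by a matrix's dimnames
system_of <- function(m) factor_system(rownames(m))
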