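#' Read a connectivity matrix from a delimited text file
#'
#' Reads one subject's square connectivity matrix from plain text. The
#' delimiter (comma or whitespace) is auto-detected unless given. An optional
#' single header line may carry node labels. The matrix must be square,
#' nonnegative and symmetric up to a relative tolerance of `1e-8`; matrices
#' within tolerance are symmetrized by averaging, larger asymmetries are an
#' error naming the worst cell.
#'
#' @param path Path to a text file holding one numeric square matrix.
#' @param delimiter Optional single-character delimiter; `NULL` auto-detects
#'   comma versus whitespace from the first data line.
#' @return A `connectivity_matrix`: a numeric p x p matrix with attributes
#'   `node_labels` (or `NULL`) and class `c("connectivity_matrix", "matrix")`.
#' @seealso [normalize_by_max()], [stack_cohort()]
#' @export
read_connectivity_matrix <- function(path, delimiter = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty matrix file: ", path)
  if (is.null(delimiter)) {
    delimiter <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else ""
  }
  split1 <- strsplit(trimws(lines[[1]]),
                     if (delimiter == "") "[[:space:]]+" else delimiter)[[1]]
  labels <- NULL
  if (any(is.na(suppressWarnings(as.numeric(split1))))) {
    labels <- trimws(split1)
    lines <- lines[-1L]
  }
  rows <- lapply(lines, function(l) {
    v <- strsplit(trimws(l),
                  if (delimiter == "") "[[:space:]]+" else delimiter)[[1]]
    v <- v[nzchar(v)]
    as.numeric(v)
  })
  ncols <- vapply(rows, length, integer(1))
  if (length(unique(ncols)) != 1L || any(is.na(unlist(rows)))) {
    stop("malformed matrix file (ragged rows or non-numeric entries): ", path)
  }
  m <- do.call(rbind, rows)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix in %s is not square (%d x %d)", path, nrow(m), ncol(m)))
  }
  if (!is.null(labels) && length(labels) != ncol(m)) {
    stop("header label count does not match matrix dimension in ", path)
  }
  as_connectivity_matrix(m, node_labels = labels)
}

#' Validate and construct a connectivity matrix
#'
#' Checks squareness, nonnegativity, a zero diagonal and symmetry (relative
#' tolerance `1e-8` on the maximum absolute entry, then symmetrized by
#' averaging) and attaches the `connectivity_matrix` class.
#'
#' @param m Numeric square matrix.
#' @param node_labels Optional character vector of node names.
#' @return A `connectivity_matrix`.
#' @export
as_connectivity_matrix <- function(m, node_labels = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("connectivity matrix must be square")
  if (nrow(m) < 2L) stop("connectivity matrix needs at least 2 nodes")
  if (any(!is.finite(m))) stop("connectivity matrix has non-finite entries")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative entry at (%d, %d): connectivity weights must be >= 0",
                 bad[1L], bad[2L]))
  }
  asym <- abs(m - t(m))
  tol <- 1e-8 * max(max(m), .Machine$double.eps)
  if (max(asym) > tol) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "matrix asymmetry %.3g at cell (%d, %d) exceeds tolerance %.3g",
      max(asym), bad[1L], bad[2L], tol))
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (!is.null(node_labels)) {
    dimnames(m) <- list(node_labels, node_labels)
  }
  structure(m, class = c("connectivity_matrix", "matrix", "array"))
}

#' Write a connectivity matrix to a delimited text file
#'
#' @param m Square numeric matrix.
#' @param path Output path.
#' @param delimiter Field delimiter (default single space).
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(m, path, delimiter = " ") {
  utils::write.table(format(unclass(m), digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, sep = delimiter, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Scale a connectivity matrix by its maximum entry
#'
#' Divides every entry by the matrix's maximum, so the strongest connection
#' becomes 1. Subjects scanned or tracked under different conditions yield
#' fiber counts on different scales; per-subject max-normalization puts all
#' matrices on a common [0, 1] scale before metrics or feature extraction.
#' An all-zero matrix passes through unchanged with a warning.
#'
#' @param m Square nonnegative matrix.
#' @return Matrix of the same shape with maximum entry 1 (or all zeros).
#' @export
normalize_by_max <- function(m) {
  mx <- max(m)
  if (mx == 0) {
    warning("all-zero connectivity matrix: returning it unchanged")
    return(m)
  }
  m / mx
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Stacks entries (i, j) with i < j in row-major order (i ascending, then j
#' ascending within i), giving p(p-1)/2 features for a p-node network.
#'
#' @param m Symmetric square matrix.
#' @return Numeric vector of length `p*(p-1)/2`.
#' @seealso [symmetric_from_vector()] for the inverse.
#' @export
vectorize_upper_triangle <- function(m) {
  p <- nrow(m)
  if (p != ncol(m)) stop("matrix must be square")
  # t(m)[lower.tri] walks the upper triangle row-by-row
  t(m)[lower.tri(m)]
}

#' Rebuild a symmetric zero-diagonal matrix from its upper-triangle vector
#'
#' Inverse of [vectorize_upper_triangle()]: expects the row-major i < j
#' ordering and returns the symmetric p x p matrix with zero diagonal.
#'
#' @param v Numeric vector of length `p*(p-1)/2`.
#' @param p Node count.
#' @return p x p symmetric matrix.
#' @export
symmetric_from_vector <- function(v, p) {
  if (length(v) != p * (p - 1) / 2) {
    stop(sprintf("vector length %d does not match p = %d (need %d)",
                 length(v), p, p * (p - 1) / 2))
  }
  m <- matrix(0, p, p)
  m[lower.tri(m)] <- v
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}
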