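#' Mode-k unfolding of a tensor
#'
#' Rearranges an N-way array into a matrix whose rows index mode `k` and whose
#' columns enumerate the remaining modes in cyclic order k+1, ..., N, 1, ...,
#' k-1 with the first of those varying fastest. Any fixed convention gives the
#' same singular values; this one is declared so folds invert unfolds.
#'
#' @param x N-way numeric array.
#' @param k Mode, in 1..N.
#' @return Matrix of size `dim(x)[k]` x `prod(dim(x)[-k])`.
#' @export
unfold <- function(x, k) {
  d <- dim(x)
  N <- length(d)
  if (k < 1 || k > N) stop(sprintf("mode %d out of range 1..%d", k, N))
  perm <- ((seq_len(N) + k - 2) %% N) + 1  # k, k+1, ..., N, 1, ..., k-1
  matrix(aperm(x, perm), nrow = d[k])
}

#' Fold a mode-k unfolding back into a tensor
#'
#' Inverse of [unfold()] for the declared cyclic column convention.
#'
#' @param m Matrix produced by (or shaped like) a mode-`k` unfolding.
#' @param k Mode along which `m` was unfolded.
#' @param dims Target tensor dimensions.
#' @return Array with `dim = dims`.
#' @export
fold <- function(m, k, dims) {
  N <- length(dims)
  perm <- ((seq_len(N) + k - 2) %% N) + 1
  inv <- order(perm)
  aperm(array(m, dim = dims[perm]), inv)
}

#' Mode-k product of a tensor with a matrix
#'
#' Multiplies `u` into mode `k`: the result's mode-`k` unfolding is
#' `u %*% unfold(x, k)`.
#'
#' @param x N-way array.
#' @param u Matrix with `ncol(u) == dim(x)[k]`.
#' @param k Mode.
#' @return Array with mode `k` resized to `nrow(u)`.
#' @export
ttm <- function(x, u, k) {
  d <- dim(x)
  if (ncol(u) != d[k]) {
    stop(sprintf("mode-%d size %d does not match ncol(u) = %d", k, d[k], ncol(u)))
  }
  d2 <- d
  d2[k] <- nrow(u)
  fold(u %*% unfold(x, k), k, d2)
}

# Fix each column's sign so its largest-magnitude entry is positive
# (first such entry on ties); makes singular vectors reproducible.
fix_signs <- function(u) {
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  u
}

#' Higher-order singular value decomposition
#'
#' Decomposes an N-way tensor as the core multiplied by one orthogonal factor
#' per mode: `x = core x_1 U1 x_2 U2 ... x_N UN`. Each factor U(k) is the full
#' left singular matrix of the mode-k unfolding (sign-fixed so the
#' largest-magnitude entry of every column is positive); the k-mode singular
#' values are the unfolding's singular values, equal to the Frobenius norms of
#' the core's mode-k subtensors, which are mutually orthogonal and ordered by
#' decreasing norm.
#'
#' @param x N-way numeric array with finite entries.
#' @return An object of class `hosvd`: list with `factors` (list of N square
#'   orthogonal matrices), `mode_singular_values` (list of N descending
#'   vectors, length `dim(x)[k]`), `core` (array, same size as `x`) and
#'   `dims`.
#' @examples
#' x <- array(rnorm(24), dim = c(2, 3, 4))
#' h <- hosvd(x)
#' max(abs(reconstruct(h) - x))  # ~ 1e-15
#' @export
hosvd <- function(x) {
  if (any(!is.finite(x))) stop("tensor has non-finite entries")
  d <- dim(x)
  N <- length(d)
  factors <- vector("list", N)
  msv <- vector("list", N)
  for (k in seq_len(N)) {
    unf <- unfold(x, k)
    sv <- svd(unf, nu = d[k], nv = 0)
    factors[[k]] <- fix_signs(sv$u)
    msv[[k]] <- c(sv$d, rep(0, d[k] - length(sv$d)))[seq_len(d[k])]
  }
  core <- x
  for (k in seq_len(N)) core <- ttm(core, t(factors[[k]]), k)
  structure(list(factors = factors, mode_singular_values = msv,
                 core = core, dims = d),
            class = "hosvd")
}

#' @export
print.hosvd <- function(x, ...) {
  cat(sprintf("HO-SVD of a %s tensor\n", paste(x$dims, collapse = " x ")))
  for (k in seq_along(x$dims)) {
    sv <- x$mode_singular_values[[k]]
    cat(sprintf("  mode %d: %d singular values, top 3: %s\n", k, length(sv),
                paste(signif(utils::head(sv, 3), 4), collapse = ", ")))
  }
  invisible(x)
}

#' Reconstruct the tensor from an HO-SVD
#'
#' @param h An `hosvd` object.
#' @return Array equal to the decomposed tensor (to numerical precision).
#' @export
reconstruct <- function(h) {
  x <- h$core
  for (k in seq_along(h$dims)) x <- ttm(x, h$factors[[k]], k)
  x
}

#' Truncate an HO-SVD to reduce feature modes
#'
#' Keeps the leading `ranks[k]` components per mode. The sample mode (mode 1)
#' is kept full: the reduced tensor is the truncated core multiplied back
#' along mode 1 only, giving each subject an R2 x ... x RN reduced slice in
#' the truncated mode-2..N bases.
#'
#' @param x N-way array (mode 1 = samples) or an `hosvd` object.
#' @param ranks Integer vector of length N; `ranks[1]` must equal
#'   `dim(x)[1]` (it is forced to, with a warning if it differs).
#' @return List with `reduced` (n x R2 x ... x RN array), `factors`
#'   (truncated factor matrices) and `core` (truncated core).
#' @export
reduce_tensor <- function(x, ranks) {
  h <- if (inherits(x, "hosvd")) x else hosvd(x)
  d <- h$dims
  N <- length(d)
  if (length(ranks) != N) stop("ranks must have one entry per mode")
  if (any(ranks < 1) || any(ranks > d)) {
    stop(sprintf("ranks (%s) must lie in 1..mode size (%s)",
                 paste(ranks, collapse = ","), paste(d, collapse = ",")))
  }
  if (ranks[1] != d[1]) {
    warning("sample mode is never truncated; forcing ranks[1] = n")
    ranks[1] <- d[1]
  }
  trunc_factors <- lapply(seq_len(N), function(k) {
    h$factors[[k]][, seq_len(ranks[k]), drop = FALSE]
  })
  core <- h$core
  idx <- lapply(ranks, seq_len)
  core <- do.call(`[`, c(list(core), idx, list(drop = FALSE)))
  reduced <- ttm(core, trunc_factors[[1]], 1)
  list(reduced = reduced, factors = trunc_factors, core = core)
}

#' Raw upper-triangle features of a cohort
#'
#' Row i stacks the upper triangle (row-major, i < j) of subject i's slice,
#' giving p(p-1)/2 features per subject.
#'
#' @param cohort A `cohort_tensor`.
#' @return A `feature_matrix`: n x p(p-1)/2 matrix with attribute
#'   `method = "raw"` and subject ids as row names.
#' @export
extract_raw <- function(cohort) {
  d <- dim(cohort$data)
  n <- d[1]; p <- d[2]
  upper_rowmajor <- which(t(upper.tri(matrix(0, p, p))))  # (i,j), i<j, row-major
  flat <- matrix(cohort$data, nrow = n)   # columns are (row, col) col-major
  # column of flat for slice element (a, b) is (b-1)p + a; transpose index set
  tr <- t(matrix(seq_len(p * p), p, p))
  cols <- tr[upper_rowmajor]
  feats <- flat[, cols, drop = FALSE]
  feature_matrix(feats, cohort, "raw")
}

#' SVD/PCA features of a cohort
#'
#' Column-centers the raw feature matrix and projects it on its top-k right
#' singular directions (principal components); scores are the new features.
#' Fit on the full cohort, as the classification protocol evaluates features
#' constructed before any train/test split.
#'
#' @param cohort A `cohort_tensor`.
#' @param k Number of components (default 15).
#' @return A `feature_matrix` (n x k), `method = "svd"`.
#' @export
extract_svd <- function(cohort, k = 15L) {
  raw <- extract_raw(cohort)
  n <- nrow(raw); m <- ncol(raw)
  if (k < 1 || k > min(n, m)) {
    stop(sprintf("k = %d out of range 1..%d", k, min(n, m)))
  }
  xc <- scale(unclass(raw), center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = 0, nv = k)
  scores <- xc %*% fix_signs(sv$v)
  feature_matrix(scores, NULL, "svd", ids = rownames(raw))
}

#' HO-SVD features of a cohort
#'
#' Truncates the cohort tensor to n x k x k (sample mode kept full) and stacks
#' each subject's reduced k x k slice row-major into a k^2-long feature
#' vector. No column centering is applied before the decomposition
#' (`center = TRUE` reproduces the SVD baseline's centering on each edge).
#'
#' @param cohort A `cohort_tensor`.
#' @param k Ranks kept in both node modes (default 15).
#' @param center Center each edge across subjects before decomposing
#'   (default `FALSE`).
#' @return A `feature_matrix` (n x k^2), `method = "hosvd"`.
#' @export
extract_hosvd <- function(cohort, k = 15L, center = FALSE) {
  d <- dim(cohort$data)
  n <- d[1]; p <- d[2]
  if (k < 1 || k > p) stop(sprintf("k = %d out of range 1..%d", k, p))
  x <- cohort$data
  if (center) {
    mu <- apply(x, c(2, 3), mean)
    x <- x - aperm(array(mu, dim = c(p, p, n)), c(3, 1, 2))
  }
  red <- reduce_tensor(x, c(n, k, k))$reduced
  feats <- matrix(0, n, k * k)
  for (i in seq_len(n)) feats[i, ] <- as.vector(t(red[i, , ]))  # row-major
  feature_matrix(feats, cohort, "hosvd")
}

feature_matrix <- function(values, cohort, method, ids = NULL) {
  values <- as.matrix(values)
  if (!is.null(cohort)) ids <- cohort$phenotypes$subject_id
  rownames(values) <- ids
  colnames(values) <- NULL
  structure(values, method = method,
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix (%s): %d subjects x %d features\n",
              attr(x, "method"), nrow(x), ncol(x)))
  invisible(x)
}
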