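#' Build the age/sex covariate design matrix
#'
#' Columns: intercept, age in years, sex indicator (M = 1, F = 0). The coding
#' of sex cannot change residuals; only the column space matters.
#'
#' @param phenotypes Phenotype data frame (see [stack_cohort()]).
#' @return n x 3 numeric matrix with columns `intercept`, `age`, `sex`.
#' @export
covariate_design <- function(phenotypes) {
  phenotypes <- validate_phenotypes(phenotypes)
  n <- nrow(phenotypes)
  if (n < 4L) stop("need at least 4 subjects to fit an age/sex model")
  cbind(intercept = rep(1, n),
        age = phenotypes$age,
        sex = as.numeric(phenotypes$sex == "M"))
}

#' Remove covariate effects from a response by least-squares residualization
#'
#' Fits y on the design by ordinary least squares (Gaussian linear model with
#' identity link) and returns the residuals y - X b. A rank-deficient design
#' (all ages equal, or one sex absent) is handled by the pseudoinverse with a
#' warning; residuals remain well-defined.
#'
#' @param y Numeric response vector, or a matrix whose columns are
#'   residualized independently.
#' @param design Design matrix from [covariate_design()].
#' @return Residuals with the shape of `y`.
#' @export
residualize <- function(y, design) {
  ym <- as.matrix(y)
  if (nrow(ym) != nrow(design)) {
    stop(sprintf("response has %d rows but design has %d",
                 nrow(ym), nrow(design)))
  }
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    warning("rank-deficient covariate design; using pseudoinverse fit")
    sv <- svd(design)
    pos <- sv$d > max(dim(design)) * .Machine$double.eps * sv$d[1]
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% ym) / sv$d[pos])
    res <- ym - design %*% beta
  } else {
    res <- qr.resid(qrX, ym)
  }
  if (is.matrix(y)) res else drop(res)
}

#' Remove age and sex effects from every edge of a cohort
#'
#' For each unordered node pair (i < j) the n-vector of edge weights across
#' subjects is residualized against the age/sex design and written back
#' symmetrically; diagonals stay zero. The result holds signed residual
#' networks, the input to element-wise group tests and feature extraction.
#'
#' @param cohort A `cohort_tensor`.
#' @return A `cohort_tensor` of adjusted (possibly negative) slices.
#' @export
adjust_cohort <- function(cohort) {
  d <- dim(cohort$data)
  n <- d[1]; p <- d[2]
  design <- covariate_design(cohort$phenotypes)
  edges <- matrix(cohort$data, nrow = n)  # n x p^2, edge (j,k) at column (k-1)p+j
  upper <- which(upper.tri(matrix(0, p, p)))
  lower <- which(lower.tri(matrix(0, p, p)))
  res <- residualize(edges[, upper, drop = FALSE], design)
  adjusted <- matrix(0, n, p * p)
  adjusted[, upper] <- res
  # mirror: lower-tri linear index of (j,i) given upper (i,j)
  tr <- matrix(seq_len(p * p), p, p)
  adjusted[, lower] <- adjusted[, t(tr)[lower]]
  out <- cohort
  out$data <- array(adjusted, dim = d)
  out
}

#' Remove age and sex effects from a table of network measures
#'
#' Column-wise residualization of a subjects x measures matrix against the
#' age/sex design; see [residualize()].
#'
#' @param metric_table n x m numeric matrix (rows = subjects).
#' @param design Design matrix from [covariate_design()].
#' @return Residual matrix of the same shape.
#' @export
adjust_metrics <- function(metric_table, design) {
  res <- residualize(as.matrix(metric_table), design)
  dimnames(res) <- dimnames(as.matrix(metric_table))
  res
}
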