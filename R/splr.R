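# stable log(1 + exp(z))
softplus <- function(z) {
  out <- z
  small <- z < 35
  out[small] <- log1p(exp(z[small]))
  out
}

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -700), 700)))

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

splr_objective <- function(x, y, w, c0, lambda) {
  eta <- drop(x %*% w) + c0
  mean(softplus(-y * eta)) + lambda * sum(abs(w))
}

splr_grad <- function(x, y, w, c0) {
  eta <- drop(x %*% w) + c0
  s <- sigmoid(-y * eta)          # d/d eta of softplus(-y eta) = -y * s
  gy <- -y * s / length(y)
  list(gw = drop(crossprod(x, gy)), gc = sum(gy), loss = mean(softplus(-y * eta)))
}

#' Average logistic loss
#'
#' `(1/n) sum log(1 + exp(-y_i (x_i' w + c)))` with labels in {-1, +1},
#' evaluated with softplus stabilization.
#'
#' @param x n x m feature matrix.
#' @param y Numeric labels in `{-1, 1}`.
#' @param w Coefficient vector (length m).
#' @param c0 Intercept.
#' @return The average loss (scalar).
#' @export
logistic_loss <- function(x, y, w, c0) {
  x <- as.matrix(x)
  if (length(y) == 0) stop("no samples")
  check_labels(y)
  mean(softplus(-y * (drop(x %*% w) + c0)))
}

check_labels <- function(y) {
  if (!all(y %in% c(-1, 1))) stop("labels must be coded -1 / +1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  invisible(y)
}

intercept_only_fit <- function(y) {
  # minimizer of mean softplus(-y c): c = log(n+ / n-)
  log(sum(y == 1) / sum(y == -1))
}

#' Smallest penalty that zeroes all coefficients
#'
#' At the optimal intercept-only model (c* = log(n+/n-)), the KKT conditions
#' give w = 0 as the solution whenever lambda >= max_j |dL/dw_j|; this
#' function returns that threshold.
#'
#' @param x n x m feature matrix.
#' @param y Labels in `{-1, 1}`.
#' @return lambda_max (scalar).
#' @export
lambda_max <- function(x, y) {
  x <- as.matrix(x)
  check_labels(y)
  c0 <- intercept_only_fit(y)
  max(abs(splr_grad(x, y, rep(0, ncol(x)), c0)$gw))
}

#' Logarithmic penalty grid for the lasso path
#'
#' `n_values` penalties, log-spaced and strictly descending from
#' [lambda_max()] down to `ratio * lambda_max`.
#'
#' @param x n x m feature matrix.
#' @param y Labels in `{-1, 1}`.
#' @param n_values Grid size (>= 2, default 20).
#' @param ratio Smallest/largest penalty ratio (default 1e-3).
#' @return Descending numeric vector of length `n_values`.
#' @export
lambda_path <- function(x, y, n_values = 20L, ratio = 1e-3) {
  if (n_values < 2L) stop("need at least 2 grid values")
  lmax <- lambda_max(x, y)
  exp(seq(log(lmax), log(ratio * lmax), length.out = n_values))
}

#' Fit L1-penalized logistic regression by accelerated proximal gradient
#'
#' Minimizes the average logistic loss plus `lambda * ||w||_1` (the intercept
#' is unpenalized) with a monotone FISTA scheme: gradient steps from an
#' extrapolated point, soft-thresholding of `w`, backtracking line search on
#' the smooth part, and fallback to a plain proximal step whenever the
#' accelerated candidate would increase the objective — so the objective is
#' non-increasing across iterations. Convergence is declared when the relative
#' objective change drops below `tol`.
#'
#' @param x n x m feature matrix (standardized columns recommended).
#' @param y Labels in `{-1, +1}` (numeric), or a factor/character vector
#'   combined with `positive` naming the +1 class.
#' @param lambda Penalty (>= 0).
#' @param tol Relative objective-change tolerance (default 1e-7).
#' @param max_iter Iteration cap (default 5000); hitting it returns the best
#'   iterate with a warning and `converged = FALSE`.
#' @param kkt_tol Maximum subgradient-optimality violation additionally
#'   required at convergence (default 1e-6); see [splr_kkt()].
#' @param positive When `y` is not numeric, the level mapped to +1.
#' @param w0,c0 Optional warm starts.
#' @return Object of class `splr`: coefficients `w`, intercept `c`, `lambda`,
#'   final penalized `objective`, `n_nonzero`, `converged`, `iterations`, and
#'   the per-iteration `objective_trace`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 50, 4)
#' y <- ifelse(x[, 1] - x[, 2] + rnorm(50) > 0, 1, -1)
#' fit <- splr(x, y, lambda = 0.05)
#' coef(fit)
#' @export
splr <- function(x, y, lambda, tol = 1e-7, max_iter = 5000L, kkt_tol = 1e-6,
                 positive = NULL, w0 = NULL, c0 = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(y)) {
    if (is.null(positive)) stop("supply `positive` for non-numeric labels")
    y <- ifelse(as.character(y) == positive, 1, -1)
  }
  check_labels(y)
  if (lambda < 0) stop("lambda must be >= 0")
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  m <- ncol(x)
  w <- if (is.null(w0)) rep(0, m) else w0
  cc <- if (is.null(c0)) intercept_only_fit(y) else c0
  obj <- splr_objective(x, y, w, cc, lambda)
  trace <- obj
  # Lipschitz guess for the logistic loss gradient: ||X||^2 / (4n), refined
  # by backtracking.
  L <- max(colSums(rbind(x, 1)^2)) / (4 * length(y))
  L <- max(L, 1e-10)
  w_prev <- w; c_prev <- cc
  t_prev <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    t_cur <- (1 + sqrt(1 + 4 * t_prev^2)) / 2
    beta <- (t_prev - 1) / t_cur
    vw <- w + beta * (w - w_prev)
    vc <- cc + beta * (cc - c_prev)
    g <- splr_grad(x, y, vw, vc)
    repeat {
      w_new <- soft_threshold(vw - g$gw / L, lambda / L)
      c_new <- vc - g$gc / L
      eta <- drop(x %*% w_new) + c_new
      loss_new <- mean(softplus(-y * eta))
      dw <- w_new - vw; dc <- c_new - vc
      quad <- g$loss + sum(g$gw * dw) + g$gc * dc +
        (L / 2) * (sum(dw^2) + dc^2)
      if (loss_new <= quad + 1e-12) break
      L <- L * 2
    }
    obj_new <- loss_new + lambda * sum(abs(w_new))
    if (obj_new > obj) {
      # monotone fallback: plain proximal step from the current iterate
      g <- splr_grad(x, y, w, cc)
      repeat {
        w_new <- soft_threshold(w - g$gw / L, lambda / L)
        c_new <- cc - g$gc / L
        loss_new <- mean(softplus(-y * (drop(x %*% w_new) + c_new)))
        dw <- w_new - w; dc <- c_new - cc
        quad <- g$loss + sum(g$gw * dw) + g$gc * dc +
          (L / 2) * (sum(dw^2) + dc^2)
        if (loss_new <= quad + 1e-12) break
        L <- L * 2
      }
      obj_new <- loss_new + lambda * sum(abs(w_new))
      t_cur <- 1  # restart momentum
    }
    w_prev <- w; c_prev <- cc; t_prev <- t_cur
    done <- abs(obj - obj_new) <= tol * max(1, abs(obj))
    if (obj_new <= obj) { w <- w_new; cc <- c_new; obj <- obj_new }
    trace <- c(trace, obj)
    if (done) {
      # objective has flattened; accept only if subgradient optimality holds
      gk <- splr_grad(x, y, w, cc)
      act <- w != 0
      viol <- max(abs(gk$gc),
                  if (any(act)) max(abs(gk$gw[act] + lambda * sign(w[act]))) else 0,
                  if (any(!act)) max(pmax(abs(gk$gw[!act]) - lambda, 0)) else 0)
      if (viol <= kkt_tol) { converged <- TRUE; break }
    }
  }
  if (!converged) warning("splr did not converge in ", max_iter, " iterations")
  structure(list(w = w, c = cc, lambda = lambda, objective = obj,
                 n_nonzero = sum(w != 0), converged = converged,
                 iterations = length(trace) - 1L, objective_trace = trace),
            class = "splr")
}

#' KKT optimality residual of a fitted splr model
#'
#' For active coordinates the subgradient condition requires
#' `grad_j + lambda * sign(w_j) = 0`; for zero coordinates
#' `|grad_j| <= lambda`. Returns the largest violation (0 at an exact
#' optimum).
#'
#' @param fit An `splr` object.
#' @param x,y The training data the model was fit on.
#' @return Maximum KKT violation (scalar, >= 0).
#' @export
splr_kkt <- function(fit, x, y) {
  g <- splr_grad(as.matrix(x), y, fit$w, fit$c)
  active <- fit$w != 0
  viol <- max(abs(g$gc),
              if (any(active)) max(abs(g$gw[active] + fit$lambda * sign(fit$w[active]))) else 0,
              if (any(!active)) max(pmax(abs(g$gw[!active]) - fit$lambda, 0)) else 0)
  viol
}

#' @export
print.splr <- function(x, ...) {
  cat(sprintf(
    "Sparse logistic regression: lambda = %.4g, %d / %d nonzero, objective %.6g%s\n",
    x$lambda, x$n_nonzero, length(x$w), x$objective,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
coef.splr <- function(object, ...) c(`(Intercept)` = object$c, object$w)

#' @export
summary.splr <- function(object, ...) {
  cat("L1-penalized logistic regression\n")
  print(object)
  cat(sprintf("  iterations: %d\n", object$iterations))
  act <- which(object$w != 0)
  if (length(act)) {
    cat("  active features:",
        paste(utils::head(act, 10), collapse = ", "),
        if (length(act) > 10) "..." else "", "\n")
  }
  invisible(object)
}

#' Predict from a sparse logistic regression fit
#'
#' @param object An `splr` object.
#' @param newdata n x m matrix of features.
#' @param type `"response"` (probability of the +1 class, default), `"link"`
#'   (linear predictor) or `"class"` (labels in -1/+1 at threshold 0.5).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.splr <- function(object, newdata, type = c("response", "link", "class"),
                         ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$w)) {
    stop(sprintf("newdata has %d columns but model has %d coefficients",
                 ncol(newdata), length(object$w)))
  }
  eta <- drop(newdata %*% object$w) + object$c
  switch(type,
         link = eta,
         response = sigmoid(eta),
         class = ifelse(sigmoid(eta) >= 0.5, 1, -1))
}
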