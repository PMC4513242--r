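make_toy <- function(seed, n = 60, m = 3, sd = 1.5) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m)
  beta <- seq(0.5, by = 0.3, length.out = m)
  y <- ifelse(drop(x %*% beta) + rnorm(n, sd = sd) > 0, 1, -1)
  list(x = x, y = y)
}

test_that("predicted probabilities follow the logistic form", {
  f <- structure(list(w = c(2), c = -1, lambda = 0), class = "splr")
  expect_equal(predict(f, matrix(1)), 1 / (1 + exp(-1)), tolerance = 1e-12)
  f0 <- structure(list(w = c(0, 0), c = 0, lambda = 0), class = "splr")
  expect_equal(predict(f0, matrix(rnorm(10), 5, 2)), rep(0.5, 5))
  fbig <- structure(list(w = 1, c = 0, lambda = 0), class = "splr")
  expect_equal(predict(fbig, matrix(700)), 1, tolerance = 1e-12)
  expect_true(predict(fbig, matrix(-700)) > 0)
  expect_error(predict(f, matrix(1, 1, 3)), "columns")
})

test_that("logistic loss matches naive summation and its known constants", {
  d <- make_toy(1)
  expect_equal(logistic_loss(d$x, d$y, rep(0, 3), 0), log(2), tolerance = 1e-12)
  set.seed(2)
  w <- rnorm(3); c0 <- 0.4
  naive <- mean(log(1 + exp(-d$y * (d$x %*% w + c0))))
  expect_equal(logistic_loss(d$x, d$y, w, c0), naive, tolerance = 1e-12)
  # scaling a separating direction drives the loss to zero monotonically
  xs <- matrix(c(-2, -1, 1, 2)); ys <- c(-1, -1, 1, 1)
  losses <- vapply(c(1, 5, 25), function(s) logistic_loss(xs, ys, s, 0),
                   numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[3], 1e-10)
})

test_that("unpenalized fits match the glm Newton oracle to 1e-6", {
  for (s in 1:20) {
    d <- make_toy(s, m = 1 + s %% 4)
    fit <- splr(d$x, d$y, lambda = 0, tol = 1e-10, max_iter = 50000,
                kkt_tol = 1e-8)
    oracle <- suppressWarnings(glm((d$y + 1) / 2 ~ d$x, family = binomial,
                                   control = glm.control(epsilon = 1e-12)))
    expect_lt(max(abs(coef(fit) - coef(oracle))), 1e-6)
  }
})

test_that("lambda at or above lambda_max zeroes all coefficients", {
  for (s in 1:5) {
    d <- make_toy(s, m = 5)
    lmax <- lambda_max(d$x, d$y)
    fit <- splr(d$x, d$y, lambda = lmax * (1 + 1e-10))
    expect_equal(fit$n_nonzero, 0L)
    expect_equal(fit$c, log(sum(d$y == 1) / sum(d$y == -1)), tolerance = 1e-6)
    # just below the threshold at least one coefficient activates
    fit2 <- splr(d$x, d$y, lambda = lmax * 0.9)
    expect_gt(fit2$n_nonzero, 0L)
  }
})

test_that("KKT conditions hold at convergence and the objective is monotone", {
  for (s in 1:5) {
    d <- make_toy(s, n = 80, m = 10)
    lam <- 0.3 * lambda_max(d$x, d$y)
    fit <- splr(d$x, d$y, lam)
    expect_true(fit$converged)
    expect_lt(splr_kkt(fit, d$x, d$y), lam + 1e-6)
    expect_true(all(diff(fit$objective_trace) <= 1e-12))
    expect_equal(fit$objective,
                 logistic_loss(d$x, d$y, fit$w, fit$c) + lam * sum(abs(fit$w)),
                 tolerance = 1e-12)
  }
})

test_that("degenerate inputs are handled as declared", {
  x <- matrix(0, 10, 2)
  y <- rep(c(1, -1), 5)
  fit <- splr(x, y, lambda = 0.1)
  expect_equal(fit$w, c(0, 0))
  expect_equal(fit$c, 0, tolerance = 1e-10)
  expect_equal(fit$objective, log(2), tolerance = 1e-10)
  expect_error(splr(x, rep(1, 10), 0.1), "both classes")
  expect_error(splr(x, y, -1), "lambda")
  expect_error(splr(x, c(y[-1], 2), 0.1), "-1")
})

test_that("lambda path descends from an all-zero fit and has declared ends", {
  d <- make_toy(3, m = 5)
  path <- lambda_path(d$x, d$y, n_values = 8)
  expect_length(path, 8)
  expect_true(all(diff(path) < 0))
  expect_equal(path[1], lambda_max(d$x, d$y))
  expect_equal(path[8], 1e-3 * path[1], tolerance = 1e-12)
  expect_equal(splr(d$x, d$y, path[1])$n_nonzero, 0L)
  p2 <- lambda_path(d$x, d$y, n_values = 2)
  expect_equal(p2, c(path[1], 1e-3 * path[1]), tolerance = 1e-12)
  expect_error(lambda_path(d$x, rep(1, 60), 5), "both classes")
})

test_that("sparsity is monotone along the path and warm starts agree", {
  d <- make_toy(4, n = 100, m = 20)
  path <- lambda_path(d$x, d$y, n_values = 10)
  nz_cold <- integer(10); w0 <- NULL; c0 <- NULL
  for (j in seq_along(path)) {
    cold <- splr(d$x, d$y, path[j], tol = 1e-12, kkt_tol = 1e-9,
                 max_iter = 200000)
    warm <- splr(d$x, d$y, path[j], tol = 1e-12, kkt_tol = 1e-9,
                 max_iter = 200000, w0 = w0, c0 = c0)
    w0 <- warm$w; c0 <- warm$c
    nz_cold[j] <- cold$n_nonzero
    expect_lt(max(abs(cold$w - warm$w)), 1e-5)
    expect_lt(abs(cold$c - warm$c), 1e-5)
  }
  # non-increasing sparsity in lambda (allow one-step solver wobble)
  expect_true(all(diff(nz_cold) >= -1))
})

test_that("penalized fits agree with glmnet on the shared objective", {
  skip_if_not_installed("glmnet")
  d <- make_toy(5, n = 120, m = 8, sd = 1)
  lam <- 0.05
  fit <- splr(d$x, d$y, lam, tol = 1e-10, kkt_tol = 1e-7, max_iter = 20000)
  gn <- glmnet::glmnet(d$x, factor(d$y), family = "binomial", alpha = 1,
                       lambda = lam, standardize = FALSE, thresh = 1e-12)
  expect_lt(max(abs(fit$w - as.numeric(gn$beta))), 1e-4)
  expect_lt(abs(fit$c - as.numeric(gn$a0)), 1e-4)
})

test_that("a sparse ground truth is recovered at a cross-validated penalty", {
  set.seed(11)
  n <- 500; m <- 200
  x <- matrix(rnorm(n * m), n, m)
  support <- 1:5
  beta <- numeric(m); beta[support] <- c(1.5, -1.5, 1.2, -1, 1)
  y <- ifelse(drop(x %*% beta) + rnorm(n) > 0, 1, -1)
  grid <- lambda_path(x, y, n_values = 12)
  fold <- rep_len(1:5, n)[sample(n)]
  acc <- sapply(seq_along(grid), function(j) {
    mean(vapply(1:5, function(f) {
      fit <- splr(x[fold != f, ], y[fold != f], grid[j],
                  tol = 1e-6, max_iter = 1000, kkt_tol = 1e-3)
      mean(predict(fit, x[fold == f, ], type = "class") == y[fold == f])
    }, numeric(1)))
  })
  best <- splr(x, y, grid[which.max(acc)])
  found <- which(best$w != 0)
  tp <- length(intersect(found, support))
  f1 <- 2 * tp / (length(found) + length(support))
  expect_gte(f1, 0.8)
})
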