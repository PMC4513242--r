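test_that("unfold puts mode-k fibers in rows and fold inverts it", {
  x <- array(1:24, dim = c(2, 3, 4))
  u1 <- unfold(x, 1)
  expect_equal(dim(u1), c(2L, 12L))
  expect_setequal(u1[1, ], as.vector(x[1, , ]))
  for (k in 1:3) expect_equal(fold(unfold(x, k), k, dim(x)), x)
  expect_error(unfold(x, 4), "out of range")

  # singular values do not depend on the column-ordering convention
  alt_unfold <- function(x, k) {  # non-cyclic: remaining modes in natural order
    d <- dim(x)
    matrix(aperm(x, c(k, setdiff(seq_along(d), k))), nrow = d[k])
  }
  set.seed(1)
  y <- array(rnorm(60), dim = c(3, 4, 5))
  for (k in 1:3) {
    expect_equal(svd(unfold(y, k))$d, svd(alt_unfold(y, k))$d,
                 tolerance = 1e-10)
  }
})

test_that("hosvd satisfies orthogonality, core structure and exactness", {
  set.seed(2)
  x <- array(rnorm(60), dim = c(3, 4, 5))
  h <- hosvd(x)
  for (k in 1:3) {
    u <- h$factors[[k]]
    expect_lt(max(abs(crossprod(u) - diag(dim(x)[k]))), 1e-10)
    # mode singular values equal a direct SVD of the unfolding
    expect_equal(h$mode_singular_values[[k]], svd(unfold(x, k))$d,
                 tolerance = 1e-10)
    # and equal the Frobenius norms of the core subtensors, in order
    uk <- unfold(h$core, k)
    norms <- sqrt(rowSums(uk^2))
    expect_equal(norms, h$mode_singular_values[[k]], tolerance = 1e-10)
    expect_true(all(diff(norms) <= 1e-10))
    # all-orthogonality of the core
    gram <- uk %*% t(uk)
    off <- gram - diag(diag(gram))
    expect_lt(max(abs(off)), 1e-8 * max(1, max(abs(gram))))
  }
  expect_lt(max(abs(reconstruct(h) - x)), 1e-8 * max(abs(x)))
})

test_that("hosvd of a rank-1 tensor concentrates in a single core entry", {
  a <- c(1, -2, 3); b <- c(2, 0.5, -1, 4); cc <- c(1, 1, 2)
  x <- outer(outer(a, b), cc)
  h <- hosvd(x)
  core <- h$core
  expect_equal(abs(core[1, 1, 1]),
               sqrt(sum(a^2)) * sqrt(sum(b^2)) * sqrt(sum(cc^2)),
               tolerance = 1e-10)
  core[1, 1, 1] <- 0
  expect_lt(max(abs(core)), 1e-10)
})

test_that("hosvd with a singleton mode reduces to matrix SVD", {
  set.seed(3)
  m <- matrix(rnorm(20), 4, 5)
  x <- array(m, dim = c(1, 4, 5))
  h <- hosvd(x)
  expect_equal(h$mode_singular_values[[2]], svd(m)$d, tolerance = 1e-10)
  expect_equal(h$mode_singular_values[[3]], c(svd(t(m))$d, 0), tolerance = 1e-10)
})

test_that("truncation is exact at full rank and error-bounded below it", {
  set.seed(4)
  x <- array(rnorm(8 * 10 * 12), dim = c(8, 10, 12))
  h <- hosvd(x)

  full <- reduce_tensor(h, c(8, 10, 12))
  rec <- full$reduced
  for (k in 2:3) rec <- ttm(rec, full$factors[[k]], k)
  expect_lt(max(abs(rec - x)), 1e-8 * max(abs(x)))

  prev_err <- Inf
  for (r in c(2, 4, 6, 8, 10)) {
    red <- reduce_tensor(h, c(8, r, min(r, 12)))
    rec <- red$reduced
    for (k in 2:3) rec <- ttm(rec, red$factors[[k]], k)
    err <- sum((rec - x)^2)
    bound <- sum(vapply(2:3, function(k) {
      sv <- h$mode_singular_values[[k]]
      keep <- if (k == 2) r else min(r, 12)
      sum(sv[-seq_len(keep)]^2)
    }, numeric(1)))
    expect_lte(err, bound + 1e-8)
    expect_lte(err, prev_err + 1e-10)  # nested truncations improve monotonically
    prev_err <- err
  }

  expect_error(reduce_tensor(h, c(8, 11, 12)), "ranks")
  expect_warning(reduce_tensor(h, c(4, 10, 12)), "sample mode")
})

test_that("raw features stack the upper triangle per subject", {
  sim <- worked_fixture()
  raw <- extract_raw(sim$cohort)
  expect_equal(dim(raw), c(12L, 15L))
  for (i in c(1, 7)) {
    expect_equal(unclass(raw)[i, ],
                 vectorize_upper_triangle(sim$cohort$data[i, , ]))
    expect_equal(symmetric_from_vector(unclass(raw)[i, ], 6),
                 sim$cohort$data[i, , ])
  }
  ph1 <- sim$cohort$phenotypes[1, ]
  tiny <- stack_cohort(list(matrix(c(0, 3, 3, 0), 2, 2)), ph1)
  expect_equal(dim(extract_raw(tiny)), c(1L, 1L))
})

test_that("svd features equal PCA scores from a covariance oracle", {
  sim <- toy_cohort(n_each = 15, p = 7, delta = 1, seed = 5)
  fs <- extract_svd(sim$cohort, k = 4)
  raw <- unclass(extract_raw(sim$cohort))
  xc <- scale(raw, center = TRUE, scale = FALSE)
  eig <- eigen(cov(xc), symmetric = TRUE)
  oracle <- xc %*% eig$vectors[, 1:4]
  for (j in 1:4) {
    # sign per component is arbitrary in the oracle
    expect_equal(abs(unclass(fs)[, j]), abs(oracle[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  # exact-rank data is fully retained
  ph <- sim$cohort$phenotypes[1:10, ]
  base1 <- symmetric_from_vector(runif(21), 7)
  base2 <- symmetric_from_vector(runif(21), 7)
  mats <- lapply(1:10, function(i) i * base1 + (11 - i) * base2)
  co <- stack_cohort(mats, ph)
  f2 <- extract_svd(co, k = 2)
  r2 <- unclass(extract_raw(co))
  xc2 <- scale(r2, center = TRUE, scale = FALSE)
  sv <- svd(xc2)
  expect_lt(sum(sv$d[-(1:2)]^2), 1e-16 * sum(sv$d^2))  # rank 2 exactly
  expect_equal(sum(f2^2), sum(xc2^2), tolerance = 1e-10) # variance retained

  expect_error(extract_svd(co, k = 50), "out of range")
})

test_that("hosvd features are k^2 per subject and full-rank is an isometry", {
  sim <- worked_fixture()
  fh <- extract_hosvd(sim$cohort, k = 2)
  expect_equal(dim(fh), c(12L, 4L))

  # row-major stacking of the reduced slice
  red <- reduce_tensor(sim$cohort$data, c(12, 2, 2))$reduced
  expect_equal(unclass(fh)[3, ], as.vector(t(red[3, , ])))

  # k = p: an orthogonal change of basis preserves pairwise distances
  fp <- unclass(extract_hosvd(sim$cohort, k = 6))
  flat <- unclass(extract_raw(sim$cohort))
  # distances on full slices (both triangles + diagonal) = 2 * upper dist
  for (pair in list(c(1, 2), c(3, 9))) {
    d_feat <- sum((fp[pair[1], ] - fp[pair[2], ])^2)
    d_slice <- sum((sim$cohort$data[pair[1], , ] - sim$cohort$data[pair[2], , ])^2)
    expect_equal(d_feat, d_slice, tolerance = 1e-8)
  }
  expect_error(extract_hosvd(sim$cohort, k = 7), "out of range")
})

test_that("feature extraction is deterministic across repeated runs", {
  sim <- toy_cohort(n_each = 8, p = 6, delta = 1, seed = 6)
  expect_identical(extract_hosvd(sim$cohort, k = 3),
                   extract_hosvd(sim$cohort, k = 3))
  expect_identical(extract_svd(sim$cohort, k = 3),
                   extract_svd(sim$cohort, k = 3))
})

test_that("planted low-rank group structure concentrates in hosvd features", {
  sim <- simulate_cohort(n_per_group = c(AD = 30, NC = 30), p = 20,
                         base_rank = 2, effect_edges = 20, effect_size = 1.5,
                         noise_sd = 0.1, effect_structure = "lowrank",
                         seed = 9)
  lab <- sim$cohort$phenotypes$label
  fh <- unclass(extract_hosvd(sim$cohort, k = 5))
  fr <- unclass(extract_raw(sim$cohort))
  tmax <- function(f) {
    max(abs(apply(f, 2, function(col) {
      if (sd(col) == 0) return(0)
      t.test(col[lab == "AD"], col[lab == "NC"], var.equal = TRUE)$statistic
    })))
  }
  expect_gt(tmax(fh), tmax(fr))
})
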