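#' Simulate a connectome cohort with planted group effects
#'
#' Generates synthetic structural connectivity cohorts with known ground
#' truth. Every subject's matrix is built as
#' `W = |M + shift_g * S + age_slope * (age - mean(age)) + sex_offset * sex + E|`
#' where `M` is a shared symmetric nonnegative low-rank mean network,
#' `S` marks the planted effect edges, the group shifts are
#' `(0, 0.5, 1) * effect_size * noise_sd` for NC, MCI and AD (the disease
#' gradient), the age and sex confound terms apply to all off-diagonal cells,
#' and `E` is symmetric i.i.d. Gaussian noise with sd `noise_sd`. Diagonals
#' are zeroed and each matrix is max-normalized, so outputs satisfy the same
#' invariants as real fiber-count networks. Ages are uniform on `age_range`
#' (optionally a per-group list, to construct age confounding) and sex is
#' Bernoulli(0.5).
#'
#' @param n_per_group Named integer vector, e.g. `c(AD = 39, MCI = 112,
#'   NC = 51)` (the defaults); groups with 0 subjects are dropped.
#' @param p Node count (default 113).
#' @param base_rank Rank of the shared mean network (default 4).
#' @param effect_edges Number of planted effect edges (default 20).
#' @param effect_size Group shift on effect edges, in units of `noise_sd`
#'   (default 1).
#' @param age_slope Per-year additive effect of (centered) age on every cell
#'   (default 0).
#' @param sex_offset Additive effect of male sex on every cell (default 0).
#' @param noise_sd Noise standard deviation (default 0.1; the mean network is
#'   scaled to maximum 1).
#' @param age_range Length-2 numeric, or a named list of length-2 numerics per
#'   group (default `c(60, 85)`).
#' @param effect_structure `"random"` scatters the effect edges uniformly over
#'   the upper triangle; `"block"` takes all edges within the smallest node
#'   clique holding at least `effect_edges` edges; `"lowrank"` spreads a
#'   rank-one group difference `u u'` (dense nonnegative `u`, off-diagonal
#'   cells scaled to unit root-mean-square) over the whole network — weak at
#'   every single edge but concentrated in one tensor direction, the regime
#'   where truncated tensor features aggregate signal that raw edges dilute.
#'   For `"lowrank"`, `effect_edges` only sets how many top cells are reported
#'   as ground truth.
#' @param seed Integer seed; the cohort is bitwise-reproducible.
#' @return List with `cohort` (a `cohort_tensor`) and `truth`: the effect-edge
#'   index matrix (i, j with i < j), per-group shifts, the mean network `M`,
#'   and the generator arguments.
#' @export
simulate_cohort <- function(n_per_group = c(AD = 39, MCI = 112, NC = 51),
                            p = 113L, base_rank = 4L, effect_edges = 20L,
                            effect_size = 1, age_slope = 0, sex_offset = 0,
                            noise_sd = 0.1, age_range = c(60, 85),
                            effect_structure = c("random", "block", "lowrank"),
                            seed = 1L) {
  effect_structure <- match.arg(effect_structure)
  n_per_group <- n_per_group[n_per_group > 0]
  if (length(n_per_group) == 0) stop("no subjects requested")
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% c("AD", "MCI", "NC"))) {
    stop("n_per_group must be named with AD/MCI/NC")
  }
  max_edges <- p * (p - 1) / 2
  if (effect_edges > max_edges) {
    stop(sprintf("effect_edges = %d exceeds available edges %d",
                 effect_edges, max_edges))
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)

  a <- matrix(abs(stats::rnorm(p * base_rank)), p, base_rank)
  m0 <- a %*% t(a)
  diag(m0) <- 0
  m0 <- m0 / max(m0)

  # row-major (i < j) coordinates of all edges
  ij <- which(t(upper.tri(matrix(0, p, p))), arr.ind = TRUE)[, c(2, 1)]
  colnames(ij) <- c("i", "j")
  if (effect_structure == "random") {
    edge_idx <- sample.int(max_edges, effect_edges)
    s_vec <- numeric(max_edges); s_vec[edge_idx] <- 1
    s_mat <- symmetric_from_vector(s_vec, p)
  } else if (effect_structure == "block") {
    q <- which(choose(seq_len(p), 2) >= effect_edges)[1]  # clique size
    nodes <- sample.int(p, q)
    in_clique <- ij[, "i"] %in% nodes & ij[, "j"] %in% nodes
    edge_idx <- which(in_clique)[seq_len(effect_edges)]
    s_vec <- numeric(max_edges); s_vec[edge_idx] <- 1
    s_mat <- symmetric_from_vector(s_vec, p)
  } else {
    u <- abs(stats::rnorm(p))
    s_mat <- u %*% t(u)
    diag(s_mat) <- 0
    s_vec <- vectorize_upper_triangle(s_mat)
    s_vec <- s_vec / sqrt(mean(s_vec^2))
    s_mat <- symmetric_from_vector(s_vec, p)
    edge_idx <- order(s_vec, decreasing = TRUE)[seq_len(effect_edges)]
  }
  effect_coords <- ij[edge_idx, , drop = FALSE]

  shifts <- c(NC = 0, MCI = 0.5, AD = 1) * effect_size * noise_sd
  groups <- rep(names(n_per_group), n_per_group)
  n <- length(groups)
  ages <- numeric(n)
  for (g in unique(groups)) {
    rng <- if (is.list(age_range)) age_range[[g]] else age_range
    ages[groups == g] <- stats::runif(sum(groups == g), rng[1], rng[2])
  }
  sexes <- ifelse(stats::runif(n) < 0.5, "M", "F")
  age_c <- ages - mean(ages)

  data <- array(0, dim = c(n, p, p))
  off_diag <- 1 - diag(p)
  for (i in seq_len(n)) {
    noise <- matrix(0, p, p)
    noise[upper.tri(noise)] <- stats::rnorm(max_edges, sd = noise_sd)
    noise <- noise + t(noise)
    w <- m0 + shifts[[groups[i]]] * s_mat +
      (age_slope * age_c[i] + sex_offset * (sexes[i] == "M")) * off_diag +
      noise
    w <- abs(w)
    diag(w) <- 0
    data[i, , ] <- w / max(w)
  }
  phenotypes <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    label = groups, age = ages, sex = sexes, stringsAsFactors = FALSE)
  cohort <- structure(list(data = data, phenotypes = phenotypes),
                      class = "cohort_tensor")
  list(cohort = cohort,
       truth = list(effect_edges = effect_coords, shifts = shifts,
                    mean_network = m0,
                    args = list(n_per_group = n_per_group, p = p,
                                base_rank = base_rank,
                                effect_edges = effect_edges,
                                effect_size = effect_size,
                                age_slope = age_slope,
                                sex_offset = sex_offset,
                                noise_sd = noise_sd, seed = seed)))
}

#' Tiny deterministic example cohort
#'
#' A fixed 12-subject, 6-node cohort (4 per diagnostic group, mild planted
#' effect) used in examples and unit tests. Always identical.
#'
#' @return The `simulate_cohort()` result for the fixed settings.
#' @export
worked_fixture <- function() {
  simulate_cohort(n_per_group = c(AD = 4, MCI = 4, NC = 4), p = 6L,
                  base_rank = 2L, effect_edges = 3L, effect_size = 2,
                  noise_sd = 0.1, seed = 42L)
}
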