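# Independent brute-force oracles used to pin expected values.

# All set partitions of 1..n (Bell-number enumeration, n <= 8).
enumerate_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (part in enumerate_partitions(n - 1)) {
    for (b in seq_along(part)) {
      newp <- part
      newp[[b]] <- c(newp[[b]], n)
      out[[length(out) + 1L]] <- newp
    }
    out[[length(out) + 1L]] <- c(part, list(n))
  }
  out
}

# Newman weighted modularity of a given partition (membership vector).
newman_q <- function(w, membership) {
  tw2 <- sum(w)               # 2W
  s <- rowSums(w)
  same <- outer(membership, membership, "==")
  sum((w - outer(s, s) / tw2) * same) / tw2
}

# Exhaustive maximum modularity over all partitions (small graphs only).
max_modularity_bruteforce <- function(w) {
  best <- -Inf
  for (part in enumerate_partitions(nrow(w))) {
    memb <- integer(nrow(w))
    for (b in seq_along(part)) memb[part[[b]]] <- b
    best <- max(best, newman_q(w, memb))
  }
  best
}

# All-pairs shortest paths with edge length 1/weight, Floyd-Warshall.
floyd_warshall_dist <- function(w) {
  p <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(p)) {
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Onnela clustering by direct enumeration of node triples.
onnela_bruteforce <- function(w) {
  p <- nrow(w)
  wh <- (w / max(w))^(1 / 3)
  ci <- numeric(p)
  for (i in seq_len(p)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(p)) {
      for (h in seq_len(p)) {
        if (j != i && h != i && j != h) acc <- acc + wh[i, j] * wh[i, h] * wh[j, h]
      }
    }
    ci[i] <- acc / (k * (k - 1))
  }
  mean(ci)
}

# Least-squares residuals via explicit pseudoinverse (SVD), independent of
# the package's QR path.
pinv_residuals <- function(y, x) {
  sv <- svd(x)
  pos <- sv$d > 1e-12 * sv$d[1]
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  drop(y - x %*% beta)
}

# AUC by exhaustive pair counting with half-credit for ties.
auc_pairs <- function(probs, truth) {
  pos <- which(truth == 1); neg <- which(truth == -1)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (probs[i] > probs[j]) + 0.5 * (probs[i] == probs[j])
    }
  }
  total / (length(pos) * length(neg))
}

# Small two-group cohort for harness tests.
toy_cohort <- function(n_each = 10, p = 8, delta = 0, seed = 1) {
  simulate_cohort(n_per_group = c(AD = n_each, NC = n_each), p = p,
                  base_rank = 2, effect_edges = 5, effect_size = delta,
                  noise_sd = 0.1, seed = seed)
}
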