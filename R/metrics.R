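#' @importFrom igraph graph_from_adjacency_matrix cluster_louvain modularity
#'   distances membership ecount rewire keeping_degseq as_edgelist
#'   components E
NULL

graph_from_weights <- function(m) {
  igraph::graph_from_adjacency_matrix(as.matrix(unclass(m)), mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted modularity by multi-restart Louvain optimization
#'
#' Maximizes Newman's weighted modularity Q with Louvain community detection,
#' taking the best of `restarts` runs over randomly permuted node orders
#' (Louvain's greedy passes depend on node order). Deterministic for a fixed
#' seed.
#'
#' @param m Nonnegative symmetric weight matrix.
#' @param seed Integer seed for restart permutations.
#' @param restarts Number of restarts (default 10).
#' @return List with `modularity` (Q, in [-0.5, 1]) and `partition`
#'   (integer community id per node).
#' @export
modularity_louvain <- function(m, seed = 1L, restarts = 10L) {
  m <- as.matrix(unclass(m))
  p <- nrow(m)
  if (max(m) == 0) {
    warning("graph has no edges; modularity defined as 0")
    return(list(modularity = 0, partition = seq_len(p)))
  }
  best_q <- -Inf
  best_part <- NULL
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  for (r in seq_len(restarts)) {
    perm <- if (r == 1L) seq_len(p) else sample.int(p)
    g <- graph_from_weights(m[perm, perm, drop = FALSE])
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    q <- igraph::modularity(g, igraph::membership(cl),
                            weights = igraph::E(g)$weight)
    if (q > best_q) {
      best_q <- q
      best_part <- integer(p)
      best_part[perm] <- as.integer(igraph::membership(cl))
    }
  }
  list(modularity = best_q, partition = best_part)
}

#' Mean Onnela weighted clustering coefficient
#'
#' Per node i with binary degree k_i >= 2,
#' C_i = (1 / (k_i (k_i - 1))) * sum over pairs (j, h) of
#' (w_ij w_ih w_jh)^(1/3) with weights first scaled by the matrix maximum;
#' nodes of degree < 2 contribute 0. Returns the mean over all nodes.
#'
#' @param m Nonnegative symmetric weight matrix.
#' @return Mean clustering coefficient, in [0, 1].
#' @export
mean_clustering <- function(m) {
  m <- as.matrix(unclass(m))
  mx <- max(m)
  if (mx == 0) return(0)
  w <- (m / mx)^(1 / 3)
  k <- rowSums(m > 0)
  cyc <- diag(w %*% w %*% w)       # 2 * sum over unordered triangle pairs
  ci <- ifelse(k >= 2, cyc / (k * (k - 1)), 0)
  mean(ci)
}

pair_distances <- function(m) {
  m <- as.matrix(unclass(m))
  g <- graph_from_weights(m)
  if (igraph::ecount(g) == 0) {
    d <- matrix(Inf, nrow(m), nrow(m)); diag(d) <- 0
    return(d)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

#' Weighted characteristic path length
#'
#' Mean shortest-path length over ordered reachable node pairs, with edge
#' length 1/weight (strong connections are short). Unreachable pairs are
#' excluded from the mean; a graph with no edges is an error.
#'
#' @param m Nonnegative symmetric weight matrix.
#' @return Characteristic path length (> 0).
#' @export
characteristic_path_length <- function(m) {
  d <- pair_distances(m)
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  if (length(finite) == 0) stop("no finite paths: graph has no edges")
  mean(finite)
}

#' Weighted global efficiency
#'
#' Mean of inverse shortest-path distances over ordered node pairs, counting
#' unreachable pairs as efficiency 0. In [0, 1] for max-normalized weights.
#'
#' @param m Nonnegative symmetric weight matrix.
#' @return Global efficiency.
#' @export
global_efficiency <- function(m) {
  d <- pair_distances(m)
  off <- d[row(d) != col(d)]
  if (length(off) == 0) return(0)
  mean(ifelse(is.finite(off), 1 / off, 0))
}

maslov_sneppen_null <- function(m, swap_passes = 10L) {
  # degree-preserving rewire of the binarized topology, weights reshuffled
  p <- nrow(m)
  g <- graph_from_weights(m)
  ne <- igraph::ecount(g)
  weights <- igraph::E(g)$weight
  for (attempt in 1:10) {
    gr <- if (swap_passes > 0) {
      igraph::rewire(g, igraph::keeping_degseq(niter = swap_passes * ne))
    } else g
    if (igraph::components(gr)$no == igraph::components(g)$no) {
      el <- igraph::as_edgelist(gr, names = FALSE)
      w <- if (swap_passes > 0) sample(weights) else weights
      null <- matrix(0, p, p)
      null[el] <- w
      null[el[, c(2, 1), drop = FALSE]] <- w
      return(null)
    }
  }
  stop("could not generate a connected null network in 10 attempts")
}

#' Small-worldness sigma against rewired null networks
#'
#' sigma = (C / C_null) / (L / L_null) where C is the mean Onnela clustering
#' coefficient, L the characteristic path length, and the null values are
#' means over `n_null` degree-preserving Maslov-Sneppen rewirings of the
#' binarized topology with edge weights reshuffled. `swap_passes = 0` keeps
#' the graph itself as its null (sigma exactly 1), which is useful as a
#' self-consistency check. sigma > 1 indicates small-world organization.
#'
#' @param m Nonnegative symmetric weight matrix.
#' @param n_null Number of null networks (default 10).
#' @param seed Integer seed.
#' @param swap_passes Edge-swap passes per edge for the rewiring (default 10).
#' @return Small-worldness sigma (> 0).
#' @export
small_worldness <- function(m, n_null = 10L, seed = 1L, swap_passes = 10L) {
  m <- as.matrix(unclass(m))
  if (n_null < 1L) stop("need at least one null network")
  cc <- mean_clustering(m)
  cpl <- characteristic_path_length(m)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  c_null <- l_null <- numeric(n_null)
  for (i in seq_len(n_null)) {
    nm <- maslov_sneppen_null(m, swap_passes)
    c_null[i] <- mean_clustering(nm)
    l_null[i] <- characteristic_path_length(nm)
  }
  if (mean(c_null) <= 0) stop("degenerate null: zero clustering in null ensemble")
  (cc / mean(c_null)) / (cpl / mean(l_null))
}

#' Five weighted global network measures for one network
#'
#' Computes modularity (MOD), mean clustering coefficient (MCC),
#' characteristic path length (CPL), global efficiency (GLOB) and
#' small-worldness (SW) on a max-normalized copy of the input (a warning is
#' issued if normalization was needed).
#'
#' @param m Nonnegative symmetric weight matrix.
#' @param n_null Null networks for SW (default 10).
#' @param seed Integer seed for MOD restarts and SW nulls.
#' @return Named numeric vector `c(MOD, MCC, CPL, GLOB, SW)`.
#' @export
global_metrics <- function(m, n_null = 10L, seed = 1L) {
  m <- as.matrix(unclass(m))
  if (max(m) > 0 && abs(max(m) - 1) > 1e-12) {
    warning("weights not max-normalized; normalizing internally")
    m <- m / max(m)
  }
  c(MOD = modularity_louvain(m, seed = seed)$modularity,
    MCC = mean_clustering(m),
    CPL = characteristic_path_length(m),
    GLOB = global_efficiency(m),
    SW = small_worldness(m, n_null = n_null, seed = seed))
}

#' Global network measures for every subject of a cohort
#'
#' @param cohort A `cohort_tensor` of nonnegative networks.
#' @param n_null Null networks for SW per subject.
#' @param seed Master seed; subject i uses `seed + i`.
#' @return n x 5 matrix with columns MOD, MCC, CPL, GLOB, SW and subject ids
#'   as row names.
#' @export
cohort_metrics <- function(cohort, n_null = 10L, seed = 1L) {
  n <- dim(cohort$data)[1]
  out <- t(vapply(seq_len(n), function(i) {
    global_metrics(cohort$data[i, , ], n_null = n_null, seed = seed + i)
  }, numeric(5)))
  rownames(out) <- cohort$phenotypes$subject_id
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
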