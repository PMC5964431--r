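# Graph-topology metrics of the binarized covariance network: clustering,
# harmonic characteristic path length, global/local efficiency, normalized
# betweenness, degree-preserving rewired nulls, and small-world indices.
# Conventions follow the binary undirected brain-network literature:
# disconnected pairs contribute 0 reciprocal distance, nodes of degree < 2
# contribute 0 to clustering and local efficiency.

#' Clustering coefficient
#'
#' Per node, `C_i = 2 E(i) / (k_i (k_i - 1))` where `E(i)` counts edges among
#' the `k_i` neighbours of node i; nodes with fewer than two neighbours
#' contribute 0. The network value `C` is the mean over all nodes.
#'
#' @param A Binary symmetric adjacency matrix.
#' @return List with `C_node` (per-node values) and `C` (their mean).
#' @export
clustering_coefficient <- function(A) {
  check_adjacency(A)
  k <- colSums(A)
  # diag(A^3)[i] = closed 3-walks at i = 2 * E(i), so C_i = diag(A^3)/(k(k-1))
  walks3 <- diag(A %*% A %*% A)
  C_node <- ifelse(k >= 2, walks3 / (k * (k - 1)), 0)
  list(C_node = as.numeric(C_node), C = mean(C_node))
}

# All-pairs shortest-path lengths on the binary graph; Inf marks
# disconnected pairs. Level-synchronous BFS through boolean matrix powers:
# a pair's distance is the first power of A with a nonzero walk count —
# efficient for the dense <= 90-node matrices this package handles.
shortest_path_lengths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  walk <- A
  d <- 1
  repeat {
    d <- d + 1
    walk <- (walk %*% A > 0) + 0
    new <- walk == 1 & !is.finite(D)
    if (!any(new) || d > n) break
    D[new] <- d
  }
  D
}

# Mean reciprocal shortest-path length over ordered pairs (the efficiency
# sum); shared by the global and local efficiency entry points.
mean_inverse_distance <- function(A) {
  n <- nrow(A)
  inv <- 1 / shortest_path_lengths(A)
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Characteristic path length (harmonic form)
#'
#' `L = 1 / ((1 / (N (N - 1))) * sum_{i != j} 1 / d_ij)`: the reciprocal of
#' the mean reciprocal shortest-path length, so that disconnected pairs
#' (infinite distance) contribute 0 rather than breaking the mean. An
#' edgeless graph has `L = Inf`. By construction `L * E_glob = 1` whenever
#' `E_glob > 0`.
#'
#' @param A Binary symmetric adjacency matrix, at least 2 nodes.
#' @return Scalar path length (`Inf` for an edgeless graph).
#' @export
characteristic_path_length <- function(A) {
  eg <- global_efficiency(A)
  if (eg == 0) Inf else 1 / eg
}

#' Global efficiency
#'
#' Mean reciprocal shortest-path length over ordered node pairs; disconnected
#' pairs contribute 0. Equals 1 on a complete graph.
#'
#' @param A Binary symmetric adjacency matrix, at least 2 nodes.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(A) {
  check_adjacency(A)
  if (nrow(A) < 2) stopf("need at least 2 nodes")
  mean_inverse_distance(A)
}

#' Local efficiency
#'
#' For each node k, the global efficiency of the subgraph induced by k's
#' neighbours (distances measured inside that subgraph); nodes with fewer
#' than two neighbours contribute 0. The network value is the mean over all
#' nodes.
#'
#' @param A Binary symmetric adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
local_efficiency <- function(A) {
  check_adjacency(A)
  n <- nrow(A)
  e <- vapply(seq_len(n), function(k) {
    nb <- which(A[k, ] == 1)
    if (length(nb) < 2) return(0)
    mean_inverse_distance(A[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(e)
}

#' Betweenness centrality, raw and normalized
#'
#' `B_i` sums, over unordered source-target pairs excluding i, the fraction
#' of shortest paths between the pair that pass through i. The normalized
#' value is `bi = B_i / mean(B)`; hubs are defined by `bi > 1.5`. If every
#' `B_i` is 0 (e.g. a complete graph) the normalization is degenerate and
#' `bi` is returned as all zeros with `degenerate = TRUE`.
#'
#' @param A Binary symmetric adjacency matrix, at least 3 nodes.
#' @return List with `B_node`, `bi_node`, and `degenerate` flag.
#' @export
betweenness_normalized <- function(A) {
  check_adjacency(A)
  if (nrow(A) < 3) stopf("need at least 3 nodes")
  B <- igraph::betweenness(adjacency_to_igraph(A), directed = FALSE)
  B <- as.numeric(B)
  mB <- mean(B)
  if (mB == 0) {
    list(B_node = B, bi_node = rep(0, length(B)), degenerate = TRUE)
  } else {
    list(B_node = B, bi_node = B / mB, degenerate = FALSE)
  }
}

#' Degree-preserving rewired null network
#'
#' Randomizes the graph by double-edge swaps — pick edges (a,b) and (c,d)
#' and replace them with (a,d) and (c,b) when that creates no self-loop or
#' duplicate — which preserves every node's degree exactly. This is the
#' standard null model for small-world indices: same number of nodes, edges
#' and degrees, randomized topology.
#'
#' @param A Binary symmetric adjacency matrix with at least 2 edges.
#' @param seed Integer RNG seed; output is deterministic for a fixed seed.
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @return A rewired adjacency matrix with the same degree sequence. With
#'   `swaps_per_edge = 0` the input is returned unchanged.
#' @export
rewire_null <- function(A, seed = 1L, swaps_per_edge = 10) {
  check_adjacency(A)
  n_edges <- sum(A) / 2
  if (n_edges < 2) stopf("need at least 2 edges to rewire")
  if (swaps_per_edge == 0) return(A)
  g <- adjacency_to_igraph(A)
  g2 <- with_seed(seed, igraph::rewire(
    g, igraph::keeping_degseq(niter = ceiling(swaps_per_edge * n_edges))))
  igraph_to_adjacency(g2)
}

#' Small-world indices against rewired nulls
#'
#' Compares the observed clustering and path length with their means over
#' `n_null` degree-preserving rewired null networks:
#' `gamma = C / C_rand`, `lambda = L / L_rand`, `sigma = gamma / lambda`.
#' A small-world network has `gamma >> 1`, `lambda ~ 1`, `sigma > 1`.
#' Nulls with zero clustering or infinite path length carry no ratio and are
#' excluded (their count is reported).
#'
#' @param A Binary symmetric adjacency matrix with at least one edge.
#' @param n_null Number of null networks (default 200).
#' @param seed Master integer seed; per-null seeds are derived from it.
#' @param swaps_per_edge Attempted swaps per edge in each null.
#' @return List with `gamma`, `lambda`, `sigma`, `C`, `L`, `C_rand`,
#'   `L_rand`, `n_null_used`, `n_null_degenerate`.
#' @export
small_world_indices <- function(A, n_null = 200, seed = 1L, swaps_per_edge = 10) {
  check_adjacency(A)
  if (sum(A) == 0) stopf("graph must have at least one edge")
  C_obs <- clustering_coefficient(A)$C
  L_obs <- characteristic_path_length(A)
  C_null <- numeric(n_null)
  L_null <- numeric(n_null)
  for (b in seq_len(n_null)) {
    An <- rewire_null(A, seed = derive_seed(seed, b), swaps_per_edge = swaps_per_edge)
    C_null[b] <- clustering_coefficient(An)$C
    L_null[b] <- characteristic_path_length(An)
  }
  ok <- C_null > 0 & is.finite(L_null)
  if (!any(ok)) stopf("all null networks degenerate (zero clustering or disconnected)")
  C_rand <- mean(C_null[ok])
  L_rand <- mean(L_null[ok])
  gamma <- C_obs / C_rand
  lambda <- L_obs / L_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       C = C_obs, L = L_obs, C_rand = C_rand, L_rand = L_rand,
       n_null_used = sum(ok), n_null_degenerate = sum(!ok))
}

#' Detect hubs from normalized betweenness
#'
#' Hubs are nodes whose normalized betweenness strictly exceeds the
#' threshold (default `bi > 1.5`), returned sorted by descending `bi`.
#'
#' @param bi_node Numeric vector of normalized betweenness values.
#' @param threshold Hub threshold (default 1.5).
#' @return Integer vector of node indices (empty, with attribute
#'   `degenerate = TRUE`, when `bi_node` is all zero).
#' @export
detect_hubs <- function(bi_node, threshold = 1.5) {
  if (all(bi_node == 0)) {
    return(structure(integer(0), degenerate = TRUE))
  }
  idx <- which(bi_node > threshold)
  idx[order(-bi_node[idx])]
}

#' Full metric set for one network
#'
#' Computes every reported network parameter — C, L, global and local
#' efficiency, gamma/lambda/sigma against `n_null` rewired nulls, and raw
#' plus normalized betweenness — for a single binarized network.
#'
#' @param A Binary symmetric adjacency matrix.
#' @param n_null Number of rewired nulls for the small-world indices
#'   (default 200); `0` skips them.
#' @param seed Master integer seed for the nulls.
#' @param swaps_per_edge Attempted swaps per edge in each null.
#' @return An object of class `metric_set` (a named list).
#' @export
network_metrics <- function(A, n_null = 200, seed = 1L, swaps_per_edge = 10) {
  check_adjacency(A)
  cc <- clustering_coefficient(A)
  eg <- global_efficiency(A)
  bt <- betweenness_normalized(A)
  out <- list(C = cc$C, C_node = cc$C_node,
              L = if (eg > 0) 1 / eg else Inf,
              E_glob = eg, E_loc = local_efficiency(A),
              B_node = bt$B_node, bi_node = bt$bi_node,
              betweenness_degenerate = bt$degenerate,
              gamma = NA_real_, lambda = NA_real_, sigma = NA_real_,
              C_rand = NA_real_, L_rand = NA_real_,
              n_null = n_null, seed = as.integer(seed))
  if (n_null > 0) {
    sw <- small_world_indices(A, n_null = n_null, seed = seed,
                              swaps_per_edge = swaps_per_edge)
    out[c("gamma", "lambda", "sigma", "C_rand", "L_rand")] <-
      sw[c("gamma", "lambda", "sigma", "C_rand", "L_rand")]
  }
  class(out) <- "metric_set"
  out
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> C = %.4f, L = %.4f, E_glob = %.4f, E_loc = %.4f\n",
              x$C, x$L, x$E_glob, x$E_loc))
  if (!is.na(x$gamma)) {
    cat(sprintf("  gamma = %.4f, lambda = %.4f, sigma = %.4f (%d nulls)\n",
                x$gamma, x$lambda, x$sigma, x$n_null))
  }
  cat(sprintf("  hubs (bi > 1.5): %s\n",
              paste(detect_hubs(x$bi_node), collapse = ", ")))
  invisible(x)
}
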