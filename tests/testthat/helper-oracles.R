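# Independent brute-force oracles for graph metrics and multiple testing.
# Deliberately naive (triple loops, exhaustive path enumeration, direct
# definitions) so they share no code path with the implementation.

# All-pairs shortest paths by Floyd-Warshall.
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Per-node clustering by exhaustive triangle counting.
oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    e <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (A[nb[a], nb[b]] == 1) e <- e + 1
      }
    }
    2 * e / (k * (k - 1))
  }, numeric(1))
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
    }
  }
  tot / (n * (n - 1))
}

oracle_path_length <- function(A) {
  eg <- oracle_global_efficiency(A)
  if (eg == 0) Inf else 1 / eg
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(k) {
    nb <- which(A[k, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

# Betweenness by exhaustive enumeration of all shortest paths: for each
# ordered step we only follow edges that decrease the distance to the target.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  B <- numeric(n)
  enumerate_paths <- function(v, t) {
    if (v == t) return(list(t))
    out <- list()
    for (w in which(A[v, ] == 1)) {
      if (is.finite(D[w, t]) && D[w, t] == D[v, t] - 1) {
        for (p in enumerate_paths(w, t)) out[[length(out) + 1]] <- c(v, p)
      }
    }
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t])) next
      paths <- enumerate_paths(s, t)
      np <- length(paths)
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        B[interior] <- B[interior] + 1 / np
      }
    }
  }
  B
}

# Benjamini-Hochberg rejections straight from the step-up definition.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  s <- sort(p)
  k <- max(c(0, which(s <= seq_len(m) * q / m)))
  if (k == 0) rep(FALSE, m) else p <= s[k]
}

# Seeded Erdos-Renyi-style random adjacency at a given edge density.
random_adjacency <- function(n, density, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.numeric(runif(length(up)) < density)
  A + t(A)
}
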