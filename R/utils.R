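# Internal helpers shared across modules.

# Derive a child seed from a master seed and a stream index. Kept below 2^31
# so it is always a valid argument to set.seed().
derive_seed <- function(master, index) {
  master <- as.integer(master)
  index <- as.integer(index)
  as.integer((as.double(master %% 65011) * 32749 + as.double(index) * 7919 + 104729) %% 2147483647)
}

# Evaluate `expr` under a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_adjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stopf("adjacency must be a square matrix")
  }
  if (any(A != 0 & A != 1)) stopf("adjacency must be binary (0/1)")
  if (any(A != t(A))) stopf("adjacency must be symmetric")
  if (any(diag(A) != 0)) stopf("adjacency must have a zero diagonal")
  invisible(A)
}

adjacency_to_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

igraph_to_adjacency <- function(g) {
  A <- igraph::as_adjacency_matrix(g, type = "both", sparse = FALSE)
  storage.mode(A) <- "double"
  dimnames(A) <- NULL
  A
}

# Upper-triangle index pairs (i < j) in lexicographic (row-major) order;
# the deterministic tie-break order used by sparsity binarization.
upper_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}
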