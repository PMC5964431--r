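# Group-level metabolic covariance network: shrinkage partial-correlation
# estimation and sparsity-threshold binarization.

#' Group partial-correlation network
#'
#' Estimates the N x N matrix of partial correlations between regions from a
#' normalized subjects x regions table. With p = 90 regions and n = 22
#' subjects the sample covariance is singular, so it is shrunk toward its
#' diagonal before inversion:
#' `S* = (1 - shrinkage) * S + shrinkage * diag(S)`; the partial correlation
#' is then `R_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj)` with
#' `Omega = inv(S*)`, diagonal set to 1.
#'
#' @param cohort A normalized [region_matrix()] with at least 4 subjects.
#' @param shrinkage Diagonal shrinkage intensity in `[0, 1]` (default 0.5).
#'   `shrinkage = 0` requires n > p; a pseudo-inverse fallback is available
#'   via `estimator = "pseudoinverse"`.
#' @param estimator `"shrinkage"` (default) or `"pseudoinverse"`
#'   (Moore-Penrose inverse of the raw sample covariance).
#' @return An object of class `group_network` with fields `region_ids`, `R`
#'   (partial correlations, diagonal 1), `shrinkage`, and empty binarization
#'   slots `A`/`sparsity` until [binarize_by_sparsity()] is applied.
#' @export
partial_correlation_matrix <- function(cohort, shrinkage = 0.7,
                                       estimator = c("shrinkage", "pseudoinverse")) {
  if (!inherits(cohort, "region_matrix")) stopf("cohort must be a region_matrix")
  if (!cohort$normalized) {
    stopf("cohort must be normalized first (see normalize_region_matrix)")
  }
  if (nrow(cohort$values) < 4) stopf("need at least 4 subjects")
  estimator <- match.arg(estimator)
  if (shrinkage < 0 || shrinkage > 1) stopf("shrinkage must be in [0, 1]")

  S <- stats::cov(cohort$values)
  if (estimator == "pseudoinverse") {
    Omega <- MASS::ginv(S)
  } else {
    S_star <- (1 - shrinkage) * S + shrinkage * diag(diag(S))
    Omega <- tryCatch(chol2inv(chol(S_star)), error = function(e) NULL)
    if (is.null(Omega)) {
      stopf(paste("shrunk covariance is singular (possible only near shrinkage 0",
                  "with regions >= subjects); use a positive shrinkage"))
    }
  }
  d <- sqrt(diag(Omega))
  R <- -Omega / tcrossprod(d)
  R <- (R + t(R)) / 2  # symmetrize away rounding asymmetry
  diag(R) <- 1
  structure(list(region_ids = cohort$region_ids, R = R,
                 shrinkage = if (estimator == "shrinkage") shrinkage else NA_real_,
                 estimator = estimator, A = NULL, sparsity = NA_real_),
            class = "group_network")
}

#' @export
print.group_network <- function(x, ...) {
  n <- nrow(x$R)
  cat(sprintf("<group_network> %d regions, estimator %s", n, x$estimator))
  if (!is.null(x$A)) {
    cat(sprintf(", binarized at sparsity %.3g (%d edges)",
                x$sparsity, sum(x$A[upper.tri(x$A)])))
  }
  cat("\n")
  invisible(x)
}

#' Binarize a network at a fixed sparsity
#'
#' Ranks the N(N-1)/2 distinct region pairs by absolute partial correlation
#' (negative correlations participate through their absolute value) and keeps
#' the top `floor(sparsity * N(N-1)/2)` pairs as edges. Ties are broken by
#' ascending (i, j) pair order, so the rule is deterministic and depends on
#' `|R|` only through ranks.
#'
#' @param net A `group_network` from [partial_correlation_matrix()].
#' @param sparsity Fraction of retained edges in `(0, 1)`; the headline
#'   analysis threshold is 0.21.
#' @return The `group_network` with `A` (binary adjacency, zero diagonal) and
#'   `sparsity` filled in.
#' @export
binarize_by_sparsity <- function(net, sparsity) {
  if (!inherits(net, "group_network")) stopf("net must be a group_network")
  if (!is.finite(sparsity) || sparsity <= 0 || sparsity >= 1) {
    stopf("sparsity must be in (0, 1)")
  }
  n <- nrow(net$R)
  pairs <- upper_pairs(n)
  vals <- abs(net$R[pairs])
  n_edges <- floor(sparsity * nrow(pairs))
  ord <- order(-vals, seq_along(vals))  # ties keep lexicographic (i, j) order
  keep <- ord[seq_len(n_edges)]
  A <- matrix(0, n, n)
  A[pairs[keep, , drop = FALSE]] <- 1
  A <- A + t(A)
  net$A <- A
  net$sparsity <- sparsity
  net
}

#' Largest connected component size
#'
#' @param A Binary symmetric adjacency matrix.
#' @return Node count of the largest connected component (1 for an edgeless
#'   graph).
#' @export
largest_component_size <- function(A) {
  check_adjacency(A)
  comp <- igraph::components(adjacency_to_igraph(A))
  max(comp$csize)
}

#' Minimum sparsity keeping the network connected enough
#'
#' Scans an ascending sparsity grid and reports the smallest value at which
#' the largest connected component exceeds `min_size` nodes, together with
#' the full component-size-versus-sparsity curve.
#'
#' @param net A `group_network` (R estimated).
#' @param sparsity_grid Ascending sparsities in `(0, 1)`; default the
#'   0.06-0.40 step 0.01 analysis grid (see [sparsity_grid()]).
#' @param min_size Component-size requirement (strict `>`); default 50.
#' @return List with `sparsity` (the first qualifying grid value, or `NA` if
#'   none — `reached = FALSE`), `reached`, and `curve` (data.frame of
#'   sparsity, largest component size, edge count).
#' @export
min_connected_sparsity <- function(net, sparsity_grid = NULL, min_size = 50) {
  if (is.null(sparsity_grid)) sparsity_grid <- sparsity_grid()
  if (is.unsorted(sparsity_grid, strictly = TRUE)) {
    stopf("sparsity_grid must be strictly ascending")
  }
  sizes <- vapply(sparsity_grid, function(s) {
    largest_component_size(binarize_by_sparsity(net, s)$A)
  }, numeric(1))
  edges <- vapply(sparsity_grid, function(s) {
    n <- nrow(net$R)
    floor(s * n * (n - 1) / 2)
  }, numeric(1))
  hit <- which(sizes > min_size)
  list(sparsity = if (length(hit)) sparsity_grid[hit[1]] else NA_real_,
       reached = length(hit) > 0,
       curve = data.frame(sparsity = sparsity_grid,
                          largest_component = sizes, n_edges = edges))
}

#' The analysis sparsity grid
#'
#' The network-density grid over which metric curves are traced: 0.06 to
#' 0.40 in steps of 0.01 (35 thresholds).
#'
#' @return Numeric vector of sparsities.
#' @export
sparsity_grid <- function() seq(0.06, 0.40, by = 0.01)

#' Write a group network's matrices as TSV
#'
#' @param net A `group_network`.
#' @param r_path,a_path Output paths for the partial-correlation matrix and
#'   (if binarized) the adjacency; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_group_network <- function(net, r_path = NULL, a_path = NULL) {
  hdr <- paste0("r", net$region_ids)
  if (!is.null(r_path)) {
    m <- net$R
    dimnames(m) <- list(hdr, hdr)
    utils::write.table(m, r_path, sep = "\t", quote = FALSE, col.names = NA)
  }
  if (!is.null(a_path)) {
    if (is.null(net$A)) stopf("network is not binarized; call binarize_by_sparsity")
    m <- net$A
    dimnames(m) <- list(hdr, hdr)
    utils::write.table(m, a_path, sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(c(r_path, a_path))
}
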