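# Synthetic cohort generator: regional signals with a small-world covariance
# backbone, planted hub alterations, and optional toy volume rendering.
# Stands in for an undeposited clinical FDG-PET cohort (2 x 22 subjects,
# 90 regions) so every downstream stage is testable.

#' Ring-lattice adjacency, optionally Watts-Strogatz rewired
#'
#' Builds the classic ring lattice in which every node is tied to its
#' `k` nearest neighbours (`k/2` on each side), then rewires each lattice
#' edge with probability `p` to a uniformly chosen new endpoint (avoiding
#' self-loops and duplicate edges). With small `p` this is the canonical
#' small-world construction.
#'
#' @param n Number of nodes (>= 4).
#' @param k Even number of neighbours per node, `k < n`.
#' @param p Rewiring probability in `[0, 1]`.
#' @param seed Integer RNG seed (only consulted when `p > 0`).
#' @return Binary symmetric adjacency matrix with zero diagonal.
#' @export
small_world_lattice <- function(n, k, p = 0, seed = 1L) {
  if (n < 4) stopf("n must be >= 4")
  if (k %% 2 != 0) stopf("k must be even (ring-lattice neighbours per node)")
  if (k >= n) stopf("k must be < n")
  if (p < 0 || p > 1) stopf("p must be in [0, 1]")
  A <- matrix(0, n, n)
  for (d in seq_len(k / 2)) {
    idx <- seq_len(n)
    nb <- ((idx - 1L + d) %% n) + 1L
    A[cbind(idx, nb)] <- 1
    A[cbind(nb, idx)] <- 1
  }
  if (p > 0) {
    A <- with_seed(seed, {
      pairs <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
      # iterate in deterministic order; rewire the far endpoint
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      for (e in seq_len(nrow(pairs))) {
        if (stats::runif(1) < p) {
          i <- pairs[e, 1]; j <- pairs[e, 2]
          if (A[i, j] == 0) next  # already moved by an earlier rewire
          candidates <- which(A[i, ] == 0)
          candidates <- setdiff(candidates, i)
          if (length(candidates) == 0L) next
          new_j <- candidates[sample.int(length(candidates), 1L)]
          A[i, j] <- A[j, i] <- 0
          A[i, new_j] <- A[new_j, i] <- 1
        }
      }
      A
    })
  }
  A
}

#' Specify a group covariance with a small-world backbone
#'
#' Constructs the population covariance from which one cohort's regional
#' signals are drawn: identity plus `diagonal_load` on the diagonal and
#' `edge_strength` on every backbone edge of a (possibly rewired) ring
#' lattice. Planted alterations then strengthen (add `magnitude` to) or
#' weaken (zero) all off-diagonal entries incident to named regions —
#' the covariance-level analogue of creating or destroying a network hub.
#' If the result is not positive definite the diagonal is loaded minimally:
#' `|min eigenvalue| + 0.01` is added.
#'
#' @param n_regions Number of regions (>= 4); 90 matches an AAL-style atlas.
#' @param backbone_degree Even lattice degree (default 8).
#' @param rewire_prob Backbone rewiring probability (default 0.05).
#' @param edge_strength Covariance placed on each backbone edge (default 0.3).
#' @param diagonal_load Value added to the unit diagonal (default 0.5); keeps
#'   the matrix well-conditioned at n = 22 subjects, p = 90 regions.
#' @param planted_alterations List of `list(region = id, mode =
#'   "strengthen"|"weaken", magnitude = m)` entries (magnitude ignored for
#'   "weaken").
#' @param seed Integer seed controlling backbone rewiring.
#' @return An object of class `covariance_spec`: the arguments plus `matrix`
#'   (the symmetric positive-definite covariance) and `backbone` (the lattice
#'   adjacency).
#' @export
build_group_covariance <- function(n_regions, backbone_degree = 8,
                                   rewire_prob = 0.05, edge_strength = 0.3,
                                   diagonal_load = 0.5,
                                   planted_alterations = list(),
                                   seed = 1L) {
  if (n_regions < 4) stopf("n_regions must be >= 4")
  if (edge_strength < 0) stopf("edge_strength must be >= 0")
  if (diagonal_load < 0) stopf("diagonal_load must be >= 0")
  A <- small_world_lattice(n_regions, backbone_degree, rewire_prob, seed)
  S <- diag(1 + diagonal_load, n_regions) + edge_strength * A

  for (alt in planted_alterations) {
    r <- alt$region
    if (is.null(r) || r < 1 || r > n_regions) {
      stopf("planted alteration names an invalid region id")
    }
    mode <- match.arg(alt$mode, c("strengthen", "weaken"))
    off <- setdiff(seq_len(n_regions), r)
    if (mode == "strengthen") {
      m <- alt$magnitude
      if (is.null(m) || m < 0) stopf("strengthen alteration needs magnitude >= 0")
      S[r, off] <- S[r, off] + m
      S[off, r] <- S[off, r] + m
    } else {
      S[r, off] <- 0
      S[off, r] <- 0
    }
  }

  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  min_ev <- min(ev)
  if (min_ev <= 0) {
    bump <- abs(min_ev) + 0.01
    diag(S) <- diag(S) + bump
    diagonal_load <- diagonal_load + bump
    min_ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (min_ev <= 0) stopf("internal error: covariance repair failed")
  }

  structure(list(n_regions = as.integer(n_regions),
                 backbone_degree = as.integer(backbone_degree),
                 rewire_prob = rewire_prob, edge_strength = edge_strength,
                 diagonal_load = diagonal_load,
                 planted_alterations = planted_alterations,
                 seed = as.integer(seed),
                 backbone = A, matrix = S),
            class = "covariance_spec")
}

#' @export
print.covariance_spec <- function(x, ...) {
  if (!is.null(x$communities)) {
    cat(sprintf(paste0("<covariance_spec> %d regions in %d communities ",
                       "(within cov %.3g), %d planted alteration(s)\n"),
                x$n_regions, x$n_communities, x$within_cov,
                length(x$planted_alterations)))
  } else {
    cat(sprintf(paste0("<covariance_spec> %d regions, lattice degree %d, ",
                       "rewire p = %.3g, edge strength %.3g, %d planted alteration(s)\n"),
                x$n_regions, x$backbone_degree, x$rewire_prob, x$edge_strength,
                length(x$planted_alterations)))
  }
  invisible(x)
}

#' Modular (connected-caveman) group covariance
#'
#' The cohort emulator used for the two-group study layout. Regions are
#' grouped into contiguous communities with strong within-community
#' covariance (equicorrelated blocks, the positive-definite way to obtain
#' correlations strong enough to estimate from 22 subjects), and adjacent
#' communities are tied by a small number of weaker bridge pairs — the
#' connected-caveman construction, the classic modular small-world graph:
#' high clustering inside communities, short paths through bridges.
#'
#' Planted alterations model hub pathology:
#' \describe{
#'   \item{strengthen}{The region decouples from its own community and gains
#'     covariance `magnitude` with `targets_per_community` members of every
#'     other community — it becomes a global bridge, raising its betweenness.}
#'   \item{weaken}{All off-diagonal entries incident to the region are zeroed.}
#'   \item{pair_strengthen}{The region and `target_region` both decouple from
#'     their communities and gain mutual covariance `magnitude` — a planted
#'     seed-target connectivity increase for seed-correlation analyses.}
#' }
#' After planting, positive definiteness is restored by raising only the
#' altered regions' variances to their minimal admissible value (Schur
#' complement bound) plus a small margin; a global diagonal load is the
#' fallback if the construction is still not positive definite.
#'
#' @param n_regions Number of regions (>= 8).
#' @param n_communities Number of contiguous communities (default
#'   `max(2, round(n_regions / 18))`, giving communities of about 18).
#' @param within_cov Covariance between regions of one community (default
#'   1.45; with the default diagonal 1.5 this is a within-community
#'   correlation of about 0.97, a near-redundant functional system).
#' @param diagonal_load Added to the unit diagonal (default 0.5).
#' @param bridge_frac Bridge covariance as a fraction of `within_cov`
#'   (default 0.2).
#' @param bridges_per_pair Bridge pairs between adjacent communities
#'   (default 1).
#' @param planted_alterations List of alteration entries (see above), each
#'   `list(region =, mode =, magnitude =, targets_per_community =,
#'   target_region =)` with mode-appropriate fields.
#' @param seed Integer seed controlling bridge placement and strengthen
#'   targets.
#' @return An object of class `covariance_spec` with fields `matrix`,
#'   `communities`, and the construction parameters.
#' @export
build_modular_covariance <- function(n_regions, n_communities = NULL,
                                     within_cov = 1.45, diagonal_load = 0.5,
                                     bridge_frac = 0.2, bridges_per_pair = 1,
                                     planted_alterations = list(),
                                     seed = 1L) {
  if (n_regions < 8) stopf("n_regions must be >= 8")
  if (is.null(n_communities)) n_communities <- max(2L, round(n_regions / 18))
  if (n_communities < 2 || n_communities > n_regions / 2) {
    stopf("n_communities must be in [2, n_regions/2]")
  }
  comm <- sort(rep_len(seq_len(n_communities), n_regions))
  S <- matrix(0, n_regions, n_regions)
  for (c_ in seq_len(n_communities)) {
    idx <- which(comm == c_)
    S[idx, idx] <- within_cov
  }
  diag(S) <- 1 + diagonal_load

  bridge_ends <- integer(0)
  S <- with_seed(seed, {
    for (c_ in seq_len(n_communities)) {
      c2 <- (c_ %% n_communities) + 1L
      for (b in seq_len(bridges_per_pair)) {
        i <- sample(which(comm == c_), 1L)
        j <- sample(which(comm == c2), 1L)
        S[i, j] <- S[j, i] <- bridge_frac * within_cov
        bridge_ends <- c(bridge_ends, i, j)
      }
    }
    S
  })
  # bridges perturb the thin eigen-margin of the equicorrelated blocks;
  # restore positive definiteness locally at the bridge endpoints
  for (e in unique(bridge_ends)) S <- repair_region_variance(S, e)

  altered <- integer(0)
  for (k in seq_along(planted_alterations)) {
    alt <- planted_alterations[[k]]
    r <- alt$region
    if (is.null(r) || r < 1 || r > n_regions) {
      stopf("planted alteration names an invalid region id")
    }
    mode <- match.arg(alt$mode, c("strengthen", "weaken", "pair_strengthen"))
    own <- setdiff(which(comm == comm[r]), r)
    if (mode == "weaken") {
      S[r, -r] <- 0
      S[-r, r] <- 0
    } else if (mode == "strengthen") {
      m <- alt$magnitude %||% 2.4
      tpc <- alt$targets_per_community %||% 6L
      S[r, own] <- 0
      S[own, r] <- 0
      S <- with_seed(derive_seed(seed, 1000L + k), {
        for (c_ in setdiff(seq_len(n_communities), comm[r])) {
          mem <- which(comm == c_)
          mem <- sample(mem, min(tpc, length(mem)))
          S[r, mem] <- S[r, mem] + m
          S[mem, r] <- S[mem, r] + m
        }
        S
      })
      S <- repair_region_variance(S, r)
      altered <- c(altered, r)
    } else {
      t_ <- alt$target_region
      if (is.null(t_) || t_ < 1 || t_ > n_regions || t_ == r) {
        stopf("pair_strengthen needs a distinct target_region")
      }
      m <- alt$magnitude %||% 1.45
      own_t <- setdiff(which(comm == comm[t_]), t_)
      S[r, -r] <- 0; S[-r, r] <- 0
      S[t_, -t_] <- 0; S[-t_, t_] <- 0
      S[r, t_] <- S[t_, r] <- m
      S <- repair_region_variance(S, r)
      S <- repair_region_variance(S, t_)
      altered <- c(altered, r, t_)
    }
  }

  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0.02) {
    diag(S) <- diag(S) + abs(ev) + 0.05  # global fallback load
    diagonal_load <- diagonal_load + abs(ev) + 0.05
  }

  structure(list(n_regions = as.integer(n_regions),
                 n_communities = as.integer(n_communities),
                 communities = comm, within_cov = within_cov,
                 diagonal_load = diagonal_load, bridge_frac = bridge_frac,
                 bridges_per_pair = as.integer(bridges_per_pair),
                 planted_alterations = planted_alterations,
                 altered_regions = altered,
                 seed = as.integer(seed), matrix = S),
            class = "covariance_spec")
}

# Raise region r's variance to the minimal value keeping S positive
# definite given its row (Schur complement bound), plus a small margin.
repair_region_variance <- function(S, r, margin = 0.05) {
  c_ <- S[-r, r]
  if (all(c_ == 0)) return(S)
  need <- drop(crossprod(c_, solve(S[-r, -r], c_)))
  if (S[r, r] <= need + margin) S[r, r] <- need + margin
  S
}

#' Sample one cohort of regional signals
#'
#' Draws `n_subjects` independent multivariate-normal subject rows with mean
#' 100 (positive, SUVR-like scale) and the spec's covariance.
#'
#' @param spec A [build_group_covariance()] result.
#' @param n_subjects Number of subjects (>= 4); 22 matches the emulated cohorts.
#' @param seed Integer RNG seed; draws are bit-reproducible for a fixed seed.
#' @param mean_level Common mean of all regional signals (default 100).
#' @return A [region_matrix()] of raw (unnormalized) signals.
#' @export
sample_region_matrix <- function(spec, n_subjects = 22, seed = 1L,
                                 mean_level = 100) {
  if (!inherits(spec, "covariance_spec")) stopf("spec must be a covariance_spec")
  if (n_subjects < 4) stopf("n_subjects must be >= 4")
  ev <- eigen(spec$matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stopf("spec covariance is not positive definite")
  X <- with_seed(seed, MASS::mvrnorm(n_subjects,
                                     mu = rep(mean_level, spec$n_regions),
                                     Sigma = spec$matrix))
  region_matrix(X, region_ids = seq_len(spec$n_regions))
}

#' Build a toy atlas by partitioning an ellipsoidal mask
#'
#' Creates a centred ellipsoidal "brain" mask inside the grid and partitions
#' it into `n_regions` contiguous, non-empty, mutually exclusive regions by
#' nearest-seed growth from randomly placed in-mask seed voxels (cells of a
#' convex mask are convex, hence connected). Background voxels are labelled 0.
#'
#' @param grid_shape Length-3 integer grid dimensions.
#' @param n_regions Number of regions; requires `prod(grid_shape) >= 2 * n_regions`.
#' @param seed Integer RNG seed for seed-voxel placement.
#' @param voxel_size_mm Voxel size recorded on the atlas.
#' @return An [atlas_parcellation()].
#' @export
make_toy_atlas <- function(grid_shape = c(24, 24, 24), n_regions = 90,
                           seed = 1L, voxel_size_mm = c(2, 2, 2)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 2L)) {
    stopf("grid_shape must be 3 integers >= 2")
  }
  if (prod(grid_shape) < 2 * n_regions) {
    stopf("grid too small: need prod(grid_shape) >= 2 * n_regions")
  }
  ctr <- (grid_shape + 1) / 2
  semi <- grid_shape * 0.45
  ax <- lapply(1:3, function(d) ((seq_len(grid_shape[d]) - ctr[d]) / semi[d])^2)
  # squared normalized radius over the full grid
  r2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  mask <- which(r2 <= 1)
  if (length(mask) < n_regions) stopf("grid too small for an ellipsoid of %d regions", n_regions)

  coords <- arrayInd(mask, grid_shape)
  seeds <- with_seed(seed, sort(sample(length(mask), n_regions)))
  seed_xyz <- coords[seeds, , drop = FALSE]
  # nearest seed by squared Euclidean distance; ties to the lowest seed index
  d2 <- outer(rowSums(coords^2), rowSums(seed_xyz^2), "+") -
    2 * tcrossprod(coords, seed_xyz)
  lab <- max.col(-d2, ties.method = "first")

  labels <- array(0L, grid_shape)
  labels[mask] <- lab
  atlas_parcellation(labels, voxel_size_mm = voxel_size_mm)
}

#' Render subject region values into toy volumes
#'
#' Paints each subject's regional values onto the atlas grid: every voxel of
#' region r takes that subject's region-r value plus independent Gaussian
#' noise with standard deviation `noise_sd`; background voxels are 0. This
#' lets voxel-level stages (smoothing, extraction, seed correlation) run at
#' desk scale.
#'
#' @param cohort A [region_matrix()] whose region count equals the atlas's.
#' @param atlas An [atlas_parcellation()].
#' @param noise_sd Voxel noise standard deviation (>= 0).
#' @param seed Integer RNG seed.
#' @return List of [volume_image()], one per subject.
#' @export
render_subject_volumes <- function(cohort, atlas, noise_sd = 0, seed = 1L) {
  if (!inherits(cohort, "region_matrix")) stopf("cohort must be a region_matrix")
  if (!inherits(atlas, "atlas_parcellation")) stopf("atlas must be an atlas_parcellation")
  n_reg <- length(atlas$region_ids)
  if (ncol(cohort$values) != n_reg) {
    stopf("region count mismatch: cohort has %d, atlas has %d",
          ncol(cohort$values), n_reg)
  }
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  lab <- atlas$labels
  in_mask <- lab > 0
  n_vox <- sum(in_mask)
  with_seed(seed, {
    lapply(seq_len(nrow(cohort$values)), function(s) {
      vol <- array(0, dim(lab))
      vol[in_mask] <- cohort$values[s, lab[in_mask]]
      if (noise_sd > 0) {
        vol[in_mask] <- vol[in_mask] + stats::rnorm(n_vox, sd = noise_sd)
      }
      volume_image(vol, voxel_size_mm = atlas$voxel_size_mm)
    })
  })
}

#' Simulate a pair of cohorts
#'
#' Convenience wrapper producing the two-group study layout: a shared
#' modular small-world covariance backbone (see
#' [build_modular_covariance()]), group-specific planted alterations, and
#' one [region_matrix()] per group. The backbone seed is shared between
#' groups, so without alterations the two cohorts are draws from one
#' population covariance.
#'
#' @param n_subjects Subjects per group (default 22).
#' @param n_regions Regions (default 90).
#' @param alterations_a,alterations_b Planted alteration lists per group.
#' @param seed Master integer seed.
#' @param generator `"modular"` (default, the study emulator) or
#'   `"lattice"` for the ring-lattice covariance of
#'   [build_group_covariance()].
#' @param ... Passed on to the chosen covariance builder.
#' @return List with elements `spec_a`, `spec_b`, `cohort_a`, `cohort_b`.
#' @export
simulate_cohort_pair <- function(n_subjects = 22, n_regions = 90,
                                 alterations_a = list(), alterations_b = list(),
                                 seed = 1L, generator = c("modular", "lattice"),
                                 ...) {
  generator <- match.arg(generator)
  builder <- if (generator == "modular") build_modular_covariance
             else build_group_covariance
  spec_a <- builder(n_regions, planted_alterations = alterations_a,
                    seed = derive_seed(seed, 1L), ...)
  spec_b <- builder(n_regions, planted_alterations = alterations_b,
                    seed = derive_seed(seed, 1L), ...)
  list(spec_a = spec_a, spec_b = spec_b,
       cohort_a = sample_region_matrix(spec_a, n_subjects, derive_seed(seed, 2L)),
       cohort_b = sample_region_matrix(spec_b, n_subjects, derive_seed(seed, 3L)))
}
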