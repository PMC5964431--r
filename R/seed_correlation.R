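# Seed-based voxel-wise correlation analysis: per-group Pearson r-maps from
# a seed region, Fisher r-to-z, two-sample Z comparison, and
# Benjamini-Hochberg FDR masking.

#' Voxel-wise seed correlation map for one group
#'
#' Each subject's seed value is the mean intensity over the seed region.
#' For every in-mask voxel, r is the Pearson correlation across subjects
#' between the seed values and that voxel's values. Voxels with zero
#' variance across subjects get r = 0 and are excluded from later inference
#' (recorded in the `valid` attribute).
#'
#' @param volumes List of [volume_image()] (>= 4 subjects) on the atlas grid.
#' @param atlas An [atlas_parcellation()].
#' @param seed_region_id Region id used as the seed.
#' @return Numeric 3-D array of correlations (0 outside the mask), with
#'   attribute `valid`: logical array marking testable voxels.
#' @export
seed_rmap <- function(volumes, atlas, seed_region_id) {
  if (length(volumes) < 4) stopf("need at least 4 subjects")
  if (!seed_region_id %in% atlas$region_ids) {
    stopf("seed region %d not in atlas", seed_region_id)
  }
  lab <- atlas$labels
  in_mask <- which(lab > 0)
  seed_vox <- which(lab == seed_region_id)
  if (length(seed_vox) == 0L) stopf("seed region %d is empty", seed_region_id)

  V <- vapply(volumes, function(v) {
    if (!identical(dim(v$values), dim(lab))) stopf("volume grid mismatch with atlas")
    v$values[in_mask]
  }, numeric(length(in_mask)))            # voxels x subjects
  seed_vals <- colMeans(
    vapply(volumes, function(v) v$values[seed_vox], numeric(length(seed_vox))))

  s_c <- seed_vals - mean(seed_vals)
  V_c <- V - rowMeans(V)
  num <- as.numeric(V_c %*% s_c)
  den <- sqrt(rowSums(V_c^2) * sum(s_c^2))
  valid_vox <- den > 0
  r <- numeric(length(in_mask))
  r[valid_vox] <- num[valid_vox] / den[valid_vox]
  r <- pmin(1, pmax(-1, r))

  rmap <- array(0, dim(lab))
  rmap[in_mask] <- r
  valid <- array(FALSE, dim(lab))
  valid[in_mask] <- valid_vox
  attr(rmap, "valid") <- valid
  rmap
}

#' Fisher r-to-z transform
#'
#' `z = 0.5 * log((1 + r) / (1 - r))`: the variance-stabilizing transform
#' making correlation coefficients approximately Gaussian. Odd and strictly
#' increasing on (-1, 1). Inputs at |r| >= 1 are clipped to
#' `+/-(1 - 1e-7)` with a warning.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return Transformed z value(s).
#' @export
fisher_z <- function(r) {
  clip <- abs(r) >= 1
  if (any(clip)) {
    warning(sprintf("%d correlation(s) at |r| >= 1 clipped before transform",
                    sum(clip)))
    r <- pmin(1 - 1e-7, pmax(-(1 - 1e-7), r))
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Two-sample Z comparison of Fisher-transformed correlations
#'
#' `z = (z1 - z2) / sqrt(1/(n1 - 3) + 1/(n2 - 3))`, the standard-normal
#' deviate for comparing two independent correlations after the Fisher
#' transform.
#'
#' @param z1,z2 Fisher-transformed correlations.
#' @param n1,n2 Group sizes (both > 3).
#' @return The standard-normal deviate (vectorized).
#' @export
z_compare <- function(z1, z2, n1, n2) {
  if (n1 <= 3 || n2 <= 3) stopf("both group sizes must exceed 3")
  (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up FDR over the in-mask p-values: sort ascending, find the largest k
#' with `p_(k) <= k * q / m`, and reject every p at or below that threshold.
#' An empty rejection set is allowed.
#'
#' @param p_map Numeric 3-D array of p-values.
#' @param q FDR level (default 0.05).
#' @param mask Logical array marking the m tested voxels.
#' @return Logical array: `TRUE` where rejected (always within `mask`).
#' @export
fdr_mask <- function(p_map, q = 0.05, mask) {
  if (!any(mask)) stopf("mask is empty")
  p <- p_map[mask]
  if (any(!is.finite(p) | p <= 0 | p > 1)) stopf("p-values must lie in (0, 1]")
  reject <- stats::p.adjust(p, method = "BH") <= q
  out <- array(FALSE, dim(p_map))
  out[mask] <- reject
  out
}

#' Seed-based between-group comparison
#'
#' End-to-end seed analysis: per-group r-maps from the seed region, Fisher
#' r-to-z, voxel-wise two-sample Z deviate with the two group sizes,
#' two-sided normal p, and the Benjamini-Hochberg mask at level `q`.
#' Strengthened (z > 0: group A exceeds group B) and weakened (z < 0)
#' significant voxels are reported as separate masks.
#'
#' @param volumes_a,volumes_b Lists of [volume_image()] per group (>= 4
#'   subjects each).
#' @param atlas An [atlas_parcellation()].
#' @param seed_region_id Seed region id.
#' @param q FDR level (default 0.05).
#' @return An object of class `seed_maps`: `r_map_a`, `r_map_b`, `z_map_a`,
#'   `z_map_b`, `z_diff_map`, `p_map`, `fdr_mask`, `strengthened_mask`,
#'   `weakened_mask`, `valid` (testable-voxel mask), `n_a`, `n_b`,
#'   `seed_region_id`, `q`.
#' @export
seed_group_compare <- function(volumes_a, volumes_b, atlas, seed_region_id,
                               q = 0.05) {
  r_a <- seed_rmap(volumes_a, atlas, seed_region_id)
  r_b <- seed_rmap(volumes_b, atlas, seed_region_id)
  valid <- attr(r_a, "valid") & attr(r_b, "valid")
  # the seed region correlates with itself by construction; exclude it from
  # inference so the comparison concerns the rest of the brain
  valid[atlas$labels == seed_region_id] <- FALSE

  n_a <- length(volumes_a)
  n_b <- length(volumes_b)
  z_a <- array(0, dim(r_a)); z_a[valid] <- fisher_z(r_a[valid])
  z_b <- array(0, dim(r_b)); z_b[valid] <- fisher_z(r_b[valid])
  z_diff <- array(0, dim(r_a))
  z_diff[valid] <- z_compare(z_a[valid], z_b[valid], n_a, n_b)

  p_map <- array(1, dim(r_a))
  pv <- 2 * stats::pnorm(-abs(z_diff[valid]))
  pv[pv <= 0] <- .Machine$double.xmin  # keep p in (0, 1] for the BH step
  p_map[valid] <- pv

  sig <- fdr_mask(p_map, q = q, mask = valid)
  structure(list(r_map_a = r_a, r_map_b = r_b, z_map_a = z_a, z_map_b = z_b,
                 z_diff_map = z_diff, p_map = p_map, fdr_mask = sig,
                 strengthened_mask = sig & z_diff > 0,
                 weakened_mask = sig & z_diff < 0,
                 valid = valid, n_a = n_a, n_b = n_b,
                 seed_region_id = as.integer(seed_region_id), q = q),
            class = "seed_maps")
}

#' Summarize a significance mask as connected clusters
#'
#' Labels the 6-connected components of a binary voxel mask and reports,
#' per cluster, its voxel count, peak statistic value, and peak voxel
#' coordinates — the usual tabular companion to a thresholded map.
#'
#' @param mask Logical (or 0/1) 3-D array.
#' @param values Optional numeric array of the same shape (e.g. a z map);
#'   the peak is the voxel with the largest `|values|` in the cluster.
#' @return data.frame with columns cluster_id, n_voxels, peak_x, peak_y,
#'   peak_z, peak_value, sorted by decreasing size (0 rows for an empty
#'   mask).
#' @export
mask_cluster_summary <- function(mask, values = NULL) {
  dims <- dim(mask)
  if (length(dims) != 3L) stopf("mask must be a 3-D array")
  idx <- which(mask != 0)
  if (length(idx) == 0L) {
    return(data.frame(cluster_id = integer(0), n_voxels = integer(0),
                      peak_x = integer(0), peak_y = integer(0),
                      peak_z = integer(0), peak_value = numeric(0)))
  }
  lab <- array(0L, dims)
  lab[idx] <- -1L  # unvisited mask voxel
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  next_id <- 0L
  rows <- list()
  for (start in idx) {
    if (lab[start] != -1L) next
    next_id <- next_id + 1L
    queue <- start
    lab[start] <- next_id
    members <- start
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      co <- arrayInd(v, dims)
      for (o in seq_len(6)) {
        nb <- co + offsets[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        j <- nb[1] + (nb[2] - 1L) * dims[1] + (nb[3] - 1L) * dims[1] * dims[2]
        if (lab[j] == -1L) {
          lab[j] <- next_id
          queue <- c(queue, j)
          members <- c(members, j)
        }
      }
    }
    pk <- if (is.null(values)) members[1] else members[which.max(abs(values[members]))]
    pco <- arrayInd(pk, dims)
    rows[[next_id]] <- data.frame(
      cluster_id = next_id, n_voxels = length(members),
      peak_x = pco[1], peak_y = pco[2], peak_z = pco[3],
      peak_value = if (is.null(values)) NA_real_ else values[pk])
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_voxels), ]
  out$cluster_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.seed_maps <- function(x, ...) {
  cat(sprintf(paste0("<seed_maps> seed region %d, groups n = %d / %d, ",
                     "%d tested voxels, %d significant (q = %.3g): ",
                     "%d strengthened, %d weakened\n"),
              x$seed_region_id, x$n_a, x$n_b, sum(x$valid), sum(x$fdr_mask),
              x$q, sum(x$strengthened_mask), sum(x$weakened_mask)))
  invisible(x)
}
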