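# Volumetric preprocessing and reduction of per-subject images to
# normalized regional signal vectors: smooth -> grayscale rescale ->
# region-mean extraction -> whole-brain normalization.

#' Gaussian-smooth a volume
#'
#' Separable Gaussian convolution with the kernel width given as full width
#' at half maximum (FWHM) in millimetres, the convention of PET/fMRI
#' preprocessing; per-axis sigma in voxels is
#' `fwhm / (voxel_size * sqrt(8 * log(2)))`. Boundaries are handled by edge
#' replication.
#'
#' @param img A [volume_image()].
#' @param fwhm_mm Length-3 (or scalar, recycled) positive FWHM in mm; the
#'   default 10 mm matches routine whole-brain PET smoothing.
#' @return A smoothed [volume_image()] of the same shape.
#' @export
smooth_volume <- function(img, fwhm_mm = c(10, 10, 10)) {
  if (!inherits(img, "volume_image")) stopf("img must be a volume_image")
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3L)
  if (any(fwhm_mm <= 0)) stopf("fwhm_mm must be positive")
  sigma_vox <- fwhm_mm / (img$voxel_size_mm * sqrt(8 * log(2)))
  out <- img$values
  for (axis in 1:3) {
    out <- convolve_axis(out, gaussian_kernel(sigma_vox[axis]), axis)
  }
  volume_image(out, img$voxel_size_mm, img$affine)
}

# Discretized 1-D Gaussian kernel, truncated at 4 sigma, normalized to sum 1.
gaussian_kernel <- function(sigma) {
  radius <- max(1L, ceiling(4 * sigma))
  x <- (-radius):radius
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# 1-D convolution of a 3-D array along `axis` with edge replication,
# vectorized as a weighted sum of index-shifted slabs.
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  radius <- (length(kernel) - 1L) / 2L
  # replicated-edge index lookup for each kernel offset
  out <- array(0, d)
  for (k in seq_along(kernel)) {
    offset <- k - radius - 1L
    idx <- pmin(pmax(seq_len(n) + offset, 1L), n)
    slab <- switch(axis,
                   arr[idx, , , drop = FALSE],
                   arr[, idx, , drop = FALSE],
                   arr[, , idx, drop = FALSE])
    out <- out + kernel[k] * slab
  }
  out
}

#' Rescale a volume to a grayscale range
#'
#' Linear min-max map of intensities onto `[lo, hi]` (default `[0, 255]`).
#' A constant volume maps to `lo` by convention.
#'
#' @param img A [volume_image()].
#' @param lo,hi Target range, `hi > lo`.
#' @return The rescaled [volume_image()].
#' @export
rescale_grayscale <- function(img, lo = 0, hi = 255) {
  if (!inherits(img, "volume_image")) stopf("img must be a volume_image")
  if (hi <= lo) stopf("hi must exceed lo")
  v <- img$values
  rng <- range(v)
  out <- if (rng[2] > rng[1]) {
    lo + (v - rng[1]) * (hi - lo) / (rng[2] - rng[1])
  } else {
    array(lo, dim(v))
  }
  volume_image(out, img$voxel_size_mm, img$affine)
}

#' Extract per-region mean intensities
#'
#' Entry r is the arithmetic mean of the image over voxels labelled r,
#' ordered by the atlas's region ids.
#'
#' @param img A [volume_image()] on the atlas grid.
#' @param atlas An [atlas_parcellation()].
#' @return Numeric vector of region means, one per region id.
#' @export
extract_region_means <- function(img, atlas) {
  if (!inherits(img, "volume_image")) stopf("img must be a volume_image")
  if (!inherits(atlas, "atlas_parcellation")) stopf("atlas must be an atlas_parcellation")
  if (!identical(dim(img$values), dim(atlas$labels))) {
    stopf("image grid %s does not match atlas grid %s",
          paste(dim(img$values), collapse = "x"),
          paste(dim(atlas$labels), collapse = "x"))
  }
  lab <- as.integer(atlas$labels)
  in_mask <- lab > 0L
  sums <- rowsum(as.numeric(img$values)[in_mask], lab[in_mask])
  counts <- tabulate(lab[in_mask], nbins = max(atlas$region_ids))
  if (any(counts == 0L)) {
    stopf("empty region(s): %s", paste(which(counts == 0L), collapse = ", "))
  }
  means <- as.numeric(sums[order(as.integer(rownames(sums))), 1]) / counts
  means
}

#' Whole-brain normalize one subject's region means
#'
#' Centres and scales a subject's regional signals by that subject's
#' whole-brain mean and standard deviation, yielding z-units; this removes
#' per-subject global uptake scale before covariance estimation.
#'
#' @param region_means Numeric vector of region means.
#' @param brain_mean,brain_sd The subject's whole-brain statistics
#'   (`brain_sd > 0`).
#' @return Numeric vector `(region_means - brain_mean) / brain_sd`.
#' @export
normalize_subject_signals <- function(region_means, brain_mean, brain_sd) {
  if (!is.finite(brain_sd) || brain_sd <= 0) stopf("brain_sd must be > 0")
  (region_means - brain_mean) / brain_sd
}

#' Whole-brain normalize a cohort's region matrix
#'
#' Applies [normalize_subject_signals()] row-wise. By default each subject's
#' whole-brain statistics are the mean and sd of that subject's region means
#' (`brain_stats = "regions"`); with region voxel counts supplied as
#' `weights`, voxel-level whole-brain statistics are reproduced exactly for
#' piecewise-constant volumes (`brain_stats = "voxels"` in the volume path).
#'
#' @param cohort A raw [region_matrix()].
#' @param weights Optional per-region weights (e.g. voxel counts) for the
#'   whole-brain statistics; `NULL` for unweighted.
#' @return A normalized [region_matrix()].
#' @export
normalize_region_matrix <- function(cohort, weights = NULL) {
  if (!inherits(cohort, "region_matrix")) stopf("cohort must be a region_matrix")
  if (cohort$normalized) return(cohort)
  X <- cohort$values
  out <- t(vapply(seq_len(nrow(X)), function(s) {
    x <- X[s, ]
    if (is.null(weights)) {
      m <- mean(x)
      sd_ <- sqrt(mean((x - m)^2))
    } else {
      w <- weights / sum(weights)
      m <- sum(w * x)
      sd_ <- sqrt(sum(w * (x - m)^2))
    }
    normalize_subject_signals(x, m, sd_)
  }, numeric(ncol(X))))
  region_matrix(out, cohort$subject_ids, cohort$region_ids, normalized = TRUE)
}

#' Reduce subject volumes to a normalized region matrix
#'
#' The full reduction used ahead of network construction: optional Gaussian
#' smoothing, optional grayscale rescaling, region-mean extraction, and
#' per-subject whole-brain normalization.
#'
#' @param volumes List of [volume_image()], one per subject.
#' @param atlas An [atlas_parcellation()].
#' @param fwhm_mm Smoothing FWHM in mm, or `NULL` to skip smoothing.
#' @param grayscale Logical: rescale each subject to `[lo, hi]` first.
#' @param lo,hi Grayscale range (defaults 0 and 255).
#' @param brain_stats `"regions"` (default) normalizes by the mean/sd of the
#'   subject's region means; `"voxels"` uses that subject's in-mask voxel
#'   mean/sd.
#' @param normalize Logical; set `FALSE` to return raw region means.
#' @param reference_region Optional region id; each subject's region means
#'   are divided by that region's mean first (SUVR-style referencing, e.g.
#'   to a cerebellar region). The later z-normalization is invariant to this
#'   per-subject scale, so the flag matters mainly for raw outputs.
#' @param subject_ids Optional subject identifiers.
#' @return A [region_matrix()].
#' @export
volumes_to_region_matrix <- function(volumes, atlas, fwhm_mm = NULL,
                                     grayscale = FALSE, lo = 0, hi = 255,
                                     brain_stats = c("regions", "voxels"),
                                     normalize = TRUE, reference_region = NULL,
                                     subject_ids = NULL) {
  brain_stats <- match.arg(brain_stats)
  if (!is.null(reference_region) &&
      !reference_region %in% atlas$region_ids) {
    stopf("reference_region %s is not an atlas region", reference_region)
  }
  in_mask <- atlas$labels > 0
  rows <- lapply(volumes, function(v) {
    if (!is.null(fwhm_mm)) v <- smooth_volume(v, fwhm_mm)
    if (grayscale) v <- rescale_grayscale(v, lo, hi)
    means <- extract_region_means(v, atlas)
    if (!is.null(reference_region)) {
      ref <- means[reference_region]
      if (!is.finite(ref) || ref == 0) {
        stopf("reference region %d has non-positive mean", reference_region)
      }
      means <- means / ref
      v$values <- v$values / ref  # keep voxel stats consistent with means
    }
    if (!normalize) return(means)
    if (brain_stats == "voxels") {
      vox <- v$values[in_mask]
      m <- mean(vox)
      sd_ <- sqrt(mean((vox - m)^2))
    } else {
      m <- mean(means)
      sd_ <- sqrt(mean((means - m)^2))
    }
    normalize_subject_signals(means, m, sd_)
  })
  region_matrix(do.call(rbind, rows), subject_ids = subject_ids,
                region_ids = atlas$region_ids, normalized = normalize)
}

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti keeping the package's containers at the API
#' surface.
#'
#' @param img A [volume_image()] (or [atlas_parcellation()] for
#'   `write_atlas_nifti`).
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @return Readers return the package container; writers return `path`
#'   invisibly.
#' @export
write_volume_nifti <- function(img, path) {
  nii <- RNifti::asNifti(img$values)
  RNifti::pixdim(nii) <- img$voxel_size_mm
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(nii)[1:3]
  volume_image(array(as.numeric(nii), dim(nii)[1:3]), voxel_size_mm = vox)
}

#' @rdname write_volume_nifti
#' @param atlas An [atlas_parcellation()].
#' @export
write_atlas_nifti <- function(atlas, path) {
  nii <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(nii) <- atlas$voxel_size_mm
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_atlas_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(nii)[1:3]
  lab <- array(as.integer(round(as.numeric(nii))), dim(nii)[1:3])
  atlas_parcellation(lab, voxel_size_mm = vox)
}
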