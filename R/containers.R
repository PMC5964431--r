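#' Volumetric image container
#'
#' A minimal 3-D image carrier: a numeric intensity grid plus voxel size and a
#' voxel-to-world affine. This is the in-memory form of one subject's PET
#' volume after conversion to a common atlas space.
#'
#' @param values Numeric 3-D array of intensities.
#' @param voxel_size_mm Length-3 positive numeric, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world transform. Defaults to a diagonal scaling
#'   by `voxel_size_mm`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, voxel_size_mm = c(2, 2, 2), affine = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L || length(values) == 0L) {
    stopf("values must be a non-empty 3-D array")
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stopf("voxel_size_mm must be 3 positive values")
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  structure(list(values = values, voxel_size_mm = voxel_size_mm, affine = affine),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_image> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' Atlas parcellation container
#'
#' Integer-labelled volume assigning every voxel to a region (1..N) or to
#' background (0), in the manner of the 90-region AAL parcellation.
#'
#' @param labels Integer 3-D array; 0 marks background.
#' @param region_names Optional character vector of region names, one per
#'   region id; defaults to `"region_<id>"`.
#' @param voxel_size_mm Length-3 positive numeric.
#' @return An object of class `atlas_parcellation` with fields `labels`,
#'   `region_ids`, `region_names`, `voxel_size_mm`.
#' @export
atlas_parcellation <- function(labels, region_names = NULL, voxel_size_mm = c(2, 2, 2)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stopf("labels must be a 3-D array")
  }
  if (any(labels < 0) || any(labels != round(labels))) {
    stopf("labels must be nonnegative integers")
  }
  ids <- sort(unique(as.integer(labels[labels > 0])))
  if (length(ids) == 0L) stopf("atlas contains no labelled voxels")
  if (!identical(ids, seq_len(max(ids)))) {
    stopf("region labels must be contiguous 1..N (found gaps)")
  }
  if (is.null(region_names)) region_names <- paste0("region_", ids)
  if (length(region_names) != length(ids)) {
    stopf("region_names must have one entry per region")
  }
  structure(list(labels = labels, region_ids = ids, region_names = region_names,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "atlas_parcellation")
}

#' @export
print.atlas_parcellation <- function(x, ...) {
  cat(sprintf("<atlas_parcellation> %d regions over %s grid (%d in-mask voxels)\n",
              length(x$region_ids), paste(dim(x$labels), collapse = "x"),
              sum(x$labels > 0)))
  invisible(x)
}

#' Subjects-by-regions signal matrix
#'
#' One cohort's regional signal table: rows are subjects, columns are atlas
#' regions. Signals may be raw (SUVR-like) or per-subject normalized to
#' z-units.
#'
#' @param values Numeric matrix, subjects x regions, no missing entries.
#' @param subject_ids Optional character vector of row identifiers.
#' @param region_ids Optional integer vector of column region ids.
#' @param normalized Logical flag: have rows been whole-brain normalized?
#' @return An object of class `region_matrix`.
#' @export
region_matrix <- function(values, subject_ids = NULL, region_ids = NULL,
                          normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stopf("region matrix must not contain missing values")
  if (is.null(subject_ids)) subject_ids <- paste0("subj_", seq_len(nrow(values)))
  if (is.null(region_ids)) region_ids <- seq_len(ncol(values))
  if (length(subject_ids) != nrow(values)) stopf("subject_ids length mismatch")
  if (length(region_ids) != ncol(values)) stopf("region_ids length mismatch")
  rownames(values) <- subject_ids
  structure(list(values = values, subject_ids = subject_ids,
                 region_ids = as.integer(region_ids),
                 normalized = isTRUE(normalized)),
            class = "region_matrix")
}

#' @export
print.region_matrix <- function(x, ...) {
  cat(sprintf("<region_matrix> %d subjects x %d regions (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized z-units" else "raw signal units"))
  invisible(x)
}

#' @export
dim.region_matrix <- function(x) dim(x$values)

#' Write / read a region matrix as TSV
#'
#' Plain-text interchange: one row per subject, `subject_id` key column, one
#' column per region named `r<id>`.
#'
#' @param x A [region_matrix()].
#' @param path Output file path.
#' @return `write_region_matrix` returns `path` invisibly;
#'   `read_region_matrix` returns a [region_matrix()].
#' @export
write_region_matrix <- function(x, path) {
  df <- data.frame(subject_id = x$subject_ids, x$values,
                   check.names = FALSE, row.names = NULL)
  names(df) <- c("subject_id", paste0("r", x$region_ids))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_region_matrix
#' @param normalized Flag recorded on the object read back.
#' @export
read_region_matrix <- function(path, normalized = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!"subject_id" %in% names(df)) stopf("TSV must carry a subject_id column")
  ids <- as.integer(sub("^r", "", setdiff(names(df), "subject_id")))
  region_matrix(as.matrix(df[setdiff(names(df), "subject_id")]),
                subject_ids = as.character(df$subject_id),
                region_ids = ids, normalized = normalized)
}
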