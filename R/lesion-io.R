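#' Binary lesion mask (VOI) for one sample
#'
#' Wraps a 3-D binary array of lesioned voxels together with its grid and
#' sample id. Masks are binary by construction (tumor volumes of interest
#' delineated on post-contrast T1 images); values other than 0/1 are only
#' produced upstream by interpolation and are thresholded on read.
#'
#' @param voxels 3-D array coercible to 0/1.
#' @param grid a [volume_grid()] matching `dim(voxels)`.
#' @param sample_id sample identifier.
#' @return An object of class `lesion_mask` with elements `sample_id`,
#'   `grid` and `voxels` (integer 0/1 array).
#' @export
lesion_mask <- function(voxels, grid, sample_id = "sample") {
  stopifnot(inherits(grid, "volume_grid"))
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array")
  if (!identical(as.integer(dim(voxels)), grid$shape))
    stop("mask dimensions do not match the grid shape")
  v <- array(as.integer(voxels != 0), dim = grid$shape)
  structure(list(sample_id = as.character(sample_id)[1L],
                 grid = grid, voxels = v),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("lesion_mask '%s': %d lesioned voxels on %s grid\n",
              x$sample_id, sum(x$voxels), paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' @rdname lesion_mask
#' @param mask a `lesion_mask`.
#' @return `mask_volume()` returns the lesioned voxel count.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask$voxels)
}

#' Read and write lesion masks as NIfTI
#'
#' `read_mask()` ingests a NIfTI-1/2 volume, binarizes it at 0.5 and attaches
#' the grid read from the header (sform/qform). An empty volume is readable
#' but flagged: a valid tumor VOI has at least one lesioned voxel, and cohort
#' assembly rejects empty masks. When `expected_grid` is given, a geometry
#' mismatch beyond tolerance is an error -- resampling is never silent; call
#' [resample_to_grid()] explicitly.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @param expected_grid optional [volume_grid()] the mask must already be on.
#' @param strict if `TRUE`, refuse inputs whose values are not exactly
#'   \{0, 1\} (VOIs are binary by construction; probability maps must be
#'   thresholded deliberately with `strict = FALSE`).
#' @param space frame label to record when the header carries none.
#' @return A [lesion_mask()]; attribute `empty` is `TRUE` for all-zero input.
#' @export
read_mask <- function(path, expected_grid = NULL, strict = FALSE,
                      space = "unknown") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) {
    img <- array(as.numeric(img), dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop(sprintf("'%s' is %d-D; lesion masks must be 3-D volumes",
                 path, length(d)))
  aff <- unname(unclass(RNifti::xform(img)))
  attributes(aff) <- list(dim = c(4L, 4L))
  grid <- volume_grid(d, aff, space = space)
  vals <- as.numeric(img)
  if (strict && !all(vals %in% c(0, 1)))
    stop(sprintf("'%s' is not binary and strict mode is on", path))
  vox <- array(as.integer(vals > 0.5), dim = d)
  if (!is.null(expected_grid) && !grids_equal(grid, expected_grid))
    stop(sprintf(paste0("grid of '%s' does not match the expected grid; ",
                        "call resample_to_grid() explicitly"), path))
  m <- lesion_mask(vox, grid, sample_id = sub("\\.nii(\\.gz)?$", "",
                                              basename(path)))
  attr(m, "empty") <- sum(vox) == 0L
  m
}

#' @rdname read_mask
#' @param mask a [lesion_mask()] (or, for `write_volume()`, any numeric array).
#' @return `write_mask()` invisibly returns `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  write_volume(mask$voxels, mask$grid, path, datatype = "uint8")
}

#' @rdname read_mask
#' @param x 3-D numeric array on `grid`.
#' @param grid the [volume_grid()] supplying the affine.
#' @param datatype NIfTI on-disk type, e.g. `"uint8"` or `"float"`.
#' @export
write_volume <- function(x, grid, path, datatype = "float") {
  stopifnot(inherits(grid, "volume_grid"))
  x <- array(as.numeric(x), dim = grid$shape)
  img <- RNifti::asNifti(x, datatype = datatype)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Nearest-neighbour resampling of a mask onto a target grid
#'
#' Pulls every target voxel back through the composed world transform
#' (target affine, then the inverse source affine), rounds to the nearest
#' source voxel and copies its value; voxels falling outside the source
#' field of view are 0. Binary input therefore stays binary. This is
#' deliberate plumbing for grids already registered to a common template --
#' it is not a spatial normalization.
#'
#' @param mask a [lesion_mask()].
#' @param grid target [volume_grid()].
#' @return A [lesion_mask()] on `grid`.
#' @export
resample_to_grid <- function(mask, grid) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(grid, "volume_grid"))
  if (grids_equal(mask$grid, grid)) {
    out <- mask
    out$grid <- grid
    return(out)
  }
  # 0-based target ijk -> world -> 0-based source ijk
  comp <- solve(mask$grid$affine) %*% grid$affine
  nvox <- prod(grid$shape)
  tgt <- linear_to_ijk0(seq_len(nvox), grid$shape)
  src <- cbind(tgt, 1) %*% t(comp)
  si <- as.integer(round(src[, 1L]))
  sj <- as.integer(round(src[, 2L]))
  sk <- as.integer(round(src[, 3L]))
  inside <- si >= 0L & si < mask$grid$shape[1L] &
    sj >= 0L & sj < mask$grid$shape[2L] &
    sk >= 0L & sk < mask$grid$shape[3L]
  vals <- integer(nvox)
  lin <- 1L + si[inside] +
    mask$grid$shape[1L] * (sj[inside] + mask$grid$shape[2L] * sk[inside])
  vals[inside] <- mask$voxels[lin]
  lesion_mask(array(vals, dim = grid$shape), grid, mask$sample_id)
}

#' Aligned cohort of lesion masks
#'
#' Stacks per-sample binary masks that share one template grid. Empty masks
#' are rejected: every included sample has a tumor. Internally the cohort
#' keeps a samples x voxels logical matrix so voxel-wise statistics stay
#' vectorized.
#'
#' @param masks list of [lesion_mask()] objects on a common grid.
#' @return An object of class `lesion_cohort` with elements `grid`,
#'   `sample_ids` and `mat` (n_samples x n_voxels logical matrix; voxels in
#'   array order).
#' @export
lesion_cohort <- function(masks) {
  if (length(masks) == 0L) stop("cohort must contain at least one mask")
  stopifnot(all(vapply(masks, inherits, logical(1), "lesion_mask")))
  grid <- masks[[1L]]$grid
  for (m in masks) {
    if (!grids_equal(m$grid, grid))
      stop(sprintf("mask '%s' is not on the cohort grid; resample explicitly",
                   m$sample_id))
    if (sum(m$voxels) == 0L)
      stop(sprintf("mask '%s' is empty; every cohort sample must have a tumor",
                   m$sample_id))
  }
  ids <- vapply(masks, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids in cohort")
  mat <- do.call(rbind, lapply(masks, function(m) as.logical(m$voxels)))
  rownames(mat) <- ids
  structure(list(grid = grid, sample_ids = ids, mat = mat),
            class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat(sprintf("lesion_cohort: %d samples on %s grid (space '%s')\n",
              length(x$sample_ids), paste(x$grid$shape, collapse = "x"),
              x$grid$space))
  invisible(x)
}

#' @rdname lesion_cohort
#' @param cohort a `lesion_cohort`.
#' @param i sample index or id.
#' @return `cohort_mask()` rebuilds the i-th sample as a [lesion_mask()].
#' @export
cohort_mask <- function(cohort, i) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  if (is.character(i)) i <- match(i, cohort$sample_ids)
  if (is.na(i) || i < 1L || i > length(cohort$sample_ids))
    stop("unknown sample")
  lesion_mask(array(as.integer(cohort$mat[i, ]), dim = cohort$grid$shape),
              cohort$grid, cohort$sample_ids[i])
}

#' @rdname lesion_cohort
#' @param keep_ids character vector of sample ids to retain (must all exist;
#'   an empty selection is an error because cohorts cannot be empty).
#' @export
subset_cohort <- function(cohort, keep_ids) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  keep_ids <- as.character(keep_ids)
  missing <- setdiff(keep_ids, cohort$sample_ids)
  if (length(missing))
    stop("unknown sample ids: ", paste(missing, collapse = ", "))
  keep <- cohort$sample_ids %in% keep_ids   # order-preserving
  if (!any(keep)) stop("subset would be empty")
  structure(list(grid = cohort$grid,
                 sample_ids = cohort$sample_ids[keep],
                 mat = cohort$mat[keep, , drop = FALSE]),
            class = "lesion_cohort")
}

#' Lesion overlay frequency map
#'
#' Counts, at every voxel, how many cohort masks are lesioned there -- the
#' overlap map conventionally displayed on a template to show a cohort's
#' topographic predilection.
#'
#' @param cohort a [lesion_cohort()].
#' @return An object of class `overlay_map`: `grid`, `counts` (3-D integer
#'   array) and `n_samples`.
#' @export
build_overlay <- function(cohort) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  counts <- array(as.integer(colSums(cohort$mat)), dim = cohort$grid$shape)
  structure(list(grid = cohort$grid, counts = counts,
                 n_samples = length(cohort$sample_ids)),
            class = "overlay_map")
}

#' @export
print.overlay_map <- function(x, ...) {
  cat(sprintf("overlay_map: %d samples, max overlap %d\n",
              x$n_samples, max(x$counts)))
  invisible(x)
}

#' Read a cohort from a manifest
#'
#' The manifest is a CSV/TSV with columns `sample_id` and `mask_path`
#' (relative paths resolved against the manifest's directory). All masks must
#' share one grid; mismatches are errors, never silent resamples.
#'
#' @param manifest path to the manifest file.
#' @param strict passed to [read_mask()].
#' @return A [lesion_cohort()].
#' @export
read_cohort <- function(manifest, strict = FALSE) {
  sep <- if (grepl("\\.tsv$", manifest)) "\t" else ","
  tab <- utils::read.table(manifest, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "mask_path") %in% names(tab)))
    stop("manifest needs columns 'sample_id' and 'mask_path'")
  base <- dirname(manifest)
  masks <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$mask_path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    m <- read_mask(p, strict = strict)
    m$sample_id <- as.character(tab$sample_id[i])
    m
  })
  lesion_cohort(masks)
}
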