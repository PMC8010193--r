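#' Template grid geometry
#'
#' A `volume_grid` records the voxel lattice a cohort of lesion masks lives
#' on: the array shape, the 4x4 voxel-to-world affine (mm) and a free-text
#' label for the stereotactic frame (e.g. `"MNI152"`). Voxel indices are
#' 0-based when passed through the affine; R arrays remain 1-based, and the
#' conversion happens inside [voxel_to_world()].
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param affine 4x4 invertible voxel-to-world transform in mm. Defaults to
#'   identity spacing with the origin at voxel (0,0,0).
#' @param space free-text label for the coordinate frame.
#' @return An object of class `volume_grid`.
#' @export
#' @examples
#' g <- volume_grid(c(48, 56, 48), space = "MNI152")
#' voxel_to_world(g, c(0, 0, 0))
volume_grid <- function(shape, affine = diag(4), space = "unknown") {
  shape <- as.integer(shape)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L))
    stop("'shape' must be three integers >= 1")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || anyNA(affine))
    stop("'affine' must be a numeric 4x4 matrix")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps * 1e4)
    stop("'affine' must be invertible")
  structure(list(shape = shape, affine = unname(affine),
                 space = as.character(space)[1L]),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s voxels, space '%s'\n",
              paste(x$shape, collapse = " x "), x$space))
  invisible(x)
}

#' @rdname volume_grid
#' @param a,b grids to compare.
#' @param tol per-element affine tolerance in mm.
#' @return `grids_equal()` returns a logical scalar.
#' @export
grids_equal <- function(a, b, tol = 1e-4) {
  stopifnot(inherits(a, "volume_grid"), inherits(b, "volume_grid"))
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) <= tol)
}

#' @rdname volume_grid
#' @param grid a `volume_grid`.
#' @param ijk0 numeric matrix (n x 3) or vector of 0-based voxel indices.
#' @return `voxel_to_world()` returns an n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(grid, ijk0) {
  stopifnot(inherits(grid, "volume_grid"))
  ijk0 <- matrix(as.numeric(ijk0), ncol = 3L)
  xyz1 <- cbind(ijk0, 1) %*% t(grid$affine)
  xyz1[, 1:3, drop = FALSE]
}

# 1-based array index -> 0-based (i,j,k) triples for a grid shape
linear_to_ijk0 <- function(idx, shape) {
  idx0 <- as.integer(idx) - 1L
  i <- idx0 %% shape[1L]
  j <- (idx0 %/% shape[1L]) %% shape[2L]
  k <- idx0 %/% (shape[1L] * shape[2L])
  cbind(i = i, j = j, k = k)
}
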