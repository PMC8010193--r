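neighbour_offsets <- function(connectivity = 26L) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  man <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = man == 1,
                 "18" = man >= 1 & man <= 2,
                 "26" = man >= 1,
                 stop("'connectivity' must be 6, 18 or 26"))
  off[keep, , drop = FALSE]
}

# Label connected components of a 3-D logical mask. Builds the adjacency
# graph over foreground voxels and takes igraph components; returns an
# integer array (0 = background, 1..k = component labels, relabelled later
# by extract_clusters).
label_components <- function(mask, connectivity = 26L) {
  mask <- as.array(mask)
  shape <- dim(mask)
  stopifnot(length(shape) == 3L)
  lab <- array(0L, dim = shape)
  fg <- which(mask != 0)
  if (length(fg) == 0L) return(lab)
  pos <- linear_to_ijk0(fg, shape)
  vid <- integer(prod(shape))
  vid[fg] <- seq_along(fg)
  off <- neighbour_offsets(connectivity)
  edges <- vector("list", nrow(off))
  for (r in seq_len(nrow(off))) {
    ni <- pos[, 1L] + off[r, 1L]
    nj <- pos[, 2L] + off[r, 2L]
    nk <- pos[, 3L] + off[r, 3L]
    ok <- ni >= 0L & ni < shape[1L] & nj >= 0L & nj < shape[2L] &
      nk >= 0L & nk < shape[3L]
    nlin <- 1L + ni[ok] + shape[1L] * (nj[ok] + shape[2L] * nk[ok])
    hit <- vid[nlin] > 0L
    edges[[r]] <- cbind(which(ok)[hit], vid[nlin][hit])
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(matrix(as.numeric(el), ncol = 2L),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[fg] <- as.integer(comp)
  lab
}

#' Extract connected clusters from a significance mask
#'
#' Labels connected components of the significant-voxel mask and summarizes
#' each: voxel count, peak z and 1-based peak voxel index. Clusters are
#' ordered by voxel count descending, ties broken by higher peak z, then by
#' lowest linear peak index; `label` is the rank in that order.
#'
#' @param sig_mask 3-D logical/0-1 array.
#' @param z_map 3-D numeric array of signed z-values (may hold NA outside
#'   the analyzed region).
#' @param connectivity 6, 18 or 26.
#' @return data.frame with columns `label`, `n_voxels`, `peak_z`, `peak_i`,
#'   `peak_j`, `peak_k`; zero rows for an empty mask.
#' @export
extract_clusters <- function(sig_mask, z_map = NULL, connectivity = 26L) {
  sig_mask <- as.array(sig_mask)
  shape <- dim(sig_mask)
  if (is.null(z_map)) z_map <- array(0, dim = shape)
  lab <- label_components(sig_mask, connectivity)
  ids <- sort(unique(lab[lab > 0L]))
  empty <- data.frame(label = integer(), n_voxels = integer(),
                      peak_z = numeric(), peak_i = integer(),
                      peak_j = integer(), peak_k = integer())
  if (length(ids) == 0L) return(empty)
  rows <- lapply(ids, function(id) {
    vox <- which(lab == id)
    zz <- z_map[vox]
    zz[is.na(zz)] <- -Inf
    peak <- vox[which.max(zz)]  # which.max takes the lowest index on ties
    ijk <- linear_to_ijk0(peak, shape) + 1L
    data.frame(n_voxels = length(vox), peak_z = z_map[peak],
               peak_i = ijk[1L], peak_j = ijk[2L], peak_k = ijk[3L],
               peak_lin = peak)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$n_voxels, -out$peak_z, out$peak_lin)
  out <- out[ord, , drop = FALSE]
  out$label <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("label", "n_voxels", "peak_z", "peak_i", "peak_j", "peak_k")]
}

#' Dice overlap coefficient between two binary volumes
#'
#' 2|A intersect B| / (|A| + |B|); defined as `NaN` when both volumes are
#' empty. Used to score a recovered significant region against a known
#' simulated truth.
#'
#' @param a,b arrays of identical shape, coerced to logical.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("volumes differ in size")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NaN)
  2 * sum(a & b) / denom
}
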