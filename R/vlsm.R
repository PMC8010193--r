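#' 2x2 lesion-by-label contingency table
#'
#' Cell layout at one voxel (or for one region report): `a` = lesioned and
#' label-positive, `b` = lesioned and label-negative, `c` = intact and
#' label-positive, `d` = intact and label-negative.
#'
#' @param a,b,c,d non-negative integer counts, `a+b+c+d > 0`.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d))
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if (sum(cells) == 0) stop("empty table")
  cells <- stats::setNames(as.integer(round(cells)), c("a", "b", "c", "d"))
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("lesioned", "intact"),
                              c("label+", "label-")))
  print(m)
  invisible(x)
}

#' VLSM run configuration
#'
#' Defaults reproduce the conventional settings for subtype mapping: voxels
#' analyzed only where more than 5% of the cohort is lesioned, one-sided
#' testing in the positive direction, FDR control at q = 0.05, 26-neighbour
#' cluster connectivity.
#'
#' @param min_lesion_fraction coverage filter; a voxel is analyzed iff the
#'   lesioned fraction is strictly greater than this (in (0,1)).
#' @param fdr_q false discovery rate level (in (0,1)).
#' @param direction `"positive"` tests lesion association with the positive
#'   label, `"negative"` with its complement.
#' @param connectivity 6, 18 or 26 neighbour cluster connectivity.
#' @param fdr_method `"BH"` (Benjamini-Hochberg, default) or `"BY"`
#'   (Benjamini-Yekutieli) step-up constant.
#' @return An object of class `vlsm_config`.
#' @export
vlsm_config <- function(min_lesion_fraction = 0.05, fdr_q = 0.05,
                        direction = c("positive", "negative"),
                        connectivity = 26, fdr_method = c("BH", "BY")) {
  if (!is.numeric(min_lesion_fraction) || min_lesion_fraction <= 0 ||
      min_lesion_fraction >= 1)
    stop("'min_lesion_fraction' must lie in (0, 1)")
  if (!is.numeric(fdr_q) || fdr_q <= 0 || fdr_q >= 1)
    stop("'fdr_q' must lie in (0, 1)")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("'connectivity' must be 6, 18 or 26")
  structure(list(min_lesion_fraction = min_lesion_fraction, fdr_q = fdr_q,
                 direction = match.arg(direction),
                 connectivity = connectivity,
                 fdr_method = match.arg(fdr_method)),
            class = "vlsm_config")
}

#' Voxel coverage filter
#'
#' Marks the voxels on which the voxel-wise test is computed: those lesioned
#' in strictly more than `min_lesion_fraction` of the cohort. With 125
#' samples and the default 0.05, voxels hit by 7+ lesions are kept
#' (6/125 = 4.8% is excluded, 7/125 = 5.6% kept).
#'
#' @param cohort a [lesion_cohort()].
#' @param min_lesion_fraction strict lower bound on the lesioned fraction.
#' @return 3-D logical array on the cohort grid.
#' @export
voxel_coverage_mask <- function(cohort, min_lesion_fraction = 0.05) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  if (min_lesion_fraction <= 0 || min_lesion_fraction >= 1)
    stop("'min_lesion_fraction' must lie in (0, 1)")
  n <- length(cohort$sample_ids)
  counts <- colSums(cohort$mat)
  array(counts / n > min_lesion_fraction, dim = cohort$grid$shape)
}

#' Contingency table at one voxel
#'
#' @param cohort a [lesion_cohort()].
#' @param labels logical (or 0/1) vector aligned with the cohort's samples;
#'   `TRUE` = label-positive.
#' @param voxel integer triple, 1-based array index.
#' @return A [contingency_table()].
#' @export
voxel_table <- function(cohort, labels, voxel) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  labels <- check_labels(labels, length(cohort$sample_ids))
  voxel <- as.integer(voxel)
  if (length(voxel) != 3L || any(voxel < 1L) ||
      any(voxel > cohort$grid$shape))
    stop("'voxel' out of bounds")
  lin <- voxel[1L] + cohort$grid$shape[1L] *
    ((voxel[2L] - 1L) + cohort$grid$shape[2L] * (voxel[3L] - 1L))
  les <- cohort$mat[, lin]
  contingency_table(sum(les & labels), sum(les & !labels),
                    sum(!les & labels), sum(!les & !labels))
}

check_labels <- function(labels, n) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels))
    stop("'labels' must be logical or 0/1, not character")
  if (length(labels) != n)
    stop(sprintf("'labels' has length %d but the cohort has %d samples",
                 length(labels), n))
  if (anyNA(labels)) stop("'labels' contains NA")
  if (is.numeric(labels) && !all(labels %in% c(0, 1)))
    stop("numeric 'labels' must be 0/1")
  as.logical(labels)
}

#' Liebermeister quasi-exact test for a 2x2 table
#'
#' The Liebermeister measure augments the concordant cells by one and
#' evaluates a hypergeometric tail on the augmented table: for the positive
#' direction the table becomes (a+1, b; c, d+1) and the p-value is
#' P(X >= a+1) where X is hypergeometric with population n+2, first-column
#' margin a+c+1 and first-row draws a+b+1. The negative direction augments
#' (a, b+1; c+1, d) and returns P(X <= a). The test is quasi-exact and less
#' conservative than Fisher's exact test on the unaugmented table.
#'
#' All arguments are vectorized over cells.
#'
#' @param a,b,c,d cell counts as in [contingency_table()], or pass a
#'   `contingency_table` as `a`.
#' @param direction `"positive"` or `"negative"`.
#' @return One-sided p-value(s) in (0, 1].
#' @export
#' @examples
#' liebermeister_p(3, 1, 1, 3)          # 26/252
#' liebermeister_p(5, 0, 0, 5)          # 1/choose(12, 6)
liebermeister_p <- function(a, b = NULL, c = NULL, d = NULL,
                            direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (inherits(a, "contingency_table")) {
    tab <- a; a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  }
  if (anyNA(c(a, b, c, d)) || any(c(a, b, c, d) < 0))
    stop("cell counts must be non-negative")
  # augmented margins are identical for both directions:
  # white = label-positive column a+c+1, draws = lesioned row a+b+1
  k <- a + c + 1
  m <- a + b + 1
  nn <- b + d + 1
  if (direction == "positive")
    stats::phyper(a, k, nn, m, lower.tail = FALSE)
  else
    stats::phyper(a, k, nn, m, lower.tail = TRUE)
}

#' Convert one-sided p-values to signed z-scores
#'
#' Maps p through the upper-tail standard normal quantile,
#' `z = qnorm(1 - p) * direction_sign`. Underflowing p (0 or 1) is clamped at
#' |z| = 8 with a warning so maps stay storable in finite-precision volumes.
#'
#' @param p p-values in \[0, 1\].
#' @param direction_sign +1 or -1.
#' @return Signed z-values, |z| <= 8.
#' @export
p_to_z <- function(p, direction_sign = 1) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  z <- stats::qnorm(p, lower.tail = FALSE)
  if (any(!is.finite(z) & !is.na(z)))
    warning("p-values of 0 or 1 clamped at |z| = 8")
  z <- pmin(pmax(z, -8), 8)
  z * direction_sign
}

#' Benjamini-Hochberg step-up p-value threshold
#'
#' Sorts the p-values ascending and returns the largest p(k) with
#' p(k) <= k*q/m (Benjamini-Hochberg), or `NA` when no rank qualifies. The
#' `"BY"` method divides q by the harmonic sum for dependence robustness.
#'
#' @param pvals non-empty numeric vector of p-values in (0, 1\].
#' @param q FDR level.
#' @param method `"BH"` or `"BY"`.
#' @return The p-value threshold, or `NA_real_` if nothing passes.
#' @export
#' @examples
#' bh_fdr_threshold(c(0.001, 0.2, 0.9), 0.05)   # 0.001
#' bh_fdr_threshold(c(0.01, 0.02, 0.03), 0.05)  # 0.03
bh_fdr_threshold <- function(pvals, q = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(pvals) == 0L) stop("'pvals' is empty")
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(pvals)
  ps <- sort(pvals)
  qk <- if (method == "BH") q else q / sum(1 / seq_len(m))
  ok <- which(ps <= seq_len(m) * qk / m)
  if (length(ok) == 0L) return(NA_real_)
  ps[max(ok)]
}

#' Run a voxel-based lesion-symptom mapping analysis
#'
#' Applies the coverage filter, computes the Liebermeister p and signed z at
#' every analyzed voxel, controls the FDR across analyzed voxels only, and
#' extracts connected clusters of significant voxels. Deterministic for
#' fixed input and invariant to sample order.
#'
#' @param cohort a [lesion_cohort()].
#' @param labels per-sample binary labels (logical or 0/1), `TRUE` for the
#'   subtype under study; both classes need at least two samples.
#' @param config a [vlsm_config()].
#' @return An object of class `vlsm_result`: `grid`, `analyzed_mask`
#'   (logical array), `p_map` and `z_map` (NaN / NA outside the analyzed
#'   mask), `fdr_p_threshold` (NA if no voxel survives), `sig_mask` (logical
#'   array), `clusters` (data.frame: `label`, `n_voxels`, `peak_z`,
#'   `peak_i/j/k` 1-based), `n_analyzed`, and the `config` and label margins
#'   used.
#' @export
run_vlsm <- function(cohort, labels, config = vlsm_config()) {
  stopifnot(inherits(cohort, "lesion_cohort"), inherits(config, "vlsm_config"))
  labels <- check_labels(labels, length(cohort$sample_ids))
  n <- length(labels)
  n_pos <- sum(labels)
  if (n_pos < 2L || n - n_pos < 2L)
    stop("both label classes need at least two samples")

  counts <- colSums(cohort$mat)
  analyzed <- counts / n > config$min_lesion_fraction
  if (!any(analyzed)) stop("no voxel passes the coverage filter")
  idx <- which(analyzed)

  a <- colSums(cohort$mat[labels, idx, drop = FALSE])
  lesioned <- counts[idx]
  b <- lesioned - a
  cc <- n_pos - a
  dd <- (n - n_pos) - b
  p <- liebermeister_p(a, b, cc, dd, direction = config$direction)
  sign <- if (config$direction == "positive") 1 else -1
  z <- suppressWarnings(p_to_z(p, sign))

  thr <- bh_fdr_threshold(p, config$fdr_q, method = config$fdr_method)
  sig <- !is.na(thr) & p <= thr

  shape <- cohort$grid$shape
  p_map <- array(NA_real_, dim = shape); p_map[idx] <- p
  z_map <- array(NA_real_, dim = shape); z_map[idx] <- z
  analyzed_mask <- array(FALSE, dim = shape); analyzed_mask[idx] <- TRUE
  sig_mask <- array(FALSE, dim = shape); sig_mask[idx[sig]] <- TRUE

  clusters <- extract_clusters(sig_mask, z_map, config$connectivity)

  structure(list(grid = cohort$grid, analyzed_mask = analyzed_mask,
                 p_map = p_map, z_map = z_map,
                 fdr_p_threshold = thr, sig_mask = sig_mask,
                 clusters = clusters, n_analyzed = length(idx),
                 n_pos = n_pos, n_neg = n - n_pos, config = config),
            class = "vlsm_result")
}

#' @export
print.vlsm_result <- function(x, ...) {
  cat(sprintf(paste0("vlsm_result: %d voxels analyzed (%d+/%d- samples), ",
                     "%d significant in %d cluster(s) at q = %g (%s)\n"),
              x$n_analyzed, x$n_pos, x$n_neg, sum(x$sig_mask),
              nrow(x$clusters), x$config$fdr_q, x$config$fdr_method))
  if (!is.na(x$fdr_p_threshold))
    cat(sprintf("  FDR p-threshold: %.3g\n", x$fdr_p_threshold))
  invisible(x)
}

#' Write VLSM maps and cluster table to disk
#'
#' Emits `z_map.nii.gz`, `p_map.nii.gz`, `sig_mask.nii.gz` (uint8) and
#' `clusters.csv` (with peak world coordinates) into `dir`.
#'
#' @param result a [run_vlsm()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_vlsm_result <- function(result, dir) {
  stopifnot(inherits(result, "vlsm_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(z = file.path(dir, "z_map.nii.gz"),
             p = file.path(dir, "p_map.nii.gz"),
             sig = file.path(dir, "sig_mask.nii.gz"),
             clusters = file.path(dir, "clusters.csv"))
  z <- result$z_map; z[is.na(z)] <- 0
  p <- result$p_map; p[is.na(p)] <- 1
  write_volume(z, result$grid, paths[["z"]])
  write_volume(p, result$grid, paths[["p"]])
  write_volume(result$sig_mask, result$grid, paths[["sig"]],
               datatype = "uint8")
  cl <- result$clusters
  if (nrow(cl)) {
    w <- voxel_to_world(result$grid,
                        cbind(cl$peak_i, cl$peak_j, cl$peak_k) - 1L)
    cl$peak_x_mm <- w[, 1L]; cl$peak_y_mm <- w[, 2L]; cl$peak_z_mm <- w[, 3L]
  }
  utils::write.csv(cl, paths[["clusters"]], row.names = FALSE)
  invisible(paths)
}
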