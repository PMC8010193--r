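#' Simulation configuration for coupled radiogenomic cohorts
#'
#' Defaults mirror the cohort structure the pipeline is designed for: 52
#' label-positive (proneural) and 73 label-negative (mesenchymal) samples on
#' a 48 x 56 x 48 template grid, a planted spherical hotspot that attracts
#' positive-class lesions with probability `hotspot_attraction`, survival
#' hazard doubled for tumors missing the hotspot, and a 2000-gene expression
#' matrix with a 141-gene EMT set of which 16 genes are shifted up (by
#' `effect_sd` standard deviations) in out-of-region samples, alongside
#' immune/stromal signature shifts and two depleted immune-cell marker sets.
#'
#' @param grid_shape voxel grid dimensions.
#' @param n_pos,n_neg samples in the positive/negative label class.
#' @param lesion_radius_range per-axis ellipsoid semi-axis range (voxels).
#' @param hotspot_center 1-based voxel coordinates of the planted region's
#'   center (default: left-hemisphere, inferior-posterior quadrant).
#' @param hotspot_radius hotspot sphere radius (voxels).
#' @param hotspot_attraction probability that a positive-class lesion
#'   centers inside the hotspot.
#' @param exclude_neg_from_hotspot if `TRUE`, negative-class lesion centers
#'   are rejected from the hotspot (a pure spatial separation, useful for
#'   construction tests).
#' @param hazard_out_ratio hazard ratio for samples whose tumor misses the
#'   hotspot (default 2).
#' @param median_os_days median overall survival of in-region samples.
#' @param censor_rate per-sample probability of censoring.
#' @param n_genes,emt_set_size,n_planted_up,n_planted_down expression layout.
#' @param effect_sd shift (in SD units) of planted EMT genes in
#'   out-of-region samples.
#' @param immune_shift,stromal_shift per-gene shift of the immune/stromal
#'   signature sets in out-of-region samples.
#' @param celltype_shift depletion of the two designated immune-cell marker
#'   sets (CD8, follicular helper T) in out-of-region samples.
#' @param n_celltypes number of immune-cell marker sets.
#' @param seed integer master seed; every stage derives its own stream.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(grid_shape = c(48L, 56L, 48L),
                       n_pos = 52L, n_neg = 73L,
                       lesion_radius_range = c(3, 6),
                       hotspot_center = c(15, 20, 17),
                       hotspot_radius = 7,
                       hotspot_attraction = 0.7,
                       exclude_neg_from_hotspot = FALSE,
                       hazard_out_ratio = 2,
                       median_os_days = 400,
                       censor_rate = 0.2,
                       n_genes = 2000L, emt_set_size = 141L,
                       n_planted_up = 16L, n_planted_down = 0L,
                       effect_sd = 1,
                       immune_shift = 0.5, stromal_shift = 0.5,
                       celltype_shift = 0.5, n_celltypes = 22L,
                       seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape), n_pos = as.integer(n_pos),
              n_neg = as.integer(n_neg),
              lesion_radius_range = as.numeric(lesion_radius_range),
              hotspot_center = as.numeric(hotspot_center),
              hotspot_radius = as.numeric(hotspot_radius),
              hotspot_attraction = as.numeric(hotspot_attraction),
              exclude_neg_from_hotspot = isTRUE(exclude_neg_from_hotspot),
              hazard_out_ratio = as.numeric(hazard_out_ratio),
              median_os_days = as.numeric(median_os_days),
              censor_rate = as.numeric(censor_rate),
              n_genes = as.integer(n_genes),
              emt_set_size = as.integer(emt_set_size),
              n_planted_up = as.integer(n_planted_up),
              n_planted_down = as.integer(n_planted_down),
              effect_sd = as.numeric(effect_sd),
              immune_shift = as.numeric(immune_shift),
              stromal_shift = as.numeric(stromal_shift),
              celltype_shift = as.numeric(celltype_shift),
              n_celltypes = as.integer(n_celltypes),
              seed = as.integer(seed))
  if (cfg$n_pos + cfg$n_neg < 4L) stop("need at least 4 samples")
  if (cfg$hotspot_attraction < 0 || cfg$hotspot_attraction > 1)
    stop("'hotspot_attraction' must lie in [0, 1]")
  if (cfg$effect_sd < 0) stop("'effect_sd' must be >= 0")
  if (any(cfg$hotspot_center - cfg$hotspot_radius < 1) ||
      any(cfg$hotspot_center + cfg$hotspot_radius > cfg$grid_shape))
    stop("hotspot does not fit inside the grid")
  if (cfg$n_planted_up + cfg$n_planted_down > cfg$emt_set_size)
    stop("planted genes exceed the EMT set size")
  if (cfg$emt_set_size + 160L + 10L * cfg$n_celltypes > cfg$n_genes)
    stop("gene sets do not fit in 'n_genes'")
  structure(cfg, class = "sim_config")
}

# distance^2 of every voxel to a center, on a grid shape (1-based coords)
.dist2_grid <- function(shape, center, scale = c(1, 1, 1)) {
  di <- ((seq_len(shape[1L]) - center[1L]) / scale[1L])^2
  dj <- ((seq_len(shape[2L]) - center[2L]) / scale[2L])^2
  dk <- ((seq_len(shape[3L]) - center[3L]) / scale[3L])^2
  outer(outer(di, dj, "+"), dk, "+")
}

.sphere_mask <- function(shape, center, radius) {
  .dist2_grid(shape, center) <= radius^2
}

.ellipsoid_mask <- function(shape, center, radii) {
  .dist2_grid(shape, center, scale = radii) <= 1
}

#' Simulate a coupled imaging + clinical + expression cohort
#'
#' Generates, from one master seed, (1) ellipsoidal binary lesion masks
#' whose centers are attracted to a planted hotspot for the positive class,
#' (2) exponential survival times whose hazard is multiplied by
#' `hazard_out_ratio` when the tumor misses the hotspot, with independent
#' censoring at the configured rate, (3) a standard-normal expression matrix
#' with planted EMT / immune / stromal / cell-type shifts in out-of-region
#' samples, and (4) a clinical/VASARI table with duplicate-rater codes. The
#' ground truth of every planted effect is returned alongside.
#'
#' Each stage draws from its own seed derived from `config$seed`, so the
#' lesion, survival, expression and clinical streams are individually
#' reproducible.
#'
#' @param config a [sim_config()].
#' @return An object of class `synthetic_cohort`: `lesions`
#'   ([lesion_cohort()]), `samples` (clinical data.frame), `expression`
#'   (genes x samples matrix), `gene_sets` (named list: `EMT`,
#'   `immune_signature`, `stromal_signature`, and cell-type marker sets),
#'   `truth` (list: `hotspot` logical array, `in_area` logical per sample,
#'   `labels` logical per sample, `planted_up`/`planted_down` gene ids,
#'   `hazard_out_ratio`, `depleted_celltypes`), and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  shape <- config$grid_shape
  n <- config$n_pos + config$n_neg
  ids <- sprintf("S%03d", seq_len(n))
  labels <- c(rep(TRUE, config$n_pos), rep(FALSE, config$n_neg))
  grid <- volume_grid(shape, affine = diag(c(4, 4, 4, 1)), space = "template")
  hotspot <- .sphere_mask(shape, config$hotspot_center, config$hotspot_radius)

  ## --- lesions ------------------------------------------------------------
  set.seed(config$seed)
  brain_center <- (shape + 1) / 2
  brain_radii <- 0.42 * shape
  draw_center <- function(in_hotspot) {
    repeat {
      if (in_hotspot) {
        u <- stats::runif(3, -1, 1)
        if (sum(u^2) > 1) next
        ctr <- config$hotspot_center + u * config$hotspot_radius
      } else {
        ctr <- brain_center + stats::runif(3, -1, 1) * brain_radii
        if (sum(((ctr - brain_center) / brain_radii)^2) > 1) next
        if (config$exclude_neg_from_hotspot && !in_hotspot &&
            sum((ctr - config$hotspot_center)^2) <= config$hotspot_radius^2)
          next
      }
      return(ctr)
    }
  }
  masks <- vector("list", n)
  for (s in seq_len(n)) {
    inside <- labels[s] && stats::runif(1) < config$hotspot_attraction
    repeat {
      ctr <- draw_center(inside)
      radii <- stats::runif(3, config$lesion_radius_range[1L],
                            config$lesion_radius_range[2L])
      vox <- .ellipsoid_mask(shape, ctr, radii)
      if (sum(vox) > 0L) break
    }
    masks[[s]] <- lesion_mask(vox, grid, ids[s])
  }
  lesions <- lesion_cohort(masks)

  in_area <- as.logical(lesions$mat %*% as.logical(hotspot) >= 1)

  ## --- survival -----------------------------------------------------------
  set.seed(config$seed + 1L)
  h0 <- log(2) / config$median_os_days
  hz <- h0 * ifelse(in_area, 1, config$hazard_out_ratio)
  t_event <- stats::rexp(n, rate = hz)
  cr <- min(max(config$censor_rate, 0), 0.99)
  if (cr > 0) {
    t_cens <- stats::rexp(n, rate = hz * cr / (1 - cr))
    event <- as.integer(t_event <= t_cens)
    os <- pmax(pmin(t_event, t_cens), 1)
  } else {
    event <- rep(1L, n)
    os <- pmax(t_event, 1)
  }

  ## --- expression ---------------------------------------------------------
  set.seed(config$seed + 2L)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  expr <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n,
                 dimnames = list(genes, ids))
  pool <- sample(genes)
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  emt <- take(config$emt_set_size)
  immune <- take(80L)
  stromal <- take(80L)
  ct_names <- c("T_cells_CD8", "T_cells_follicular_helper",
                sprintf("cell_type_%02d", seq_len(max(0L, config$n_celltypes - 2L))))
  ct_sets <- stats::setNames(lapply(seq_len(config$n_celltypes),
                                    function(i) take(10L)), ct_names)
  planted_up <- emt[seq_len(config$n_planted_up)]
  planted_down <- if (config$n_planted_down > 0L)
    emt[config$n_planted_up + seq_len(config$n_planted_down)] else character()
  out_cols <- which(!in_area)
  if (length(out_cols)) {
    expr[planted_up, out_cols] <- expr[planted_up, out_cols] + config$effect_sd
    if (length(planted_down))
      expr[planted_down, out_cols] <- expr[planted_down, out_cols] -
        config$effect_sd
    expr[immune, out_cols] <- expr[immune, out_cols] + config$immune_shift
    expr[stromal, out_cols] <- expr[stromal, out_cols] + config$stromal_shift
    depleted <- ct_names[1:2]
    for (ct in depleted)
      expr[ct_sets[[ct]], out_cols] <- expr[ct_sets[[ct]], out_cols] -
        config$celltype_shift
  }

  ## --- clinical / VASARI --------------------------------------------------
  set.seed(config$seed + 3L)
  age <- round(stats::rnorm(n, mean = 55 + 4 * (!in_area), sd = 10))
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4))
  kps <- sample(c(60, 70, 80, 90, 100), n, replace = TRUE,
                prob = c(0.1, 0.15, 0.45, 0.2, 0.1))
  mgmt <- stats::rbinom(n, 1, 0.4)
  resection <- stats::rbinom(n, 1, 0.91)
  radiation <- stats::rbinom(n, 1, 0.84)
  pharmaceutical <- stats::rbinom(n, 1, 0.81)
  f1 <- sample(c(1:5), n, replace = TRUE, prob = c(0.2, 0.45, 0.1, 0.15, 0.1))
  multilobe <- stats::rbinom(n, 1, 0.55)
  f5 <- sample(2:8, n, replace = TRUE,
               prob = c(0.02, 0.03, 0.1, 0.15, 0.2, 0.4, 0.1))
  flip <- function(x, opts, rate = 0.03) {
    do_flip <- stats::runif(n) < rate
    x[do_flip] <- sample(opts, sum(do_flip), replace = TRUE)
    x
  }
  # laterality from the mask: which half of the i axis holds the tumor
  mid <- shape[1L] / 2
  side <- vapply(seq_len(n), function(s) {
    vox <- which(lesions$mat[s, ])
    i <- linear_to_ijk0(vox, shape)[, 1L] + 1L
    left <- any(i <= mid); right <- any(i > mid)
    if (left && right) "bilateral" else if (left) "left" else "right"
  }, character(1))
  samples <- data.frame(
    sample_id = ids,
    subtype = ifelse(labels, "proneural", "mesenchymal"),
    os_days = round(os), event = event,
    age = age, sex = sex, kps = kps, mgmt = mgmt,
    resection = resection, radiation = radiation,
    pharmaceutical = pharmaceutical,
    vasari_f1 = f1, vasari_f5 = f5,
    rater2_f1 = flip(f1, 1:5), rater2_f5 = flip(f5, 2:8),
    multilobe_temporal = multilobe, side = side,
    stringsAsFactors = FALSE)

  structure(list(
    lesions = lesions, samples = samples, expression = expr,
    gene_sets = c(list(EMT = emt, immune_signature = immune,
                       stromal_signature = stromal), ct_sets),
    truth = list(hotspot = hotspot, in_area = in_area, labels = labels,
                 planted_up = planted_up, planted_down = planted_down,
                 hazard_out_ratio = config$hazard_out_ratio,
                 depleted_celltypes = ct_names[1:2]),
    config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d+/%d- samples, %d genes, ",
                     "%d in-region (truth), seed %d\n"),
              x$config$n_pos, x$config$n_neg, x$config$n_genes,
              sum(x$truth$in_area), x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits per-sample NIfTI masks plus `manifest.csv`, `samples.csv`,
#' `expression.tsv`, `gene_sets.gmt` and `truth.json` (hotspot stored as
#' linear voxel indices with the grid shape) into `out_dir`, so the cohort
#' round-trips through the package's own readers.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  ids <- cohort$lesions$sample_ids
  mask_paths <- file.path("masks", paste0(ids, ".nii.gz"))
  for (i in seq_along(ids))
    write_mask(cohort_mask(cohort$lesions, i),
               file.path(out_dir, mask_paths[i]))
  manifest <- file.path(out_dir, "manifest.csv")
  utils::write.csv(data.frame(sample_id = ids, mask_path = mask_paths),
                   manifest, row.names = FALSE)
  samples <- file.path(out_dir, "samples.csv")
  utils::write.csv(cohort$samples, samples, row.names = FALSE)
  expr <- file.path(out_dir, "expression.tsv")
  utils::write.table(data.frame(gene = rownames(cohort$expression),
                                cohort$expression, check.names = FALSE),
                     expr, sep = "\t", row.names = FALSE, quote = FALSE)
  gmt <- file.path(out_dir, "gene_sets.gmt")
  write_gmt(cohort$gene_sets, gmt)
  truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(grid_shape = cohort$config$grid_shape,
         hotspot_voxels = which(cohort$truth$hotspot),
         in_area = stats::setNames(as.list(cohort$truth$in_area), ids),
         planted_up = cohort$truth$planted_up,
         planted_down = cohort$truth$planted_down,
         hazard_out_ratio = cohort$truth$hazard_out_ratio,
         depleted_celltypes = cohort$truth$depleted_celltypes),
    truth, auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, samples = samples, expression = expr,
                 gene_sets = gmt, truth = truth))
}
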