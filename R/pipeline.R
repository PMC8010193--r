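#' Sample inclusion flow
#'
#' Applies the standard inclusion criteria in order -- availability of the
#' post-contrast image (a lesion mask), of clinical data, and of a subtype
#' call -- reporting the count excluded at each step and the final included
#' id set (the intersection, order-preserving over `all_ids`).
#'
#' @param all_ids every candidate sample id.
#' @param image_ids ids with a usable lesion mask.
#' @param clinical_ids ids with clinical data.
#' @param subtype_ids ids with a subtype label.
#' @return list with `included` (character vector) and `excluded` (named
#'   integer vector of per-criterion exclusion counts, applied in order).
#' @export
exclusion_flow <- function(all_ids, image_ids, clinical_ids, subtype_ids) {
  all_ids <- as.character(all_ids)
  step1 <- all_ids[all_ids %in% image_ids]
  step2 <- step1[step1 %in% clinical_ids]
  step3 <- step2[step2 %in% subtype_ids]
  list(included = step3,
       excluded = c(missing_image = length(all_ids) - length(step1),
                    missing_clinical = length(step1) - length(step2),
                    missing_subtype = length(step2) - length(step3)))
}

#' Run the full lesion-symptom mapping analysis
#'
#' Orchestrates the whole pipeline on either a simulated cohort (pass a
#' [sim_config()]) or on-disk inputs (manifest + samples + expression +
#' gene-set paths): overlay maps (total and per label class), one VLSM run
#' per direction (positive class, then its complement), region membership
#' against the positive-direction significant region, contingency and
#' location reports, survival comparison (all classified samples, and the
#' treatment/VASARI-filtered subset), expression scoring (EMT, purity
#' proxy, cell types) and per-gene differential expression with the top-k
#' report. All tabular/JSON artifacts are written under `out_dir`; the
#' bundle is also returned. Identical config and seed give identical
#' outputs.
#'
#' @param input a [sim_config()] or a list with elements `manifest`,
#'   `samples`, `expression`, `gene_sets` (file paths). Exactly one form.
#' @param out_dir output directory; `NULL` computes everything in memory.
#' @param vlsm a [vlsm_config()] for the positive-direction run.
#' @param positive_subtype the subtype treated as label-positive.
#' @param negative_subtype the complementary subtype; other subtypes are
#'   dropped before mapping.
#' @param min_overlap_voxels membership rule threshold.
#' @param emt_set,immune_set,stromal_set names of the gene sets to score.
#' @param top_k size of the top differential-gene report.
#' @return An object of class `vlsm_bundle` (a list of every stage result).
#' @export
run_pipeline <- function(input, out_dir = NULL, vlsm = vlsm_config(),
                         positive_subtype = "proneural",
                         negative_subtype = "mesenchymal",
                         min_overlap_voxels = 1,
                         emt_set = "EMT", immune_set = "immune_signature",
                         stromal_set = "stromal_signature", top_k = 10) {
  if (inherits(input, "sim_config")) {
    sim <- simulate_cohort(input)
    lesions <- sim$lesions; samples <- sim$samples
    expr <- sim$expression; sets <- sim$gene_sets
    truth <- sim$truth
  } else if (is.list(input) &&
             all(c("manifest", "samples", "expression", "gene_sets") %in%
                 names(input))) {
    if (inherits(input, "sim_config"))
      stop("provide either a sim_config or input paths, not both")
    lesions <- read_cohort(input$manifest)
    samples <- read_samples(input$samples)
    expr <- read_expression(input$expression)
    sets <- read_gmt(input$gene_sets)
    truth <- NULL
  } else stop("'input' must be a sim_config or a list of input paths")

  flow <- exclusion_flow(samples$sample_id,
                         lesions$sample_ids,
                         samples$sample_id[!is.na(samples$os_days)],
                         samples$sample_id[!is.na(samples$subtype)])
  samples <- samples[samples$sample_id %in% flow$included, , drop = FALSE]

  overlay_all <- build_overlay(lesions)

  keep <- samples$sample_id[samples$subtype %in%
                              c(positive_subtype, negative_subtype)]
  cohort <- subset_cohort(lesions, keep)
  sub <- samples[match(cohort$sample_ids, samples$sample_id), , drop = FALSE]
  labels <- sub$subtype == positive_subtype

  overlay_pos <- build_overlay(subset_cohort(cohort, cohort$sample_ids[labels]))
  overlay_neg <- build_overlay(subset_cohort(cohort, cohort$sample_ids[!labels]))

  map_pos <- run_vlsm(cohort, labels, vlsm)
  map_neg <- run_vlsm(cohort, !labels, vlsm)

  membership <- classify_membership(cohort, map_pos$sig_mask,
                                    min_overlap_voxels = min_overlap_voxels)
  cont <- contingency_report(membership, labels)
  cont_test <- if (all(cont$margins[c("in_total", "out_total",
                                      "pos_total", "neg_total")] > 0))
    chi2_test(contingency_table(cont$cells["a"], cont$cells["b"],
                                cont$cells["c"], cont$cells["d"])) else NULL
  location <- location_summary(samples)

  kappa <- NULL
  if (all(c("rater2_f1", "rater2_f5") %in% names(sub))) {
    kf1 <- cohen_kappa(sub$vasari_f1, sub$rater2_f1)
    kf5 <- cohen_kappa(sub$vasari_f5, sub$rater2_f5)
    kappa <- list(f1 = list(kappa = kf1, grade = kappa_grade(kf1)),
                  f5 = list(kappa = kf5, grade = kappa_grade(kf5)))
  }

  surv_all <- compare_survival(membership, sub)
  treated <- sub$sample_id[
    (!("resection" %in% names(sub)) | sub$resection %in% 1) &
      (!("radiation" %in% names(sub)) | sub$radiation %in% 1) &
      (!("pharmaceutical" %in% names(sub)) | sub$pharmaceutical %in% 1)]
  filtered_ids <- intersect(treated, vasari_filter(sub))
  surv_filtered <- if (length(filtered_ids) >= 4)
    compare_survival(membership, sub, subset = filtered_ids) else NULL

  expr_cols <- intersect(colnames(expr), cohort$sample_ids)
  scores <- NULL; diffexp <- NULL; topk <- NULL; group_tests <- NULL
  if (length(expr_cols) >= 4) {
    e <- expr[, cohort$sample_ids, drop = FALSE]
    in_area <- membership$in_area
    emt_scores <- ssgsea_score(e, sets[[emt_set]])
    purity <- purity_proxy(e, sets[[immune_set]], sets[[stromal_set]])
    ct <- celltype_scores(e, sets[setdiff(names(sets),
                                          c(emt_set, immune_set, stromal_set))])
    scores <- list(emt = emt_scores, purity = purity, celltypes = ct)
    group_tests <- list(
      emt = diff_by_group(emt_scores, in_area),
      purity = diff_by_group(purity, in_area),
      celltypes = lapply(seq_len(nrow(ct$scores)), function(i)
        diff_by_group(ct$scores[i, ], in_area)))
    names(group_tests$celltypes) <- rownames(ct$scores)
    diffexp <- diff_expression(e[sets[[emt_set]][sets[[emt_set]] %in%
                                                   rownames(e)], , drop = FALSE],
                               in_area)
    topk <- rank_diff_genes(diffexp, k = top_k)
  }

  bundle <- structure(list(
    flow = flow, overlay = overlay_all,
    overlay_positive = overlay_pos, overlay_negative = overlay_neg,
    vlsm_positive = map_pos, vlsm_negative = map_neg,
    membership = membership, labels = labels,
    contingency = cont, contingency_test = cont_test,
    location = location, kappa = kappa,
    survival_all = surv_all, survival_filtered = surv_filtered,
    survival_filter_n = length(filtered_ids),
    scores = scores, group_tests = group_tests,
    diff_expression = diffexp, top_genes = topk,
    truth = truth), class = "vlsm_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.vlsm_bundle <- function(x, ...) {
  cat("vlsm_bundle\n")
  cat(sprintf("  included samples: %d (mapped: %d)\n",
              length(x$flow$included), nrow(x$membership)))
  cat(sprintf("  significant voxels (positive run): %d in %d cluster(s)\n",
              sum(x$vlsm_positive$sig_mask), nrow(x$vlsm_positive$clusters)))
  cat(sprintf("  in-area samples: %d of %d\n",
              sum(x$membership$in_area), nrow(x$membership)))
  if (!is.null(x$survival_all$test))
    cat(sprintf("  log-rank (all mapped): chisq = %.2f, p = %.3g\n",
                x$survival_all$test$chisq, x$survival_all$test$p))
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- bundle$overlay$grid
  write_volume(bundle$overlay$counts, g,
               file.path(out_dir, "overlay_total.nii.gz"))
  write_volume(bundle$overlay_positive$counts, g,
               file.path(out_dir, "overlay_positive.nii.gz"))
  write_volume(bundle$overlay_negative$counts, g,
               file.path(out_dir, "overlay_negative.nii.gz"))
  write_vlsm_result(bundle$vlsm_positive, file.path(out_dir, "vlsm_positive"))
  write_vlsm_result(bundle$vlsm_negative, file.path(out_dir, "vlsm_negative"))
  utils::write.csv(bundle$membership,
                   file.path(out_dir, "membership.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(cells = as.list(bundle$contingency$cells),
         margins = as.list(bundle$contingency$margins),
         row_percent = as.list(bundle$contingency$row_percent),
         col_percent = as.list(bundle$contingency$col_percent),
         odds_ratio = bundle$contingency$odds_ratio,
         chi2 = bundle$contingency_test,
         kappa = bundle$kappa),
    file.path(out_dir, "reports.json"), auto_unbox = TRUE, digits = NA)
  surv <- list(all = bundle$survival_all$test,
               filtered = if (!is.null(bundle$survival_filtered))
                 bundle$survival_filtered$test,
               filtered_n = bundle$survival_filter_n)
  jsonlite::write_json(surv, file.path(out_dir, "survival.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$diff_expression)) {
    utils::write.csv(bundle$diff_expression,
                     file.path(out_dir, "diff_expression.csv"),
                     row.names = FALSE)
    jsonlite::write_json(bundle$top_genes,
                         file.path(out_dir, "top_genes.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}
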