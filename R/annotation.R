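#' Read a per-sample clinical/VASARI table
#'
#' Expects a CSV/TSV with a `sample_id` column; conventional columns are
#' `subtype` (proneural/mesenchymal/neural/classical), `os_days`, `event`,
#' `age`, `sex`, `kps`, `mgmt`, treatment flags (`resection`, `radiation`,
#' `pharmaceutical`), the VASARI codes `vasari_f1` (location of the lesion
#' epicenter, 0-7) and `vasari_f5` (proportion enhancing, 0-9), the lobe
#' annotations `multilobe_temporal` (0/1) and `side`
#' (left/right/bilateral), and optional second-rater duplicates
#' `rater2_f1`, `rater2_f5`. Missing values stay `NA`.
#'
#' @param path file path.
#' @return data.frame with unique `sample_id`s.
#' @export
read_samples <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"sample_id" %in% names(tab)) stop("samples table needs 'sample_id'")
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids")
  if ("os_days" %in% names(tab) && any(tab$os_days < 0, na.rm = TRUE))
    stop("'os_days' must be non-negative")
  tab
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the chance term
#' from the raters' marginal frequencies. When both raters are constant and
#' identical the statistic is undefined (p_e = 1); it is reported as 1 with
#' a warning since agreement is perfect.
#'
#' @param ratings_a,ratings_b equal-length categorical vectors (length >= 2).
#' @return Kappa in \[-1, 1\].
#' @export
#' @examples
#' cohen_kappa(rep(c("x", "y"), 25), rep(c("x", "y"), 25))  # 1
cohen_kappa <- function(ratings_a, ratings_b) {
  ratings_a <- as.character(ratings_a)
  ratings_b <- as.character(ratings_b)
  if (length(ratings_a) != length(ratings_b))
    stop("rating vectors differ in length")
  if (length(ratings_a) < 2L) stop("need at least two rated items")
  if (anyNA(ratings_a) || anyNA(ratings_b)) stop("ratings contain NA")
  lev <- sort(unique(c(ratings_a, ratings_b)))
  ta <- factor(ratings_a, levels = lev)
  tb <- factor(ratings_b, levels = lev)
  n <- length(ta)
  p_o <- mean(ta == tb)
  p_e <- sum((table(ta) / n) * (table(tb) / n))
  if (p_e >= 1 - .Machine$double.eps * 8) {
    warning("both raters constant and identical; kappa undefined, reported as 1")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Grade inter-rater agreement from kappa
#'
#' Thresholds: kappa > 0.8 is `"excellent"`, 0.6 <= kappa <= 0.8 is
#' `"good"`, kappa < 0.6 is `"poor"` (both boundaries of the middle band
#' inclusive except 0.8, which the strict reading of ">0.8 excellent"
#' assigns to `"good"`).
#'
#' @param kappa value(s) in \[-1, 1\].
#' @return Character vector of grades.
#' @export
kappa_grade <- function(kappa) {
  if (any(kappa < -1 | kappa > 1, na.rm = TRUE))
    stop("kappa must lie in [-1, 1]")
  ifelse(kappa > 0.8, "excellent", ifelse(kappa >= 0.6, "good", "poor"))
}

#' Inter-observer VOI volume discrepancy rule
#'
#' Two observers' tumor volumes are flagged for recheck when the relative
#' volume difference over the smaller volume exceeds 0.05.
#'
#' @param volume_a,volume_b positive voxel counts.
#' @param tol discrepancy threshold (default 0.05).
#' @return `"accept"` or `"recheck"` (vectorized).
#' @export
voi_discrepancy <- function(volume_a, volume_b, tol = 0.05) {
  if (any(volume_a <= 0 | volume_b <= 0)) stop("volumes must be positive")
  ratio <- abs(volume_a - volume_b) / pmin(volume_a, volume_b)
  ifelse(ratio > tol, "recheck", "accept")
}

#' Filter samples by VASARI enhancement and location codes
#'
#' Keeps samples whose F5 (proportion-enhancing) code is at least
#' `min_f5_code` -- the default 7 encodes ">95%", the striking-enhancement
#' cut-off -- and, when `require_temporal`, whose tumor involves the temporal
#' lobe (F1 epicenter code 2, or `multilobe_temporal == 1`). Codes 8
#' ("all, 100%") and 9 ("indeterminate") are distinct: 9 never passes.
#' Samples with missing codes are excluded and counted.
#'
#' @param samples data.frame as from [read_samples()].
#' @param require_temporal require temporal-lobe involvement.
#' @param min_f5_code minimum F5 code (default 7).
#' @return Character vector of kept sample ids; attribute `excluded` holds
#'   counts by reason.
#' @export
vasari_filter <- function(samples, require_temporal = TRUE, min_f5_code = 7) {
  f5 <- samples$vasari_f5
  ok_f5 <- !is.na(f5) & f5 >= min_f5_code & f5 != 9
  if (require_temporal) {
    f1 <- samples$vasari_f1
    multi <- if ("multilobe_temporal" %in% names(samples))
      samples$multilobe_temporal %in% 1 else FALSE
    ok_loc <- (!is.na(f1) & f1 == 2) | multi
  } else ok_loc <- rep(TRUE, nrow(samples))
  keep <- ok_f5 & ok_loc
  out <- samples$sample_id[keep]
  attr(out, "excluded") <- c(missing_or_low_f5 = sum(!ok_f5),
                             non_temporal = sum(ok_f5 & !ok_loc))
  out
}

#' Classify samples as in or outside a determined area
#'
#' A sample is "in the area" when its tumor mask overlaps the significant
#' region by at least `min_overlap_voxels` (default 1, the most permissive
#' reading). The overlap fraction of the tumor volume is recorded so
#' stricter rules (e.g. >= 10% of the tumor) can be applied downstream.
#'
#' @param cohort a [lesion_cohort()].
#' @param region 3-D logical/0-1 array on the cohort grid (e.g. the
#'   `sig_mask` of a [run_vlsm()] result).
#' @param min_overlap_voxels minimum overlapping voxel count.
#' @return data.frame: `sample_id`, `in_area`, `overlap_voxels`,
#'   `overlap_fraction`.
#' @export
classify_membership <- function(cohort, region, min_overlap_voxels = 1) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  region <- as.array(region)
  if (!identical(as.integer(dim(region)), cohort$grid$shape))
    stop("region is not on the cohort grid")
  rvec <- as.logical(region)
  overlap <- as.integer(cohort$mat %*% rvec)
  vol <- rowSums(cohort$mat)
  data.frame(sample_id = cohort$sample_ids,
             in_area = overlap >= min_overlap_voxels,
             overlap_voxels = overlap,
             overlap_fraction = overlap / vol,
             stringsAsFactors = FALSE)
}

#' Region-by-subtype contingency report
#'
#' Builds the 2x2 in/outside-area by label table with margins, the eight
#' row/column percentages (rounded to integers, matching the convention of
#' narrative reporting) and the odds ratio.
#'
#' `x` is either a [contingency_table()] (a = in-area label-positive, b =
#' in-area label-negative, c = out label-positive, d = out label-negative)
#' or the data.frame from [classify_membership()] together with `labels`.
#'
#' @param x contingency table or membership data.frame.
#' @param labels per-sample binary labels aligned with `x`'s rows (only for
#'   the membership form).
#' @return An object of class `contingency_report`: `cells`, `margins`
#'   (`in_total`, `out_total`, `pos_total`, `neg_total`, `n`),
#'   `row_percent` and `col_percent` (integer-rounded), `odds_ratio`.
#' @export
#' @examples
#' rep <- contingency_report(contingency_table(22, 11, 30, 62))
#' rep$margins["in_total"]      # 33
#' rep$row_percent["a"]         # 67
contingency_report <- function(x, labels = NULL) {
  if (inherits(x, "contingency_table")) {
    a <- x$a; b <- x$b; cc <- x$c; dd <- x$d
  } else {
    if (is.null(labels)) stop("membership form needs 'labels'")
    labels <- check_labels(labels, nrow(x))
    a <- sum(x$in_area & labels); b <- sum(x$in_area & !labels)
    cc <- sum(!x$in_area & labels); dd <- sum(!x$in_area & !labels)
  }
  cells <- c(a = a, b = b, c = cc, d = dd)
  margins <- c(in_total = a + b, out_total = cc + dd,
               pos_total = a + cc, neg_total = b + dd,
               n = a + b + cc + dd)
  pct <- function(num, den) if (den > 0) round(100 * num / den) else NA_real_
  row_percent <- c(a = pct(a, a + b), b = pct(b, a + b),
                   c = pct(cc, cc + dd), d = pct(dd, cc + dd))
  col_percent <- c(a = pct(a, a + cc), c = pct(cc, a + cc),
                   b = pct(b, b + dd), d = pct(dd, b + dd))
  or <- if (b * cc > 0) (a * dd) / (b * cc) else Inf
  structure(list(cells = cells, margins = margins,
                 row_percent = row_percent, col_percent = col_percent,
                 odds_ratio = or),
            class = "contingency_report")
}

#' @export
print.contingency_report <- function(x, ...) {
  m <- matrix(c(x$cells["a"], x$cells["b"], x$margins["in_total"],
                x$cells["c"], x$cells["d"], x$margins["out_total"],
                x$margins["pos_total"], x$margins["neg_total"],
                x$margins["n"]),
              3, 3, byrow = TRUE,
              dimnames = list(c("in area", "outside", "total"),
                              c("label+", "label-", "total")))
  print(m)
  cat(sprintf("odds ratio: %.2f\n", x$odds_ratio))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Without continuity correction, df = 1. A zero margin leaves the expected
#' counts undefined and is an error.
#'
#' @param table a [contingency_table()].
#' @return list with `statistic`, `df`, `p`.
#' @export
chi2_test <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  m <- matrix(c(table$a, table$b, table$c, table$d), 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin: chi-square test undefined")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Lobe-level location distribution report
#'
#' Summarizes tumor location per subtype: single temporal lobe, multiple
#' lobes including temporal, other locations, and laterality, with
#' percentages to two decimals. Temporal involvement is the single plus
#' multiple share of the column total.
#'
#' Location categories are derived from `vasari_f1` (epicenter code; 2 =
#' temporal) and `multilobe_temporal`: single temporal = F1 2 without the
#' multilobe flag; multiple including temporal = multilobe flag set; other
#' = neither.
#'
#' @param samples data.frame as from [read_samples()] with `subtype`,
#'   `vasari_f1`, `multilobe_temporal` and optionally `side`.
#' @return An object of class `location_summary`: `counts` and `percent`
#'   matrices (rows = categories, columns = Total plus subtypes) and
#'   `temporal_involvement` (percent per column).
#' @export
location_summary <- function(samples) {
  cats <- c("single_temporal", "multi_temporal", "other",
            "left", "right", "bilateral")
  subtypes <- c("proneural", "mesenchymal", "neural", "classical")
  cols <- c("total", subtypes)
  counts <- matrix(0L, length(cats), length(cols),
                   dimnames = list(cats, cols))
  if (nrow(samples)) {
    multi <- samples$multilobe_temporal %in% 1
    single <- !multi & !is.na(samples$vasari_f1) & samples$vasari_f1 == 2
    loc <- ifelse(single, "single_temporal",
                  ifelse(multi, "multi_temporal", "other"))
    side <- if ("side" %in% names(samples)) samples$side else
      rep(NA_character_, nrow(samples))
    for (col in cols) {
      pick <- if (col == "total") rep(TRUE, nrow(samples)) else
        !is.na(samples$subtype) & samples$subtype == col
      counts[1:3, col] <- vapply(cats[1:3],
                                 function(g) sum(pick & loc == g), integer(1))
      counts[4:6, col] <- vapply(cats[4:6],
                                 function(g) sum(pick & !is.na(side) & side == g),
                                 integer(1))
    }
  }
  totals <- counts["single_temporal", ] + counts["multi_temporal", ] +
    counts["other", ]
  percent <- sweep(counts, 2, pmax(totals, 1), "/") * 100
  percent[, totals == 0] <- 0
  percent <- round(percent, 2)
  temporal <- round(100 * (counts["single_temporal", ] +
                             counts["multi_temporal", ]) / pmax(totals, 1), 2)
  temporal[totals == 0] <- 0
  structure(list(counts = counts, percent = percent,
                 temporal_involvement = temporal, n = totals),
            class = "location_summary")
}

#' @export
print.location_summary <- function(x, ...) {
  cat("location_summary (counts):\n")
  print(x$counts)
  cat("temporal involvement (%):\n")
  print(x$temporal_involvement)
  invisible(x)
}
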