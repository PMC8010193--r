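#' Read and write gene-set (GMT) files
#'
#' GMT is tab-separated: set name, description, then member gene ids.
#'
#' @param path file path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors of gene ids.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a genes-by-samples expression matrix
#'
#' TSV/CSV with gene ids in the first column and one column per sample.
#' Values are assumed on a monotone-comparable (typically log-like) scale;
#' the scoring functions are rank-based per sample so any per-sample
#' monotone transform leaves them unchanged.
#'
#' @param path file path.
#' @return numeric matrix with gene-id rownames and sample-id colnames.
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (any(!is.finite(m))) stop("non-finite expression values")
  m
}

#' Single-sample GSEA enrichment score
#'
#' For each sample, genes are ranked by expression (descending); the
#' enrichment score is the sum over all rank positions of the difference
#' between the weighted empirical distribution of in-set genes walked down
#' the ranking and the unweighted distribution of out-of-set genes -- the
#' integrated running-sum form of single-sample GSEA. The weight of a gene
#' is its rank position from the bottom raised to `alpha` (`alpha = 0`
#' weights all in-set genes equally). Scores depend on ranks only, so they
#' are invariant to per-sample monotone transforms of expression.
#'
#' @param expr genes x samples numeric matrix with rownames.
#' @param gene_set character vector of gene ids (at least one present in
#'   `expr`, and not all of them).
#' @param alpha rank-weight exponent, >= 0; default 0.25, the conventional
#'   single-sample choice.
#' @param ties how tied expression values are ranked: `"average"` shares
#'   the average rank weight, `"first"` breaks ties by row order.
#' @param normalize `"none"` or `"minmax"` (rescale scores to \[0, 1\]
#'   across samples; useful when comparing sets of different size).
#' @return Named numeric vector of per-sample enrichment scores.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25,
                         ties = c("average", "first"),
                         normalize = c("none", "minmax")) {
  ties <- match.arg(ties)
  normalize <- match.arg(normalize)
  if (!is.matrix(expr) || is.null(rownames(expr)))
    stop("'expr' must be a matrix with gene-id rownames")
  if (nrow(expr) < 2L) stop("need at least two genes")
  if (!is.numeric(alpha) || alpha < 0 || !is.finite(alpha))
    stop("'alpha' must be finite and >= 0")
  in_set <- rownames(expr) %in% gene_set
  if (!any(in_set)) stop("gene set shares no genes with the matrix")
  if (all(in_set)) stop("gene set covers the whole matrix")
  n <- nrow(expr)
  n_out <- n - sum(in_set)
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    # rank n = highest expression; ordering walks the ranking top-down
    r <- rank(x, ties.method = if (ties == "first") "last" else "average")
    ord <- order(r, decreasing = TRUE)
    w <- r[ord]^alpha
    ino <- in_set[ord]
    win <- w * ino
    p_in <- cumsum(win) / sum(win)
    p_out <- cumsum(!ino) / n_out
    sum(p_in - p_out)
  }, numeric(1))
  names(scores) <- colnames(expr)
  if (normalize == "minmax") {
    rng <- range(scores)
    scores <- if (diff(rng) > 0) (scores - rng[1L]) / diff(rng) else scores * 0
  }
  scores
}

#' Score several gene sets
#'
#' Applies [ssgsea_score()] to each set, collecting per-set failures (e.g. a
#' marker set absent from the matrix) instead of aborting.
#'
#' @param expr genes x samples matrix.
#' @param sets named list of gene-id vectors (e.g. 22 immune-cell marker
#'   sets from [read_gmt()]).
#' @inheritParams ssgsea_score
#' @return list with `scores` (sets x samples matrix for the sets that
#'   scored) and `errors` (named character vector of failure messages).
#' @export
celltype_scores <- function(expr, sets, alpha = 0.25,
                            ties = "average", normalize = "none") {
  res <- lapply(sets, function(s)
    tryCatch(ssgsea_score(expr, s, alpha = alpha, ties = ties,
                          normalize = normalize),
             error = function(e) e))
  failed <- vapply(res, inherits, logical(1), "error")
  errors <- vapply(res[failed], conditionMessage, character(1))
  scores <- if (any(!failed)) do.call(rbind, res[!failed]) else
    matrix(numeric(), 0, ncol(expr), dimnames = list(NULL, colnames(expr)))
  list(scores = scores, errors = errors)
}

#' Signature-based tumor purity proxy
#'
#' Scores the immune and stromal signatures per sample, z-scores each across
#' samples and returns their negated mean: high immune/stromal signal means
#' high non-neoplastic infiltration, hence low purity. This is a
#' signature-combination proxy on an arbitrary scale (not a calibrated
#' purity fraction); it orders samples, and group contrasts are meaningful.
#'
#' @param expr genes x samples matrix (>= 2 samples).
#' @param immune_set,stromal_set gene-id vectors.
#' @inheritParams ssgsea_score
#' @return Named numeric vector; higher = purer.
#' @export
purity_proxy <- function(expr, immune_set, stromal_set, alpha = 0.25) {
  if (ncol(expr) < 2L) stop("purity z-scoring needs at least two samples")
  im <- ssgsea_score(expr, immune_set, alpha = alpha)
  st <- ssgsea_score(expr, stromal_set, alpha = alpha)
  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  -(zs(im) + zs(st)) / 2
}

#' Two-group Student's t comparison of a per-sample quantity
#'
#' Pooled-variance two-sample t-test (df = n1 + n2 - 2) of a numeric
#' per-sample vector between in-area and out-of-area samples.
#'
#' @param values named (or membership-aligned) numeric vector.
#' @param in_area logical vector, `TRUE` for in-area samples (a
#'   [classify_membership()] data.frame is also accepted).
#' @return list with `t`, `df`, `p`, `mean_in`, `mean_out`.
#' @export
diff_by_group <- function(values, in_area) {
  if (is.data.frame(in_area)) in_area <- in_area$in_area
  in_area <- as.logical(in_area)
  if (length(values) != length(in_area)) stop("lengths differ")
  x <- values[in_area]; y <- values[!in_area]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least two samples")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # degenerate: no within-group variance
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(values) - 2L, p = 1,
                  mean_in = mean(x), mean_out = mean(y)))
    warning("both groups constant with different means; p reported as 0")
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(values) - 2L, p = 0,
                mean_in = mean(x), mean_out = mean(y)))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), mean_in = mean(x), mean_out = mean(y))
}

#' Per-gene differential expression between in- and out-of-area groups
#'
#' Genewise pooled-variance Student's t-test. The log2 fold change is the
#' out-group minus in-group mean of the (log-scale) expression values, so a
#' positive value means higher expression outside the area. Significance
#' stars follow the 0.05 / 0.01 / 0.001 convention.
#'
#' @param expr genes x samples matrix, assumed on a log-like scale; set
#'   `log2_transform = TRUE` to apply log2(x + 1) first (requires
#'   non-negative values).
#' @param in_area logical per-sample vector aligned with columns (or a
#'   [classify_membership()] data.frame ordered like the columns).
#' @param log2_transform apply log2(x + 1) before testing.
#' @return data.frame (one row per gene): `gene`, `t`, `p`, `log2_fc`,
#'   `mean_in`, `mean_out`, `stars`.
#' @export
diff_expression <- function(expr, in_area, log2_transform = FALSE) {
  if (is.data.frame(in_area)) in_area <- in_area$in_area
  in_area <- as.logical(in_area)
  if (ncol(expr) != length(in_area)) stop("membership does not match columns")
  n1 <- sum(in_area); n2 <- sum(!in_area)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least two samples")
  if (log2_transform) {
    if (any(expr < 0)) stop("log2 transform needs non-negative values")
    expr <- log2(expr + 1)
  }
  xin <- expr[, in_area, drop = FALSE]
  xout <- expr[, !in_area, drop = FALSE]
  m1 <- rowMeans(xin); m2 <- rowMeans(xout)
  v1 <- apply(xin, 1L, stats::var); v2 <- apply(xout, 1L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, (m1 - m2) / se, 0)
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df)
  p[se == 0] <- 1
  data.frame(gene = rownames(expr), t = t, p = p, log2_fc = m2 - m1,
             mean_in = m1, mean_out = m2, stars = stars_for_p(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname diff_expression
#' @param p p-values.
#' @return `stars_for_p()` maps p to `"ns"`, `"*"` (p < 0.05), `"**"`
#'   (p < 0.01) or `"***"` (p < 0.001).
#' @export
stars_for_p <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Top differentially expressed genes
#'
#' Keeps genes with p < `p_cutoff`, orders them by absolute log2 fold change
#' descending (ties: smaller p, then gene id) and returns the top `k`; fewer
#' than `k` significant genes are all returned.
#'
#' @param diff data.frame from [diff_expression()].
#' @param k number of genes to report.
#' @param p_cutoff significance filter.
#' @return data.frame subset of `diff`, ranked.
#' @export
rank_diff_genes <- function(diff, k = 10, p_cutoff = 0.05) {
  if (nrow(diff) == 0L) return(diff)
  sig <- diff[diff$p < p_cutoff, , drop = FALSE]
  if (nrow(sig) == 0L) return(sig)
  ord <- order(-abs(sig$log2_fc), sig$p, sig$gene)
  out <- sig[ord, , drop = FALSE][seq_len(min(k, nrow(sig))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
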