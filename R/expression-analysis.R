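#' Fibroblast marker score and classification
#'
#' Scores every cell as the mean of z-scored marker-gene expression (markers
#' z-scored gene-wise across cells) and classifies cells with
#' `score >= threshold` as fibroblasts. Genes with zero variance contribute a
#' z-score of 0. Markers absent from the matrix are dropped with a warning; at
#' least one must remain.
#'
#' @param sce log-normalised `SingleCellExperiment`.
#' @param markers character vector of marker gene ids.
#' @param threshold classification cutoff on the mean z-score (default 0).
#' @return data.frame with `cell`, `score`, `is_fibroblast`.
#' @export
fibroblast_score <- function(sce, markers, threshold = 0) {
  expr <- get_logcounts(sce)
  present <- intersect(markers, rownames(expr))
  if (length(present) == 0L)
    stop("none of the marker genes are present in the expression matrix")
  missing <- setdiff(markers, present)
  if (length(missing))
    warning("markers absent from matrix: ", paste(missing, collapse = ", "))
  m <- as.matrix(expr[present, , drop = FALSE])
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  z <- (m - mu) / ifelse(sd == 0, 1, sd)
  z[sd == 0, ] <- 0
  score <- colMeans(z)
  data.frame(cell = colnames(expr), score = unname(score),
             is_fibroblast = unname(score >= threshold),
             stringsAsFactors = FALSE)
}

# log2 fold change on de-logged means with a small pseudocount so that a group
# expressing nothing yields a large finite magnitude instead of +/-Inf.
log2_fc <- function(x_caf, x_nf, eps = 1e-9) {
  log2((mean(expm1(x_caf)) + eps) / (mean(expm1(x_nf)) + eps))
}

#' Differential transcription-factor screen (CAF vs NF)
#'
#' For every TF of the universe present in the matrix, contrasts CAF against NF
#' cells with the rank-sum test on log-normalised expression, computes the
#' log2 fold change of de-logged group means, adjusts p-values with
#' Benjamini-Hochberg across the tested TFs, and calls a TF up-regulated when
#' `p_adj < alpha` and `log2FC > lfc_min`.
#'
#' @param sce log-normalised `SingleCellExperiment` with a `group` column
#'   containing both `"NF"` and `"CAF"` (each with at least 3 cells).
#' @param tf_universe character vector of TF gene ids.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param lfc_min minimum log2 fold change for an "up" call (default 0.25).
#' @return list with `table` (one row per tested TF: `gene`, `log2_fc`, `U`,
#'   `p`, `p_adj`, `direction`) and `up` (character vector, the up-set).
#' @export
differential_tfs <- function(sce, tf_universe, alpha = 0.05, lfc_min = 0.25) {
  expr <- get_logcounts(sce)
  group <- SummarizedExperiment::colData(sce)$group
  if (is.null(group) || !all(c("NF", "CAF") %in% group))
    stop("matrix must contain both NF and CAF cells")
  for (g in c("NF", "CAF"))
    if (sum(group %in% g) < 3L)
      stop(sprintf("group '%s' has fewer than 3 cells", g))
  tfs <- intersect(tf_universe, rownames(expr))
  if (length(tfs) == 0L)
    stop("TF universe does not overlap the expression matrix genes")
  caf <- group %in% "CAF"; nf <- group %in% "NF"
  rows <- lapply(tfs, function(g) {
    x_caf <- as.numeric(expr[g, caf]); x_nf <- as.numeric(expr[g, nf])
    ts <- rank_sum_test(x_caf, x_nf, "two.sided")
    data.frame(gene = g, log2_fc = log2_fc(x_caf, x_nf), U = ts$U, p = ts$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  tab$direction <- ifelse(tab$p_adj >= alpha, "ns",
                          ifelse(tab$log2_fc > lfc_min, "up",
                                 ifelse(tab$log2_fc < -lfc_min, "down", "ns")))
  list(table = tab, up = tab$gene[tab$direction == "up"])
}

#' Intersection of per-dataset up-regulated gene sets
#'
#' The cross-dataset step of the TF screen: a gene is commonly up-regulated
#' only if it appears in the up-set of every dataset.
#'
#' @param up_sets list of at least two character vectors.
#' @return character vector (possibly empty), sorted.
#' @export
common_upregulated <- function(up_sets) {
  if (!is.list(up_sets) || length(up_sets) < 2L)
    stop("need at least 2 up-sets to intersect")
  sort(Reduce(intersect, lapply(up_sets, unique)))
}

#' Fraction of expressing cells per group
#'
#' The proportion of cells, per `group`, whose value for `gene` exceeds
#' `detect_threshold`. The default (raw counts, threshold 0) counts a cell as
#' expressing when at least one transcript was detected.
#'
#' @param sce `SingleCellExperiment`; `assay_name` selects the values used.
#' @param gene gene id.
#' @param detect_threshold detection cutoff (default 0).
#' @param assay_name assay to read (default `"counts"`).
#' @return named numeric vector of fractions, one per group level.
#' @export
expressing_fraction <- function(sce, gene, detect_threshold = 0,
                                assay_name = "counts") {
  expr <- SummarizedExperiment::assay(sce, assay_name)
  if (!gene %in% rownames(expr)) stop(sprintf("gene '%s' not in matrix", gene))
  group <- SummarizedExperiment::colData(sce)$group
  if (is.null(group)) stop("cells carry no group labels")
  v <- as.numeric(expr[gene, ])
  vapply(split(v > detect_threshold, group), mean, numeric(1))
}

#' Pearson correlation of expression with pseudotime
#'
#' Correlates a gene's (log-normalised) expression with per-cell pseudotime;
#' the 95% confidence interval comes from the Fisher z-transform and the
#' p-value tests the null of zero correlation.
#'
#' @param sce log-normalised `SingleCellExperiment` with a `pseudotime`
#'   column; at least 4 cells with defined pseudotime.
#' @param gene gene id.
#' @return list with `r`, `ci` (length-2), `p`, `n`.
#' @export
pseudotime_correlation <- function(sce, gene) {
  expr <- get_logcounts(sce)
  if (!gene %in% rownames(expr)) stop(sprintf("gene '%s' not in matrix", gene))
  pt <- SummarizedExperiment::colData(sce)$pseudotime
  if (is.null(pt)) stop("cells carry no pseudotime")
  keep <- !is.na(pt)
  if (sum(keep) < 4L) stop("need at least 4 cells with pseudotime")
  x <- as.numeric(expr[gene, keep]); t <- pt[keep]
  if (stats::sd(x) == 0 || stats::sd(t) == 0)
    stop("zero variance in expression or pseudotime; correlation undefined")
  ct <- stats::cor.test(x, t, method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = sum(keep))
}
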