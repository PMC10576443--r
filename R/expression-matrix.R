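#' Assemble an expression matrix object
#'
#' Builds the [SingleCellExperiment::SingleCellExperiment] used throughout the
#' package: a genes x cells matrix plus per-cell metadata. Raw integer counts
#' go into the `counts` assay; library-size log-normalised values (added by
#' [normalize_expression()]) live in `logcounts`.
#'
#' @param counts numeric matrix (base or [Matrix::Matrix]), genes in rows and
#'   cells in columns, with unique dimnames; values must be non-negative and,
#'   when `normalized = FALSE`, integral.
#' @param cell_data `data.frame` with one row per cell. Recognised columns:
#'   `dataset`, `group` (`"NF"`/`"CAF"`), `cluster` (`"iCAF"`/`"myCAF"`/
#'   `"other"`), `pseudotime` (in `[0, 1]`).
#' @param normalized logical; `TRUE` if `counts` already holds log-normalised
#'   values (stored as `logcounts`).
#' @return a `SingleCellExperiment`.
#' @export
expression_matrix <- function(counts, cell_data = NULL, normalized = FALSE) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene (row) and cell (column) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids")
  if (min(counts) < 0) stop("expression values must be non-negative")
  if (!normalized && any(counts != round(counts)))
    stop("raw counts must be integers; pass normalized = TRUE for processed values")
  if (is.null(cell_data))
    cell_data <- data.frame(row.names = colnames(counts))
  if (nrow(cell_data) != ncol(counts))
    stop("cell_data must have one row per cell")
  if (!is.null(cell_data$group) &&
      !all(cell_data$group %in% c("NF", "CAF") | is.na(cell_data$group)))
    stop("group labels must be 'NF', 'CAF' or NA (non-fibroblast)")
  if (!is.null(cell_data$pseudotime)) {
    pt <- cell_data$pseudotime
    if (any(pt < 0 | pt > 1, na.rm = TRUE)) stop("pseudotime must lie in [0, 1]")
  }
  assays <- if (normalized) list(logcounts = counts) else list(counts = counts)
  SingleCellExperiment::SingleCellExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(cell_data, row.names = colnames(counts))
  )
}

is_normalized <- function(sce) "logcounts" %in% SummarizedExperiment::assayNames(sce)

get_logcounts <- function(sce) {
  if (!is_normalized(sce))
    stop("expression matrix is not log-normalised; run normalize_expression() first")
  SummarizedExperiment::assay(sce, "logcounts")
}

#' Library-size log-normalisation
#'
#' Scales each cell to a fixed total count, then applies `log1p`. This is the
#' conventional single-cell normalisation; the fixed total makes per-cell
#' profiles comparable before marker scoring, differential testing and
#' signature scoring.
#'
#' @param sce `SingleCellExperiment` with a raw `counts` assay.
#' @param scale_total target library size (default `1e4`).
#' @return the input object with a `logcounts` assay added.
#' @export
normalize_expression <- function(sce, scale_total = 1e4) {
  assert_scalar_pos(scale_total, "scale_total")
  counts <- SummarizedExperiment::assay(sce, "counts")
  libs <- Matrix::colSums(counts)
  if (any(libs == 0))
    stop("all-zero cells cannot be normalised: ",
         paste(colnames(counts)[libs == 0], collapse = ", "))
  scaled <- sweep(as.matrix(counts), 2L, libs / scale_total, "/")
  SummarizedExperiment::assay(sce, "logcounts") <- log1p(scaled)
  sce
}
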