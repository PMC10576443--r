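#' Read an expression matrix from disk
#'
#' Two formats: `"mtx"` — a directory (or prefix) holding `matrix.mtx`
#' (genes x cells sparse MatrixMarket), `genes.tsv`, `barcodes.tsv`, and
#' optionally `cell_metadata.csv`; `"csv"` — a dense genes x cells CSV with
#' gene ids in the first column, plus optional `<stem>_cell_metadata.csv`.
#'
#' @param path directory (mtx) or file (csv) path.
#' @param format `"mtx"` or `"csv"`.
#' @param normalized whether the stored values are log-normalised.
#' @return a `SingleCellExperiment` (see [expression_matrix()]).
#' @export
read_expression <- function(path, format = c("mtx", "csv"), normalized = FALSE) {
  format <- match.arg(format)
  if (format == "mtx") {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    genes <- readLines(file.path(path, "genes.tsv"))
    cells <- readLines(file.path(path, "barcodes.tsv"))
    if (length(genes) != nrow(m))
      stop(sprintf("genes.tsv has %d lines but matrix has %d rows",
                   length(genes), nrow(m)))
    if (length(cells) != ncol(m))
      stop(sprintf("barcodes.tsv has %d lines but matrix has %d columns",
                   length(cells), ncol(m)))
    m <- as.matrix(m)
    dimnames(m) <- list(genes, cells)
    meta_path <- file.path(path, "cell_metadata.csv")
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    meta_path <- sub("\\.csv$", "_cell_metadata.csv", path)
  }
  cell_data <- NULL
  if (file.exists(meta_path)) {
    cell_data <- utils::read.csv(meta_path, row.names = 1,
                                 stringsAsFactors = FALSE)
    if (!identical(rownames(cell_data), colnames(m)))
      stop("cell metadata rows do not match matrix columns")
  }
  expression_matrix(m, cell_data, normalized = normalized)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]; `read_expression(write_expression(x))`
#' reproduces values, ids and metadata.
#'
#' @param sce a `SingleCellExperiment`.
#' @param path output directory (mtx) or csv file path.
#' @param format `"mtx"` or `"csv"`.
#' @param assay_name which assay to write.
#' @return `path`, invisibly.
#' @export
write_expression <- function(sce, path, format = c("mtx", "csv"),
                             assay_name = NULL) {
  format <- match.arg(format)
  assay_name <- assay_name %||%
    SummarizedExperiment::assayNames(sce)[1]
  m <- SummarizedExperiment::assay(sce, assay_name)
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(as.matrix(m)),
                                            "generalMatrix"), "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(m), file.path(path, "genes.tsv"))
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
    if (ncol(cd))
      utils::write.csv(cd, file.path(path, "cell_metadata.csv"))
  } else {
    df <- data.frame(gene = rownames(m), as.matrix(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
    if (ncol(cd))
      utils::write.csv(cd, sub("\\.csv$", "_cell_metadata.csv", path))
  }
  invisible(path)
}

#' Write / read a multi-channel image as multi-page TIFF with a JSON sidecar
#'
#' One 32-bit float page per channel; the sidecar (`<path>.json`) records the
#' channel order, `pixel_size_um`, `roi_id` and the intensity scale used to
#' map intensities into the TIFF's `[0, 1]` range.
#'
#' @param image an `mc_image`.
#' @param path `.tif` output path.
#' @return `path`, invisibly (`read_roi_tiff` returns an `mc_image`).
#' @export
write_roi_tiff <- function(image, path) {
  scale <- max(1, vapply(image$channels, max, numeric(1)))
  pages <- lapply(image$channels, function(m) m / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(channels = names(image$channels),
                  pixel_size_um = image$pixel_size_um,
                  roi_id = image$roi_id, intensity_scale = scale)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_roi_tiff
#' @export
read_roi_tiff <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(sidecar$channels))
    stop("TIFF page count does not match sidecar channel list")
  ch <- lapply(pages, function(p) p * sidecar$intensity_scale)
  names(ch) <- sidecar$channels
  multichannel_image(ch, pixel_size_um = sidecar$pixel_size_um,
                     roi_id = sidecar$roi_id)
}
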