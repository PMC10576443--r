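#' Construct a gene set
#'
#' @param name set name.
#' @param genes character vector of gene ids; duplicates are removed.
#' @param description optional free-text description.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("a gene set must contain at least one gene")
  structure(list(name = name, genes = genes, description = description),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

as_gene_ids <- function(set) {
  if (inherits(set, "gene_set")) set$genes else unique(as.character(set))
}

#' Read gene sets from a GMT file
#'
#' One set per tab-separated line: name, description, then gene ids. Duplicate
#' genes within a set are dropped with a warning; a line with fewer than three
#' fields is an error.
#'
#' @param path file path.
#' @return named list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields (name, description, genes...)", i))
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes))
      warning(sprintf("set '%s': duplicate genes removed", f[1]))
    gene_set(f[1], genes, f[2])
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets list of `gene_set` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description %||% "", s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
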