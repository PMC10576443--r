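#' Built-in marker panels and signature fixtures
#'
#' `fibroblast_marker_panel()` returns the generic fibroblast marker genes the
#' simulator plants in fibroblasts and the classifier uses by default.
#' `caf_signatures()` returns synthetic iCAF/myCAF signature gene sets matched
#' to the simulator's planted subtype programs (stand-ins for study-specific
#' signature lists, which are inputs in real analyses).
#'
#' @return character vector / list of two `gene_set`s.
#' @export
fibroblast_marker_panel <- function() {
  c("COL1A1", "COL1A2", "COL3A1", "DCN", "LUM", "PDGFRA", "PDGFRB", "THY1")
}

#' @rdname fibroblast_marker_panel
#' @export
caf_signatures <- function() {
  list(
    ICAF_SIGNATURE = gene_set("ICAF_SIGNATURE", icaf_program_genes(),
                              "synthetic inflammatory-CAF program"),
    MYCAF_SIGNATURE = gene_set("MYCAF_SIGNATURE", mycaf_program_genes(),
                               "synthetic myofibroblastic-CAF program"))
}

icaf_program_genes <- function() {
  c("CXCL8", "IL6", "CXCL1", "CXCL2", "IL11", "LIF", "CCL2", "CXCL12")
}

mycaf_program_genes <- function() {
  c("ACTA2", "TAGLN", "MYL9", "POSTN", "MYH11", "TPM1", "TPM2", "CTGF")
}

#' Configuration for the expression-cohort simulator
#'
#' Defaults describe the emulated study design: seven independent datasets,
#' each with matched normal-fibroblast (NF) and CAF groups, a 50-gene TF
#' universe in which `HIF1A` and `PRRX1` are up-regulated in the CAFs of every
#' dataset while a few private TFs are up-regulated per dataset only, CAF
#' subtype programs split between iCAF and myCAF clusters, and `HIF1A`
#' expression rising along pseudotime.
#'
#' @param n_datasets number of independent datasets.
#' @param n_cells_per_group NF and CAF cells per dataset.
#' @param n_other_cells non-fibroblast cells per dataset (no group label;
#'   classifier negatives).
#' @param n_genes total genes (markers + programs + TF universe + filler).
#' @param tf_universe_size number of TF genes; the first two are the common TFs.
#' @param common_up_tfs TFs planted up in CAFs of every dataset.
#' @param private_up_tfs_per_dataset TFs planted up in one dataset only.
#' @param log_fold_change planted log2 fold change for up-regulated TFs.
#' @param subtype_log_fold_change planted log2 fold change of the iCAF/myCAF
#'   program genes in their cluster.
#' @param marker_log_fold_change planted log2 fold change of fibroblast
#'   markers in fibroblasts vs other cells.
#' @param baseline_mean negative-binomial baseline mean count.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param dropout_rate binomial dropout probability in the low-expression
#'   limit; the realised per-entry probability decays with the underlying mean
#'   as `dropout_rate * exp(-dropout_decay * mu)`, mirroring the
#'   expression-dependent technical zeros of droplet scRNA-seq.
#' @param dropout_decay decay constant of the dropout probability per unit of
#'   mean expression (0 recovers uniform dropout).
#' @param pseudotime_coupled_gene gene whose mean follows
#'   `exp(slope * (t - 0.5))` along pseudotime `t`.
#' @param pseudotime_slope slope of that coupling (natural-log scale).
#' @param seed integer seed; identical config + seed reproduces the bundle
#'   bitwise.
#' @return a validated list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_datasets = 7L,
                              n_cells_per_group = 150L,
                              n_other_cells = 100L,
                              n_genes = 600L,
                              tf_universe_size = 50L,
                              common_up_tfs = c("HIF1A", "PRRX1"),
                              private_up_tfs_per_dataset = 3L,
                              log_fold_change = 1.5,
                              subtype_log_fold_change = 2,
                              marker_log_fold_change = 3,
                              baseline_mean = 2,
                              dispersion = 0.3,
                              dropout_rate = 0.2,
                              dropout_decay = 0.25,
                              pseudotime_coupled_gene = "HIF1A",
                              pseudotime_slope = 1.5,
                              seed = 1L) {
  cfg <- list(n_datasets = as.integer(n_datasets),
              n_cells_per_group = as.integer(n_cells_per_group),
              n_other_cells = as.integer(n_other_cells),
              n_genes = as.integer(n_genes),
              tf_universe_size = as.integer(tf_universe_size),
              common_up_tfs = as.character(common_up_tfs),
              private_up_tfs_per_dataset = as.integer(private_up_tfs_per_dataset),
              log_fold_change = log_fold_change,
              subtype_log_fold_change = subtype_log_fold_change,
              marker_log_fold_change = marker_log_fold_change,
              baseline_mean = baseline_mean,
              dispersion = dispersion,
              dropout_rate = dropout_rate,
              dropout_decay = dropout_decay,
              pseudotime_coupled_gene = pseudotime_coupled_gene,
              pseudotime_slope = pseudotime_slope,
              seed = as.integer(seed))
  for (f in c("n_datasets", "n_cells_per_group", "n_genes", "tf_universe_size"))
    if (cfg[[f]] < 1L) stop(sprintf("'%s' must be >= 1", f))
  if (cfg$n_other_cells < 0L) stop("'n_other_cells' must be >= 0")
  if (cfg$log_fold_change < 0) stop("'log_fold_change' must be >= 0")
  if (cfg$baseline_mean <= 0 || cfg$dispersion <= 0)
    stop("'baseline_mean' and 'dispersion' must be positive")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1)
    stop("'dropout_rate' must lie in [0, 1]")
  if (cfg$dropout_decay < 0) stop("'dropout_decay' must be >= 0")
  if (length(cfg$common_up_tfs) > cfg$tf_universe_size)
    stop("common_up_tfs exceed the TF universe size")
  universe <- tf_universe_names(cfg)
  if (cfg$private_up_tfs_per_dataset >
      length(setdiff(universe, cfg$common_up_tfs)))
    stop("not enough TFs in the universe for the requested private TFs")
  cohort_gene_names(cfg)   # errors when n_genes cannot hold the named genes
  structure(cfg, class = "cohort_sim_config")
}

tf_universe_names <- function(cfg) {
  extra <- cfg$tf_universe_size - length(cfg$common_up_tfs)
  c(cfg$common_up_tfs,
    if (extra > 0) sprintf("TF%02d", seq_len(extra) + length(cfg$common_up_tfs)))
}

cohort_gene_names <- function(cfg) {
  named <- unique(c(fibroblast_marker_panel(), icaf_program_genes(),
                    mycaf_program_genes(), tf_universe_names(cfg)))
  if (length(named) > cfg$n_genes)
    stop(sprintf("n_genes must be at least %d to hold markers, programs and TFs",
                 length(named)))
  c(named, sprintf("GENE%04d", seq_len(cfg$n_genes - length(named))))
}

#' Simulate a multi-dataset NF/CAF expression cohort
#'
#' Draws counts from a negative-binomial model (`mu`, variance
#' `mu + dispersion * mu^2`) followed by binomial dropout, with planted
#' effects: fibroblast markers elevated in NF and CAF cells vs other cells,
#' the common TFs elevated in CAFs of every dataset, private TFs elevated in
#' single datasets, iCAF/myCAF program genes elevated in their CAF cluster,
#' and the pseudotime-coupled gene rising along pseudotime (NF pseudotime
#' concentrated near 0, CAF pseudotime uniform on `[0, 1]`, mimicking
#' progressive NF-to-CAF differentiation).
#'
#' @param config a [cohort_sim_config()].
#' @return list of class `cohort_bundle` with `matrices` (one
#'   `SingleCellExperiment` per dataset), `truth` (planted TFs per dataset,
#'   marker/program gene lists, per-cell truth table) and `config`.
#' @export
simulate_expression_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  genes <- cohort_gene_names(config)
  universe <- tf_universe_names(config)
  markers <- fibroblast_marker_panel()
  with_seed(config$seed, {
    private <- lapply(seq_len(config$n_datasets), function(d)
      sample(setdiff(universe, config$common_up_tfs),
             config$private_up_tfs_per_dataset))
    matrices <- vector("list", config$n_datasets)
    truth_cells <- vector("list", config$n_datasets)
    for (d in seq_len(config$n_datasets)) {
      sim <- simulate_one_dataset(config, genes, private[[d]], d)
      matrices[[d]] <- sim$sce
      truth_cells[[d]] <- sim$truth
    }
    names(matrices) <- sprintf("dataset%d", seq_len(config$n_datasets))
    structure(list(
      matrices = matrices,
      truth = list(common_up_tfs = config$common_up_tfs,
                   private_up_tfs = stats::setNames(private, names(matrices)),
                   fibroblast_markers = markers,
                   icaf_program = icaf_program_genes(),
                   mycaf_program = mycaf_program_genes(),
                   cells = do.call(rbind, truth_cells)),
      config = config), class = "cohort_bundle")
  })
}

simulate_one_dataset <- function(cfg, genes, private_tfs, d) {
  n_grp <- cfg$n_cells_per_group
  n_cells <- 2L * n_grp + cfg$n_other_cells
  group <- c(rep("NF", n_grp), rep("CAF", n_grp),
             rep(NA_character_, cfg$n_other_cells))
  is_fib <- !is.na(group)
  cluster <- rep("other", n_cells)
  caf_idx <- which(group %in% "CAF")
  cluster[caf_idx] <- rep_len(c("iCAF", "myCAF"), length(caf_idx))
  pseudotime <- rep(NA_real_, n_cells)
  pseudotime[group %in% "NF"] <- stats::rbeta(n_grp, 1.5, 8)
  pseudotime[caf_idx] <- stats::runif(length(caf_idx))

  mu <- matrix(cfg$baseline_mean, nrow = length(genes), ncol = n_cells,
               dimnames = list(genes, NULL))
  mu[intersect(fibroblast_marker_panel(), genes), is_fib] <-
    cfg$baseline_mean * 2^cfg$marker_log_fold_change
  up <- unique(c(cfg$common_up_tfs, private_tfs))
  mu[up, caf_idx] <- mu[up, caf_idx] * 2^cfg$log_fold_change
  mu[icaf_program_genes(), cluster == "iCAF"] <-
    mu[icaf_program_genes(), cluster == "iCAF"] * 2^cfg$subtype_log_fold_change
  mu[mycaf_program_genes(), cluster == "myCAF"] <-
    mu[mycaf_program_genes(), cluster == "myCAF"] * 2^cfg$subtype_log_fold_change
  pg <- cfg$pseudotime_coupled_gene
  if (pg %in% genes) {
    has_pt <- !is.na(pseudotime)
    mu[pg, has_pt] <- mu[pg, has_pt] *
      exp(cfg$pseudotime_slope * (pseudotime[has_pt] - 0.5))
  }

  counts <- matrix(stats::rnbinom(length(mu), mu = as.numeric(mu),
                                  size = 1 / cfg$dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  if (cfg$dropout_rate > 0) {
    p_drop <- cfg$dropout_rate * exp(-cfg$dropout_decay * as.numeric(mu))
    counts <- counts * matrix(stats::rbinom(length(counts), 1L, 1 - p_drop),
                              nrow = nrow(counts))
  }
  cell_ids <- sprintf("d%d_cell%04d", d, seq_len(n_cells))
  colnames(counts) <- cell_ids
  cd <- data.frame(dataset = sprintf("dataset%d", d), group = group,
                   cluster = cluster, pseudotime = pseudotime,
                   is_fibroblast = is_fib, row.names = cell_ids,
                   stringsAsFactors = FALSE)
  list(sce = expression_matrix(counts, cd),
       truth = data.frame(cell = cell_ids, dataset = cd$dataset,
                          group = group, cluster = cluster,
                          pseudotime = pseudotime, is_fibroblast = is_fib,
                          stringsAsFactors = FALSE))
}
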