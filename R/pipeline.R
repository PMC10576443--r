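default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "icaftools_out",
    stages = list(cohort = TRUE, tf_screen = TRUE, signatures = TRUE,
                  pseudotime = TRUE, spatial = TRUE),
    cohort = list(),                      # overrides for cohort_sim_config()
    tf_screen = list(alpha = 0.05, lfc_min = 0.25),
    signatures = list(alpha = 0.25, gmt = NULL, dataset = 1L),
    pseudotime = list(gene = NULL, dataset = 1L),
    spatial = list(n_rois = 7L, roi = list(),   # overrides for roi_sim_config()
                   band = list(reference_max_um = 100, band_width_um = 50,
                               max_distance_um = 400),
                   spindle_min_eccentricity = 0.8,
                   threshold_mode = "otsu"))
}

merge_config <- function(defaults, user, path = "") {
  extra <- setdiff(names(user), names(defaults))
  # parameter blocks passed through to the simulators may hold any of their args
  passthrough <- path %in% c("cohort", "spatial/roi")
  if (length(extra) && !passthrough)
    stop(sprintf("unknown config key%s under '%s': %s",
                 if (length(extra) > 1) "s" else "", if (nzchar(path)) path else "top level",
                 paste(extra, collapse = ", ")))
  out <- defaults
  for (k in names(user)) {
    sub <- if (nzchar(path)) paste(path, k, sep = "/") else k
    out[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]) && !passthrough)
      merge_config(defaults[[k]], user[[k]], sub) else user[[k]]
  }
  out
}

#' Load and validate a pipeline configuration
#'
#' Accepts a YAML file path or a list; unknown keys are rejected (except
#' inside the `cohort` and `spatial$roi` blocks, which accept any
#' [cohort_sim_config()] / [roi_sim_config()] argument).
#'
#' @param config path to a YAML file, or a list of overrides.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the enabled stages in dependency order — simulate the expression
#' cohort, screen TFs per dataset and intersect the up-sets, score iCAF/myCAF
#' signatures and contrast the CAF clusters, correlate the coupled gene with
#' pseudotime, simulate and quantify tissue ROIs — writing every table under
#' `out_dir` together with a run manifest (config hash, package version,
#' output checksums, collected warnings). A failing ROI is recorded as a
#' warning and does not abort the remaining ROIs. All randomness derives from
#' the single config seed through named per-stage substreams.
#'
#' @param config a [pipeline_config()], YAML path, or override list.
#' @return list with `manifest` and per-stage results.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character(0)
  note <- function(...) warnings <<- c(warnings, sprintf(...))
  results <- list()
  outputs <- character(0)
  emit <- function(obj, file, writer) {
    p <- file.path(cfg$out_dir, file)
    writer(obj, p)
    outputs <<- c(outputs, p)
  }
  write_csv <- function(x, p) utils::write.csv(x, p, row.names = FALSE)
  write_json <- function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                                    digits = NA, null = "null")

  bundle <- NULL
  if (isTRUE(cfg$stages$cohort)) {
    ccfg <- do.call(cohort_sim_config,
                    utils::modifyList(list(seed = derive_seed(cfg$seed, "cohort")),
                                      cfg$cohort))
    bundle <- simulate_expression_cohort(ccfg)
    bundle$matrices <- lapply(bundle$matrices, normalize_expression)
    results$cohort <- bundle
    emit(bundle$truth$cells, "cohort_cells.csv", write_csv)
    message(sprintf("[cohort] %d datasets x %d cells simulated",
                    length(bundle$matrices), ncol(bundle$matrices[[1]])))
  }

  if (isTRUE(cfg$stages$tf_screen)) {
    if (is.null(bundle)) stop("stage 'tf_screen' requires outputs of stage 'cohort'")
    universe <- tf_universe_names(bundle$config)
    screens <- lapply(bundle$matrices, differential_tfs, tf_universe = universe,
                      alpha = cfg$tf_screen$alpha, lfc_min = cfg$tf_screen$lfc_min)
    common <- common_upregulated(lapply(screens, `[[`, "up"))
    results$tf_screen <- list(screens = screens, common_up = common)
    emit(do.call(rbind, Map(function(s, nm) cbind(dataset = nm, s$table),
                            screens, names(screens))),
         "tf_screen.csv", write_csv)
    emit(list(common_upregulated = common), "common_tfs.json", write_json)
    message(sprintf("[tf_screen] %d TFs tested per dataset; common up-set: %s",
                    nrow(screens[[1]]$table), paste(common, collapse = ", ")))
  }

  if (isTRUE(cfg$stages$signatures)) {
    if (is.null(bundle)) stop("stage 'signatures' requires outputs of stage 'cohort'")
    sets <- if (is.null(cfg$signatures$gmt)) caf_signatures()
            else read_gmt(cfg$signatures$gmt)
    sce <- bundle$matrices[[cfg$signatures$dataset]]
    caf <- SummarizedExperiment::colData(sce)$group %in% "CAF"
    scores <- ssgsea_matrix(sce[, caf], sets, alpha = cfg$signatures$alpha)
    cl <- SummarizedExperiment::colData(sce)$cluster[caf]
    contrasts <- lapply(rownames(scores), function(s)
      c(list(signature = s), signature_contrast(scores[s, ], cl)))
    results$signatures <- list(scores = scores, contrasts = contrasts)
    emit(data.frame(signature = rownames(scores), scores, check.names = FALSE),
         "signature_scores.csv", write_csv)
    emit(contrasts, "signature_contrasts.json", write_json)
    message(sprintf("[signatures] %d sets scored on %d CAF cells",
                    nrow(scores), ncol(scores)))
  }

  if (isTRUE(cfg$stages$pseudotime)) {
    if (is.null(bundle)) stop("stage 'pseudotime' requires outputs of stage 'cohort'")
    gene <- cfg$pseudotime$gene %||% bundle$config$pseudotime_coupled_gene
    pc <- pseudotime_correlation(bundle$matrices[[cfg$pseudotime$dataset]], gene)
    results$pseudotime <- pc
    emit(c(list(gene = gene), pc), "pseudotime_correlation.json", write_json)
    message(sprintf("[pseudotime] %s: r = %.3f (p = %.3g)", gene, pc$r, pc$p))
  }

  if (isTRUE(cfg$stages$spatial)) {
    bcfg <- do.call(band_config, cfg$spatial$band)
    counts <- list()
    for (i in seq_len(cfg$spatial$n_rois)) {
      rcfg <- do.call(roi_sim_config,
                      utils::modifyList(
                        list(seed = derive_seed(cfg$seed, sprintf("roi%d", i))),
                        cfg$spatial$roi))
      res <- tryCatch({
        sim <- simulate_if_roi(rcfg, roi_id = sprintf("roi%d", i))
        analyze_roi(sim$image, bcfg,
                    thresholds = list(mode = cfg$spatial$threshold_mode),
                    spindle_min_eccentricity = cfg$spatial$spindle_min_eccentricity)
      }, error = function(e) {
        note("ROI %d failed: %s", i, conditionMessage(e))
        NULL
      })
      if (!is.null(res)) counts[[length(counts) + 1L]] <- res
    }
    if (length(counts) < 2L)
      stop("spatial stage needs at least 2 successfully analysed ROIs")
    rr <- withCallingHandlers(
      relative_ratios(counts),
      warning = function(w) { note("%s", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    results$spatial <- list(counts = counts, ratios = rr)
    emit(do.call(rbind, lapply(counts, function(b) cbind(roi = b$roi_id, b$bands))),
         "band_counts.csv", write_csv)
    emit(rr$summary, "band_ratios.csv", write_csv)
    message(sprintf("[spatial] %d ROIs analysed; %d bands tested",
                    length(counts), nrow(rr$summary)))
  }

  manifest <- list(
    package = "icaftools",
    version = as.character(utils::packageVersion("icaftools")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    outputs = as.list(tools::md5sum(outputs)),
    warnings = warnings)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
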