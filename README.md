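# icaftools

Hypoxia shapes the inflammatory state of cancer-associated fibroblasts
(CAFs): the hypoxia master regulator *HIF1A* is up-regulated in CAFs across
tumour types, and IL8–αSMA double-positive spindle-shaped inflammatory CAFs
(iCAFs) accumulate in tissue beyond ~100 μm from a functional blood vessel —
the distance at which hypoxia sets in. `icaftools` packages the
computational pipeline behind those observations for R users working on
tumour-stroma biology:

* **Cross-dataset TF screen** — per-dataset Wilcoxon rank-sum differential
  expression (CAF vs normal fibroblast) over a TF universe with
  Benjamini–Hochberg adjustment, and exact intersection of the up-regulated
  sets across datasets (`differential_tfs()`, `common_upregulated()`).
* **Signature scoring** — single-sample GSEA: with the universe ranked by
  expression, the score is `Σ_i [P_in^w(i) − P_out(i)]`, the summed
  difference between the rank-weighted in-set ECDF (weights `rank^α`,
  α = 0.25) and the out-of-set ECDF (`ssgsea_score()`); plus the weighted KS
  running-sum enrichment score with a gene-set permutation null
  (`running_es()`, `geneset_permutation_p()`) and group contrasts
  (`signature_contrast()`, `pathway_correlation()`).
* **Pseudotime correlation** — Pearson r with Fisher-z 95% CI for expression
  along an NF→CAF trajectory (`pseudotime_correlation()`).
* **Spatial quantification** — from four-channel immunofluorescence images
  (DAPI / αSMA / IL-8 / vessel lectin): vessel segmentation, exact
  μm-calibrated Euclidean distance map, nucleus detection with watershed
  splitting, iCAF calling as IL8–αSMA double-positive cells with
  eccentricity ≥ 0.8 ("spindle-shaped"), 50-μm distance-band counting, and
  per-band Mann–Whitney tests of iCAF ratios against the ≤100 μm
  perivascular reference (`analyze_roi()`, `relative_ratios()`).
* **Synthetic data with ground truth** — seeded generators for multi-dataset
  NF/CAF expression cohorts (negative binomial + expression-dependent
  dropout, planted common/private TFs, iCAF/myCAF programs, pseudotime
  coupling) and for tissue ROIs with a logistic iCAF–distance gradient
  (`simulate_expression_cohort()`, `simulate_if_roi()`), so every stage is
  testable against planted truth.

Formats: MTX/CSV expression with cell metadata, GMT gene sets, multi-page
TIFF images with a JSON sidecar, YAML pipeline configs
(`run_pipeline()` orchestrates all stages and writes a checksummed run
manifest).

## Worked example

```r
library(icaftools)

# --- expression side: screen TFs across 3 simulated datasets ---------------
b    <- simulate_expression_cohort(cohort_sim_config(n_datasets = 3, seed = 1))
mats <- lapply(b$matrices, normalize_expression)
tfs  <- c("HIF1A", "PRRX1", sprintf("TF%02d", 3:50))
ups  <- lapply(mats, function(m) differential_tfs(m, tfs)$up)
common_upregulated(ups)
#> [1] "HIF1A" "PRRX1"

pc <- pseudotime_correlation(mats[[1]], "HIF1A")
sprintf("HIF1A vs pseudotime: r = %.2f, 95%% CI [%.2f, %.2f]", pc$r, pc$ci[1], pc$ci[2])
#> [1] "HIF1A vs pseudotime: r = 0.56, 95% CI [0.48, 0.63]"

# --- spatial side: one simulated ROI through the full pipeline -------------
sim <- simulate_if_roi(roi_sim_config(seed = 1), roi_id = "roi1")
bc  <- analyze_roi(sim$image)
bc$bands
#>        band  lo  hi n_icaf n_caf_total area_um2
#> 1   [0,100]   0 100      7          68    90163
#> 2 (100,150] 100 150     10          19    36006
#> 3 (150,200] 150 200     21          30    32820
#> 4 (200,250] 200 250     16          23    32480
#> 5 (250,300] 250 300     16          30    32332
#> 6 (300,350] 300 350     10          19    32251
#> 7 (350,400] 350 400     18          26    32230
```

Each per-dataset screen recovers the two TFs planted in every dataset (plus
that dataset's private ones, which the intersection removes); *HIF1A*
expression rises along the NF→CAF pseudotime; and in tissue space only 7 of
68 perivascular CAFs are iCAFs while distal bands of roughly a third the
area carry 10–21 each — the hypoxic-niche enrichment the package is built to
quantify. Aggregating such band counts over several ROIs and testing each
band's ratio against the reference is `relative_ratios()`; the vignette
(`vignettes/methods.Rmd`) documents the models, defaults and calibration
properties, and `inst/extdata/demo_config.yaml` runs a scaled-down
end-to-end pipeline via `run_pipeline()`.

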