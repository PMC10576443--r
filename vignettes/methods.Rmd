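---
title: "Methods: quantifying hypoxia-shaped inflammatory CAFs in expression and tissue space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying hypoxia-shaped inflammatory CAFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icaftools)
```

## Scientific setting

Cancer-associated fibroblasts (CAFs) split into at least two recurring
subtypes: myofibroblastic CAFs (myCAFs, contractile, αSMA-high) and
inflammatory CAFs (iCAFs, cytokine-high, e.g. IL-6/IL-8). A body of evidence
implicates tissue hypoxia — which sets in roughly 100 μm away from a
functional blood vessel — as a driver of the iCAF state, with HIF1A as the
master transcription factor. `icaftools` implements the computational
arguments behind that claim as a reusable, testable pipeline:

1. a **cross-dataset TF screen**: per-dataset differential expression of
   transcription factors between CAFs and normal fibroblasts (NFs), followed
   by exact intersection of the per-dataset up-regulated sets;
2. **single-sample signature scoring** (ssGSEA) of iCAF/myCAF gene programs,
   group contrasts, and a GSEA-style running-sum enrichment score with a
   gene-set permutation null;
3. **pseudotime–expression correlation** with Fisher-z confidence intervals;
4. a **spatial pipeline** that segments vessels in four-channel
   immunofluorescence images (DAPI / αSMA / IL-8 / vessel lectin), computes a
   μm-calibrated Euclidean distance map, detects cells, calls IL8–αSMA
   double-positive spindle-shaped iCAFs, bins them into 50-μm distance bands
   and tests each band's iCAF ratio against the ≤100 μm perivascular
   reference.

Public patient datasets are not re-analysed here. Instead the package ships
seeded synthetic-data generators that emulate the statistical structure those
analyses rely on, with ground truth, so every stage can be validated by
planted-effect recovery and null calibration.

## Expression model

`simulate_expression_cohort()` draws counts from a negative binomial with
mean `mu` and variance `mu + dispersion * mu^2` (default mean 2, dispersion
0.3), followed by binomial technical dropout whose probability decays with
the underlying mean, `dropout_rate * exp(-dropout_decay * mu)` (defaults 0.2
and 0.25). The decay matters: droplet protocols rarely zero strongly
expressed genes, and a uniform dropout would corrupt exactly the
highly-expressed marker genes a classifier depends on.

Planted structure, per dataset (default 7 datasets, 150 NF + 150 CAF + 100
non-fibroblast cells, 600 genes):

* fibroblast markers (a generic collagen/proteoglycan/PDGFR panel,
  `fibroblast_marker_panel()`) elevated 8-fold
  (`marker_log_fold_change = 3`) in NF and CAF cells — collagen-class
  markers separate fibroblasts by an order of magnitude in real data;
* `HIF1A` and `PRRX1` elevated ~2.8-fold (`log_fold_change = 1.5`) in the
  CAFs of **every** dataset, plus 3 dataset-private TFs from a 50-TF
  universe — fold changes typical of reported CAF TF screens;
* CAF cells split into iCAF and myCAF clusters, each with a planted 4-fold
  program (`caf_signatures()` returns matching synthetic signature sets;
  real signature lists are user-supplied GMT inputs);
* pseudotime: NF cells concentrated near 0 (Beta(1.5, 8)), CAF cells uniform
  on [0, 1], mimicking progressive NF→CAF differentiation; the coupled gene
  (`HIF1A`) carries a mean multiplier `exp(slope * (t - 0.5))`, centred so
  the plant does not inflate its baseline.

### Screen statistics

Differential testing uses the Wilcoxon–Mann–Whitney rank-sum test on
midranks. For `n1 * n2 <= 64` the p-value is exact — closed form without
ties, exhaustive enumeration of group assignments with ties — otherwise a
normal approximation with tie and continuity corrections. Benjamini–Hochberg
adjustment runs across the TF universe within each dataset; a TF is "up"
when adjusted p < 0.05 and log2 fold change > 0.25 (fold changes are
computed on de-logged means with a 1e-9 pseudocount to avoid infinities).
These thresholds are conventional defaults and are exposed as arguments.
The cross-dataset step is a plain exact intersection: a TF must be called up
in every dataset.

## Signature scoring

`ssgsea_score()` implements the single-sample enrichment statistic: with the
universe ordered by decreasing expression, the score is the sum over all
positions of the difference between the rank-weighted in-set empirical CDF
(weights `rank^alpha`, default `alpha = 0.25`) and the unweighted out-of-set
ECDF. It depends on the expression values only through their ranks (ties are
midranked; ordering ties break by gene id so results are deterministic), and
optional normalisation divides by the score range attainable at that set and
universe size. `running_es()` is the weighted Kolmogorov–Smirnov running sum
(hit steps `|statistic|^w` normalised over the set, miss steps
`1/(N - N_set)`); its walk ends at zero by construction and the enrichment
score is the signed maximal deviation. Because a single profile has no
phenotype labels to permute, significance uses a gene-set resampling null:
`p = (1 + #{|ES_perm| >= |ES_obs|}) / (n_perm + 1)`.

## Spatial model and pipeline

`simulate_if_roi()` renders a 640 × 640 μm field at 1 μm/pixel: two
capsule-shaped vessels (radius 12 μm), 300 fibroblasts and 120 other cells
placed without overlap (minimum separation 13 μm; placement failure after
bounded retries is an error that reports the achieved density). Nuclei are
isotropic Gaussian blobs (σ = 2 μm); fibroblast cytoplasm is an elongated
Gaussian (major σ = 7 μm, true eccentricity sampled in [0.88, 0.97]) on the
αSMA and IL-8 channels, other cells are rounder and dim. iCAFs are IL8-high
with moderate αSMA; myCAFs αSMA-high with background IL8. Gaussian
background noise (sd 4) is added everywhere.

The probability that a fibroblast is an iCAF follows a logistic curve in the
distance `d` to the nearest vessel wall:
`P(iCAF | d) = p_near + (p_far - p_near) / (1 + exp(-(d - 100)/20))`,
rising from 0.05 to 0.6 with midpoint 100 μm — encoding the physiological
observation that hypoxia (and with it the iCAF state) sets in ~100 μm from a
functional vessel, with a smooth transition since no functional form is
established.

Two geometry choices deserve emphasis:

* **Vessels sit at one side of the field** (`vessel_zone_frac = 0.12`),
  emulating an ROI anchored at a perivascular margin with tissue extending
  away. With vessels scattered in the field centre, distal bands have
  vanishing tissue area and raw band *counts* fall with distance even when
  the iCAF *density* keeps rising — a pure geometry artifact.
* **Cells are placed up to the field edges** (`margin_um = 0`; a cropped
  tissue field has cells at its borders) and **band tissue area excludes
  vessel-interior pixels**. Both are required for the per-band iCAF density
  to be unbiased; with either omitted, the reference region's density is
  systematically underestimated and the null calibration of the density
  test fails.

The analysis pipeline (`analyze_roi()`) is deterministic: Otsu binarisation
of the vessel channel with hole filling and minimum-area filtering; an exact
Euclidean distance transform scaled to μm (0 inside vessels — distance is
measured to the vessel wall, and cells overlapping a vessel are retained at
distance 0); DAPI smoothing, Otsu thresholding and watershed splitting for
nuclei; and phenotype calling per the tissue definition: CAF ⇔ αSMA-positive
and spindle-shaped (eccentricity ≥ 0.8), iCAF ⇔ CAF and IL8-positive,
myCAF ⇔ CAF and IL8-negative. Positivity thresholds default to Otsu over the
per-cell mean intensities; fixed thresholds are available for
reproducibility.

Since nuclei are round (and real fibroblast shape lives in the cytoplasm,
not the DAPI channel), eccentricity is measured on the αSMA cytoplasm: the
channel is Otsu-segmented, and the second moments of the binary component at
the cell's centroid give the eccentricity — a thresholded Gaussian blob
yields an ellipse with the blob's true axis ratio, so the estimator is
unbiased for the rendered shapes. Channel means (αSMA, IL-8) are taken over
the cell's own component pixels within 12 μm of the centroid; cells without
segmentable cytoplasm fall back to a 3–9 μm annulus. An earlier
intensity-moment design in a fixed window underestimated elongation under
noise and neighbour contamination and was replaced.

### Distance bands and the ratio test

The reference region is `[0, 100]` μm — closed above, so a cell at exactly
100 μm is perivascular — and subsequent bands are left-open/right-closed
50-μm intervals up to 400 μm; cells beyond are dropped and reported, and
band counts always partition the phenotyped CAFs. Per ROI, each band's iCAF
count is divided by the reference count (ROIs with a zero reference are
excluded with a warning; a pseudocount mode exists). Two read-outs are
produced per band:

* the **headline ratio test** — a two-tailed Mann–Whitney of the across-ROI
  ratio sample against the reference's unit ratios. This mirrors the
  published figure quantity, but testing against a zero-variance pseudo-
  sample behaves like a sign test: with 7 ROIs, 6-of-7 ratios on one side
  of 1 already rejects. It is reported as the figure-analogue statistic,
  not as a calibrated test;
* the **density test** (`p_density`) — a two-tailed Mann–Whitney comparing
  the band's per-ROI iCAF densities (count / band tissue area) against the
  reference's per-ROI densities: two genuine samples, calibrated under a
  flat gradient (measured type-I ≈ 0.05 at α = 0.05 over flat-null
  cohorts). This is the statistic to trust when band areas differ from the
  reference area.

## Numerical and degenerate-input policy

All randomness flows from explicit integer seeds (the pipeline derives
per-stage substreams from one config seed); identical config + seed
reproduces outputs bitwise. Zero-variance inputs error rather than return
NaN (correlations, Otsu on constant vectors); an all-tied rank-sum returns
p = 1; blank DAPI yields an empty cell table with a warning, while an empty
vessel mask is an error because distance bands are undefined without a
vessel. Watershed tolerance (0.01 on unit-normalised intensity) splits
nuclei 5 μm apart at the default pixel size without fragmenting single
nuclei at the rendered noise level.

## What the tests do and do not show

The test suite validates the statistics against independent brute-force
oracles (exhaustive rank-sum enumeration, hand-expanded ECDF walks, pixel-
by-pixel distance minimisation, exhaustive gene-set nulls), recovers every
planted effect (common TFs, fibroblast labels, phenotypes, the spatial
gradient: distal-band p < 0.05 on 7 default ROIs), and checks null
calibration (TF screen under label-free nulls, flat-gradient band test,
Fisher-z coverage). Problem sizes in the routine suite are scaled to run in
a couple of minutes (e.g. 360-px ROIs, 20-seed recovery batches, ~200
flat-null cohorts); they are statements about this data model, not about
tissue: the simulator has no stain unmixing problems, no uneven
illumination, no 3-D sectioning effects, no perfusion heterogeneity, and
its cells do not touch. Passing here demonstrates the computations are
correct and calibrated, not that real slides will segment this cleanly.

## Known limitations

* Pseudotime is an input (or simulated); no trajectory inference.
* No clustering/embedding; CAF subtype clusters are inputs.
* The kernel-CDF single-sample variant of signature scoring is out of
  scope; only the rank-ECDF (ssGSEA) statistic is implemented.
* Whether published per-band counts were area-normalised is unknown; both
  raw-count and density statistics are emitted, raw counts as the primary
  figure analogue.
* Vessel "functionality" is taken as lectin positivity plus a minimum area;
  no lumen or perfusion criterion.
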