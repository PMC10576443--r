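Package: icaftools
Title: Hypoxia-Driven Inflammatory CAF Analysis in Expression and Tissue Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how hypoxia shapes inflammatory cancer-associated
    fibroblasts (iCAFs). Implements a cross-dataset transcription-factor screen
    (per-dataset Wilcoxon rank-sum differential expression with Benjamini-Hochberg
    adjustment and exact intersection of up-regulated sets), single-sample gene-set
    enrichment scoring (the rank-weighted ECDF-difference ssGSEA statistic and the
    weighted Kolmogorov-Smirnov running-sum enrichment score with a gene-set
    permutation null), pseudotime-expression correlation with Fisher-z confidence
    intervals, and a spatial pipeline that segments blood vessels in multi-channel
    immunofluorescence images, maps micrometre-calibrated Euclidean distances,
    detects cells, calls IL8-alphaSMA double-positive spindle-shaped iCAFs, bins them
    into 50-um distance bands and tests band ratios against the <=100 um perivascular
    reference. Ships seeded synthetic-data generators for expression cohorts and
    tissue regions with ground truth, so every stage is testable against planted
    effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
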