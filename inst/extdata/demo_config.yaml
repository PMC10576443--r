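# Demonstration pipeline configuration: a scaled-down end-to-end run
# (2 expression datasets, 3 tissue ROIs) that finishes in about a minute.
seed: 42
out_dir: icaftools_demo_out
cohort:
  n_datasets: 2
  n_cells_per_group: 80
  n_other_cells: 40
  n_genes: 200
  tf_universe_size: 30
spatial:
  n_rois: 3
  roi:
    image_shape: [480, 480]
    n_fibroblasts: 170
    n_other_cells: 70
  band:
    max_distance_um: 400
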