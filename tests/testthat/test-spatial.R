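# a small rendered ROI reused across the heavier spatial tests
roi_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_if_roi(roi_sim_config(image_shape = c(360L, 360L),
                                               n_fibroblasts = 110,
                                               n_other_cells = 40, seed = 8),
                                roi_id = "fix1")
    cache
  }
})

test_that("distance map is exact against the brute-force oracle", {
  set.seed(31)
  for (i in 1:12) {
    m <- matrix(runif(400) < 0.08, 20, 20)
    if (!any(m)) m[7, 13] <- TRUE
    px <- sample(c(0.5, 1, 2), 1)
    d <- distance_map(m, pixel_size_um = px)
    expect_equal(unclass(d), brute_distance_map(m, px),
                 ignore_attr = TRUE, tolerance = 1e-9)
    expect_true(all(d[m] == 0))
  }
  # 3-4-5 triangle
  m <- matrix(FALSE, 8, 8); m[1, 1] <- TRUE
  d <- distance_map(m, pixel_size_um = 1)
  expect_equal(d[4, 5], 5.0)
  # full mask -> all zeros; empty mask -> error
  expect_true(all(distance_map(matrix(TRUE, 4, 4), 1) == 0))
  expect_error(distance_map(matrix(FALSE, 4, 4), 1), "empty")
})

test_that("distance field is 1-Lipschitz on the pixel grid", {
  set.seed(32)
  m <- matrix(runif(900) < 0.02, 30, 30); m[5, 5] <- TRUE
  d <- distance_map(m, pixel_size_um = 2)
  step_r <- abs(diff(unclass(d)))
  step_c <- abs(t(diff(t(unclass(d)))))
  expect_lte(max(step_r), 2 + 1e-9)          # axial neighbours: <= pixel size
  expect_lte(max(step_c), 2 + 1e-9)
})

test_that("vessel segmentation recovers capsules and filters small debris", {
  sim <- roi_fixture()
  mask <- segment_vessels(sim$image)
  truth_field <- vessel_distance_field(sim$vessels, c(360L, 360L), 1)
  truth_mask <- truth_field == 0
  iou <- sum(mask & truth_mask) / sum(mask | truth_mask)
  expect_gte(iou, 0.8)

  # all-zero channel errors
  blank <- sim$image
  blank$channels$VESSEL[] <- 0
  expect_error(segment_vessels(blank), "no functional vessel")

  # of two components only the one above the minimum area survives
  img <- matrix(0, 60, 60)
  img[10:40, 10:14] <- 100      # 155 px
  img[50:51, 50:51] <- 100      # 4 px
  mc <- multichannel_image(list(DAPI = img * 0, ASMA = img * 0, IL8 = img * 0,
                                VESSEL = img), pixel_size_um = 1)
  m <- segment_vessels(mc, min_area_um2 = 50, method = "fixed", threshold = 50)
  expect_true(all(m[10:40, 10:14]))
  expect_false(any(m[50:51, 50:51]))
})

test_that("cell detection recovers simulated cells and splits close nuclei", {
  sim <- roi_fixture()
  cells <- detect_cells(sim$image)
  m <- match_cells(cells, sim$truth)
  recall <- length(unique(stats::na.omit(m))) / nrow(sim$truth)
  precision <- mean(!is.na(m))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  expect_true(all(cells$row_px >= 0 & cells$row_px <= 359))
  expect_true(all(cells$eccentricity >= 0 & cells$eccentricity <= 1))

  # blank DAPI -> empty table with a warning, not an error
  blank <- sim$image
  blank$channels$DAPI[] <- 0
  expect_warning(empty <- detect_cells(blank), "no cells")
  expect_equal(nrow(empty), 0)

  # two nuclei 5 um apart are split by the watershed
  H <- 48
  g <- function(r0, c0, s) {
    r <- matrix(rep(1:H, H), H); cc <- t(r)
    exp(-((r - r0)^2 + (cc - c0)^2) / (2 * s^2))
  }
  set.seed(33)
  dapi <- 180 * (g(24, 22, 2) + g(24, 27, 2)) +
    pmax(matrix(rnorm(H * H, 0, 3), H), 0)
  two <- multichannel_image(list(DAPI = dapi, ASMA = dapi * 0, IL8 = dapi * 0,
                                 VESSEL = dapi * 0 + 1e-6), pixel_size_um = 1)
  got <- detect_cells(two)
  expect_equal(nrow(got), 2)
  expect_lt(abs(diff(sort(got$col_px)[1:2]) - 5), 2)
})

test_that("phenotype calling follows the double-positive spindle definition", {
  cells <- data.frame(cell = c("a", "b", "c", "d"),
                      row_px = 1, col_px = 1, area_px = 30L, area_um2 = 30,
                      eccentricity = c(0.9, 0.1, 0.9, 0.9),
                      mean_DAPI = 100,
                      mean_ASMA = c(80, 80, 80, 5),
                      mean_IL8 = c(90, 90, 4, 90))
  got <- call_phenotypes(cells, thresholds = list(mode = "fixed",
                                                  ASMA = 40, IL8 = 40))
  # double positive + spindle = iCAF; round cell = other;
  # ASMA-only spindle = myCAF; ASMA-negative = other
  expect_equal(got$phenotype, c("iCAF", "other", "myCAF", "other"))
  expect_error(call_phenotypes(cells[1, ]), "fixed thresholds")
})

test_that("phenotyping on a rendered ROI matches planted truth", {
  sim <- roi_fixture()
  cells <- call_phenotypes(detect_cells(sim$image))
  m <- match_cells(cells, sim$truth)
  ok <- !is.na(m)
  acc <- mean(cells$phenotype[ok] == sim$truth$phenotype[m[ok]])
  expect_gte(acc, 0.85)
})

test_that("band conventions: closed reference, left-open bands, conservation", {
  cfg <- band_config(reference_max_um = 100, band_width_um = 50,
                     max_distance_um = 300)
  fld <- structure(matrix(c(0, 50, 100, 100.1, 150, 250, 299, 301, 20),
                          3, 3), pixel_size_um = 1, class = "distance_field")
  cells <- data.frame(cell = paste0("c", 1:9),
                      row_px = rep(0:2, 3), col_px = rep(0:2, each = 3),
                      phenotype = c("iCAF", "iCAF", "myCAF", "iCAF", "myCAF",
                                    "iCAF", "other", "iCAF", "iCAF"))
  bc <- band_assign_and_count(cells, fld, cfg)
  # cell at exactly 100 um -> reference; at 100.1 -> (100,150]
  expect_equal(bc$cells$band[3], "[0,100]")
  expect_equal(bc$cells$band[4], "(100,150]")
  # partition conservation including dropped cells beyond 300 um
  n_caf <- sum(cells$phenotype %in% c("iCAF", "myCAF"))
  expect_equal(sum(bc$bands$n_caf_total) + bc$dropped_caf, n_caf)
  expect_equal(sum(bc$bands$n_icaf) + bc$dropped_icaf,
               sum(cells$phenotype == "iCAF"))
  expect_equal(bc$dropped_caf, 1)   # the 301-um iCAF
  expect_error(band_config(reference_max_um = 80, band_width_um = 50),
               "multiple")
})

test_that("relative ratios: arithmetic, degenerate equality and zero reference", {
  mk <- function(icaf, roi) {
    cfg <- band_config(max_distance_um = 200)
    bands <- data.frame(band = cfg$labels, lo = utils::head(cfg$breaks, -1),
                        hi = cfg$breaks[-1], n_icaf = icaf,
                        n_caf_total = icaf + 2, area_um2 = c(100, 100, 100))
    structure(list(bands = bands, dropped_icaf = 0L, dropped_caf = 0L,
                   cells = NULL, roi_id = roi, config = cfg),
              class = "band_counts")
  }
  rr <- relative_ratios(list(mk(c(2, 4, 6), "r1"), mk(c(2, 4, 6), "r2"),
                             mk(c(2, 4, 6), "r3")))
  expect_equal(unname(rr$ratios[, 2]), rep(2, 3))
  expect_equal(unname(rr$ratios[, 3]), rep(3, 3))

  # identical counts in every band -> all ratios 1, p = 1
  flat <- relative_ratios(list(mk(c(3, 3, 3), "r1"), mk(c(3, 3, 3), "r2")))
  expect_true(all(flat$ratios == 1))
  expect_true(all(flat$summary$p == 1))

  expect_warning(
    zr <- relative_ratios(list(mk(c(0, 4, 6), "r1"), mk(c(2, 4, 6), "r2"),
                               mk(c(2, 4, 6), "r3"))),
    "zero reference")
  expect_equal(zr$excluded_rois, "r1")
  expect_equal(nrow(zr$ratios), 2)
  expect_error(relative_ratios(list(mk(c(1, 1, 1), "r1"))), "at least 2")
})

test_that("full ROI pipeline conserves counts and recovers truth-level ratios", {
  sim <- roi_fixture()
  bc <- analyze_roi(sim$image, band_config(max_distance_um = 300))
  n_caf <- sum(bc$cells$phenotype %in% c("iCAF", "myCAF"))
  expect_equal(sum(bc$bands$n_caf_total) + bc$dropped_caf, n_caf)

  # pipeline band iCAF counts track ground-truth band counts
  fld <- vessel_distance_field(sim$vessels, c(360L, 360L), 1)
  tb <- band_assign_and_count(sim$truth, fld,
                              band_config(max_distance_um = 300))
  expect_gt(stats::cor(bc$bands$n_icaf, tb$bands$n_icaf), 0.9)
})
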