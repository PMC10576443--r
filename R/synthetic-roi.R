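#' Configuration for the immunofluorescence ROI simulator
#'
#' Defaults describe the emulated tissue field: a 640 x 640 um region at
#' 1 um/pixel with two capsule-shaped blood vessels, ~300 fibroblasts and
#' ~120 other (non-fibroblast) cells, and a logistic phenotype gradient in
#' which the probability that a fibroblast carries the iCAF phenotype rises
#' from `p_icaf_near` to `p_icaf_far` with midpoint ~100 um from the vessel
#' wall — the distance at which hypoxia typically sets in around a functional
#' vessel.
#'
#' @param image_shape `c(height, width)` in pixels.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param n_vessels number of vessels (straight capsules).
#' @param vessel_radius_um capsule radius in um.
#' @param vessel_zone_frac fraction of the image width (left side) within
#'   which vessels are placed. The field emulates a region anchored at a
#'   perivascular margin with tissue extending away from it, so that every
#'   distance band keeps substantial tissue area; set to 1 for vessels
#'   scattered anywhere.
#' @param n_fibroblasts,n_other_cells cell counts to place.
#' @param gradient_midpoint_um logistic midpoint of the iCAF gradient (um).
#' @param gradient_steepness logistic scale (um); smaller = sharper.
#' @param p_icaf_near,p_icaf_far asymptotic iCAF probabilities near/far from
#'   the vessel wall.
#' @param intensity_model per-channel / per-phenotype amplitude `c(mean, sd)`
#'   list; see defaults. iCAFs are IL8-high with moderate aSMA, myCAFs
#'   aSMA-high with background IL8, other cells background in both.
#' @param background_noise_sd additive Gaussian noise sd on every channel.
#' @param nucleus_sigma_um isotropic Gaussian sigma of the DAPI nucleus blob.
#' @param cytoplasm_sigma_um major-axis Gaussian sigma of the elongated
#'   cytoplasm blob of fibroblasts.
#' @param fibro_eccentricity_range,other_eccentricity_range sampled true
#'   eccentricity ranges (fibroblasts are spindle-shaped, others round-ish).
#' @param min_separation_um minimum distance between cell centroids.
#' @param margin_um placement margin from the image border (default 0: a
#'   cropped tissue field has cells up to its edges).
#' @param seed integer seed.
#' @return validated list of class `roi_sim_config`.
#' @export
roi_sim_config <- function(image_shape = c(640L, 640L),
                           pixel_size_um = 1,
                           n_vessels = 2L,
                           vessel_radius_um = 12,
                           vessel_zone_frac = 0.12,
                           n_fibroblasts = 300L,
                           n_other_cells = 120L,
                           gradient_midpoint_um = 100,
                           gradient_steepness = 20,
                           p_icaf_near = 0.05,
                           p_icaf_far = 0.6,
                           intensity_model = NULL,
                           background_noise_sd = 4,
                           nucleus_sigma_um = 2,
                           cytoplasm_sigma_um = 7,
                           fibro_eccentricity_range = c(0.88, 0.97),
                           other_eccentricity_range = c(0.1, 0.5),
                           min_separation_um = 13,
                           margin_um = 0,
                           seed = 1L) {
  if (is.null(intensity_model)) intensity_model <- default_intensity_model()
  cfg <- list(image_shape = as.integer(image_shape),
              pixel_size_um = pixel_size_um,
              n_vessels = as.integer(n_vessels),
              vessel_radius_um = vessel_radius_um,
              vessel_zone_frac = vessel_zone_frac,
              n_fibroblasts = as.integer(n_fibroblasts),
              n_other_cells = as.integer(n_other_cells),
              gradient_midpoint_um = gradient_midpoint_um,
              gradient_steepness = gradient_steepness,
              p_icaf_near = p_icaf_near,
              p_icaf_far = p_icaf_far,
              intensity_model = intensity_model,
              background_noise_sd = background_noise_sd,
              nucleus_sigma_um = nucleus_sigma_um,
              cytoplasm_sigma_um = cytoplasm_sigma_um,
              fibro_eccentricity_range = fibro_eccentricity_range,
              other_eccentricity_range = other_eccentricity_range,
              min_separation_um = min_separation_um,
              margin_um = margin_um,
              seed = as.integer(seed))
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 32L))
    stop("image_shape must be two pixel sizes >= 32")
  assert_scalar_pos(cfg$pixel_size_um, "pixel_size_um")
  assert_scalar_pos(cfg$vessel_radius_um, "vessel_radius_um")
  assert_scalar_pos(cfg$gradient_midpoint_um, "gradient_midpoint_um")
  assert_scalar_pos(cfg$gradient_steepness, "gradient_steepness")
  if (cfg$n_vessels < 1L) stop("n_vessels must be >= 1")
  if (cfg$vessel_zone_frac <= 0 || cfg$vessel_zone_frac > 1)
    stop("vessel_zone_frac must lie in (0, 1]")
  for (p in c("p_icaf_near", "p_icaf_far"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(sprintf("'%s' must lie in [0, 1]", p))
  if (cfg$p_icaf_near > cfg$p_icaf_far)
    stop("p_icaf_near must be <= p_icaf_far for a positive gradient")
  if (!identical(sort(names(intensity_model$phenotypes)),
                 sort(c("iCAF", "myCAF", "other"))))
    stop("intensity_model$phenotypes must cover iCAF, myCAF, other")
  structure(cfg, class = "roi_sim_config")
}

default_intensity_model <- function() {
  list(DAPI = c(mean = 180, sd = 15),
       VESSEL = c(mean = 220, sd = 10),
       phenotypes = list(
         iCAF  = list(ASMA = c(mean = 120, sd = 12), IL8 = c(mean = 180, sd = 15)),
         myCAF = list(ASMA = c(mean = 200, sd = 15), IL8 = c(mean = 15,  sd = 6)),
         other = list(ASMA = c(mean = 12,  sd = 6),  IL8 = c(mean = 12,  sd = 6))))
}

#' Analytic distance field of simulated vessel geometry
#'
#' Evaluates the exact distance (um) from every pixel to the nearest capsule
#' vessel boundary, straight from the simulator's geometry — no rendering or
#' image-based transform involved. Useful as ground truth against the
#' image-derived [distance_map()] and for count-level studies with
#' `render = FALSE`.
#'
#' @param vessels vessel list as returned by [simulate_if_roi()].
#' @param image_shape `c(height, width)` in pixels.
#' @param pixel_size_um pixel size.
#' @return a `distance_field` matrix.
#' @export
vessel_distance_field <- function(vessels, image_shape, pixel_size_um) {
  H <- image_shape[1]; W <- image_shape[2]
  rr <- rep(0:(H - 1), W); cc <- rep(0:(W - 1), each = H)
  d <- capsule_distance_um(rr, cc, vessels, pixel_size_um)
  structure(matrix(d, H, W), pixel_size_um = pixel_size_um,
            class = "distance_field")
}

# distance (um) from points (r, c in px, 0-based) to the boundary of the
# nearest capsule vessel; 0 inside a vessel
capsule_distance_um <- function(r_px, c_px, vessels, pixel_size_um) {
  d <- rep(Inf, length(r_px))
  for (v in vessels) {
    ar <- v$a[1]; ac <- v$a[2]; br <- v$b[1]; bc <- v$b[2]
    vr <- br - ar; vc <- bc - ac
    len2 <- vr^2 + vc^2
    t <- if (len2 == 0) rep(0, length(r_px)) else
      pmin(1, pmax(0, ((r_px - ar) * vr + (c_px - ac) * vc) / len2))
    seg <- sqrt((r_px - (ar + t * vr))^2 + (c_px - (ac + t * vc))^2)
    d <- pmin(d, pmax(0, seg * pixel_size_um - v$radius_um))
  }
  d
}

#' Simulate a multi-channel immunofluorescence ROI with ground truth
#'
#' Places capsule vessels and non-overlapping cells, draws each fibroblast's
#' phenotype from the logistic distance gradient `P(iCAF | d)`, and (unless
#' `render = FALSE`) renders DAPI / ASMA / IL8 / VESSEL channels: isotropic
#' Gaussian nuclei, elongated Gaussian cytoplasm for fibroblasts (supporting
#' the spindle-shape criterion), solid bright capsules on the vessel channel,
#' and additive Gaussian background noise.
#'
#' @param config a [roi_sim_config()].
#' @param render if `FALSE`, skip pixel rendering and return only the ground
#'   truth table (fast path for count-level calibration studies).
#' @param roi_id identifier stored in the image object.
#' @return list with `image` (a `mc_image`, or `NULL`), `truth` (data.frame:
#'   `cell`, `row_px`, `col_px` (0-based), `phenotype`, `distance_um`,
#'   `eccentricity_true`, `is_fibroblast`) and `vessels` (capsule geometry).
#' @export
simulate_if_roi <- function(config = roi_sim_config(), render = TRUE,
                            roi_id = "roi1") {
  stopifnot(inherits(config, "roi_sim_config"))
  H <- config$image_shape[1]; W <- config$image_shape[2]
  px <- config$pixel_size_um
  with_seed(config$seed, {
    zone <- max(1, config$vessel_zone_frac * (W - 1))
    vessels <- lapply(seq_len(config$n_vessels), function(i)
      list(a = c(stats::runif(1, 0, H - 1), stats::runif(1, 0, zone)),
           b = c(stats::runif(1, 0, H - 1), stats::runif(1, 0, zone)),
           radius_um = config$vessel_radius_um))

    n_total <- config$n_fibroblasts + config$n_other_cells
    margin_px <- config$margin_um / px
    min_sep_px <- config$min_separation_um / px
    rows <- numeric(0); cols <- numeric(0)
    tries <- 0L; max_tries <- 300L * n_total
    while (length(rows) < n_total) {
      if (tries >= max_tries)
        stop(sprintf(
          "could not place %d cells without overlap (placed %d, density %.1f cells/mm^2); reduce cell counts or min_separation_um",
          n_total, length(rows),
          length(rows) / (H * W * px^2 / 1e6)))
      tries <- tries + 1L
      r <- stats::runif(1, margin_px, H - 1 - margin_px)
      cc <- stats::runif(1, margin_px, W - 1 - margin_px)
      if (capsule_distance_um(r, cc, vessels, px) <= 2) next
      if (length(rows) &&
          min((rows - r)^2 + (cols - cc)^2) < min_sep_px^2) next
      rows <- c(rows, r); cols <- c(cols, cc)
    }

    is_fib <- c(rep(TRUE, config$n_fibroblasts),
                rep(FALSE, config$n_other_cells))
    d_um <- capsule_distance_um(rows, cols, vessels, px)
    p_icaf <- logistic_gradient(d_um, config$p_icaf_near, config$p_icaf_far,
                                config$gradient_midpoint_um,
                                config$gradient_steepness)
    phenotype <- rep("other", n_total)
    is_icaf <- is_fib & stats::runif(n_total) < p_icaf
    phenotype[is_fib] <- ifelse(is_icaf[is_fib], "iCAF", "myCAF")
    ecc <- ifelse(is_fib,
                  stats::runif(n_total, config$fibro_eccentricity_range[1],
                               config$fibro_eccentricity_range[2]),
                  stats::runif(n_total, config$other_eccentricity_range[1],
                               config$other_eccentricity_range[2]))
    theta <- stats::runif(n_total, 0, pi)
    truth <- data.frame(cell = sprintf("cell%04d", seq_len(n_total)),
                        row_px = rows, col_px = cols,
                        phenotype = phenotype, distance_um = d_um,
                        eccentricity_true = ecc, is_fibroblast = is_fib,
                        stringsAsFactors = FALSE)

    image <- if (render)
      render_roi(config, vessels, truth, theta, roi_id) else NULL
    list(image = image, truth = truth, vessels = vessels)
  })
}

render_roi <- function(cfg, vessels, truth, theta, roi_id) {
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]; px <- cfg$pixel_size_um
  im <- cfg$intensity_model
  env <- new.env(parent = emptyenv())
  for (nm in c("DAPI", "ASMA", "IL8", "VESSEL"))
    assign(nm, matrix(0, H, W), envir = env)

  # vessel channel: bright inside the capsules
  rr <- matrix(rep(0:(H - 1), W), H); cc <- matrix(rep(0:(W - 1), each = H), H)
  inside <- capsule_distance_um(as.numeric(rr), as.numeric(cc), vessels, px) == 0
  env$VESSEL[inside] <- pmax(0, stats::rnorm(sum(inside), im$VESSEL["mean"],
                                             im$VESSEL["sd"]))

  ns <- cfg$nucleus_sigma_um / px
  cs <- cfg$cytoplasm_sigma_um / px
  for (i in seq_len(nrow(truth))) {
    r0 <- truth$row_px[i]; c0 <- truth$col_px[i]
    ph <- truth$phenotype[i]
    amp_d <- max(0, stats::rnorm(1, im$DAPI["mean"], im$DAPI["sd"]))
    add_gaussian_blob(env, "DAPI", r0, c0, ns, ns, 0, amp_d)
    minor <- cs * sqrt(1 - truth$eccentricity_true[i]^2)
    major <- if (truth$is_fibroblast[i]) cs else 0.6 * cs
    for (channel in c("ASMA", "IL8")) {
      pars <- im$phenotypes[[ph]][[channel]]
      amp <- max(0, stats::rnorm(1, pars["mean"], pars["sd"]))
      if (amp > 0)
        add_gaussian_blob(env, channel, r0, c0, major, minor, theta[i], amp)
    }
  }
  ch <- lapply(stats::setNames(nm = c("DAPI", "ASMA", "IL8", "VESSEL")),
               function(nm) get(nm, envir = env))
  if (cfg$background_noise_sd > 0)
    ch <- lapply(ch, function(m) {
      m <- m + matrix(stats::rnorm(H * W, 0, cfg$background_noise_sd), H, W)
      m[m < 0] <- 0
      m
    })
  multichannel_image(ch, pixel_size_um = px, roi_id = roi_id)
}

# adds an anisotropic Gaussian blob to the channel matrix bound in `env`
add_gaussian_blob <- function(env, name, r0, c0, s_major, s_minor, theta, amp) {
  mat <- get(name, envir = env)
  H <- nrow(mat); W <- ncol(mat)
  ext <- ceiling(3.5 * max(s_major, s_minor))
  r1 <- max(0, floor(r0) - ext); r2 <- min(H - 1, ceiling(r0) + ext)
  c1 <- max(0, floor(c0) - ext); c2 <- min(W - 1, ceiling(c0) + ext)
  rs <- r1:r2; cs <- c1:c2
  dr <- matrix(rep(rs - r0, length(cs)), length(rs))
  dc <- matrix(rep(cs - c0, each = length(rs)), length(rs))
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  blob <- amp * exp(-(u^2 / (2 * s_major^2) + v^2 / (2 * s_minor^2)))
  env[[name]][rs + 1, cs + 1] <- mat[rs + 1, cs + 1] + blob
  invisible(NULL)
}
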