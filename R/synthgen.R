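# Seeded phantom and plate-data generators with recorded ground truth.
# These stand in for animal-derived inputs: double-stained coronal slices
# (TTC-red viable tissue, pale infarct wedge, Evans-blue core, ipsilateral
# swelling) and linear fluorescence-concentration plate reads.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Phantom generation parameters
#'
#' Describes one synthetic 6-slice brain: two mirrored ellipses per slice
#' (hemispheres), the right one inflated by `swelling_factor`, with an
#' angular wedge of the right ellipse painted as pale infarct and an inner
#' portion of that wedge overlaid with Evans blue.
#'
#' @param n_slices number of coronal slices (default 6, for 2 mm
#'   sectioning of a rat brain).
#' @param hemisphere_radii_px per-slice ellipse semi-axes: a 2-column
#'   matrix (x, y semi-axis in px), recycled/truncated to `n_slices`.
#'   Defaults taper toward the rostral and caudal ends.
#' @param swelling_factor right-hemisphere area multiplier (>= 0.8);
#'   1 = no edema.
#' @param infarct_fraction infarcted fraction of right-hemisphere area,
#'   in \[0, 0.5\].
#' @param eb_fraction fraction of the infarct area covered by the Evans
#'   blue overlay, in \[0, 1\].
#' @param colors named list of RGB triplets: `viable` (TTC red), `infarct`
#'   (pale cream), `eb` (dark blue), `background`.
#' @param noise_sd per-channel Gaussian noise sd in intensity units
#'   (default 6).
#' @param width,height canvas size per slice in px.
#' @param seed integer seed; identical seeds give bit-identical images.
#' @return validated list of class `phantom_params`.
#' @export
phantom_params <- function(n_slices = 6,
                           hemisphere_radii_px = NULL,
                           swelling_factor = 1.0,
                           infarct_fraction = 0.0,
                           eb_fraction = 0.0,
                           colors = list(viable = c(190, 40, 40),
                                         infarct = c(240, 228, 205),
                                         eb = c(45, 45, 170),
                                         background = c(255, 255, 255)),
                           noise_sd = 6,
                           width = 160, height = 120,
                           seed = NULL) {
  if (is.null(hemisphere_radii_px)) {
    a <- c(26, 30, 32, 32, 30, 26)
    b <- c(38, 44, 48, 48, 44, 38)
    idx <- rep_len(seq_along(a), n_slices)
    hemisphere_radii_px <- cbind(a[idx], b[idx])
  }
  hemisphere_radii_px <- matrix(hemisphere_radii_px, ncol = 2)
  if (nrow(hemisphere_radii_px) != n_slices)
    hemisphere_radii_px <-
      hemisphere_radii_px[rep_len(seq_len(nrow(hemisphere_radii_px)),
                                  n_slices), , drop = FALSE]
  if (swelling_factor < 0.8)
    stop("`swelling_factor` must be >= 0.8", call. = FALSE)
  if (infarct_fraction < 0 || infarct_fraction > 0.5)
    stop("`infarct_fraction` must lie in [0, 0.5]", call. = FALSE)
  if (eb_fraction < 0 || eb_fraction > 1)
    stop("`eb_fraction` must lie in [0, 1]", call. = FALSE)
  for (nm in c("viable", "infarct", "eb", "background")) {
    cl <- colors[[nm]]
    if (is.null(cl) || length(cl) != 3 || any(cl < 0) || any(cl > 255))
      stop("colors$", nm, " must be an RGB triplet in 0-255", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(n_slices = n_slices,
                 hemisphere_radii_px = hemisphere_radii_px,
                 swelling_factor = swelling_factor,
                 infarct_fraction = infarct_fraction,
                 eb_fraction = eb_fraction,
                 colors = colors, noise_sd = noise_sd,
                 width = width, height = height, seed = seed),
            class = "phantom_params")
}

# paint one slice; returns list(pixels = noiseless H x W x 3, masks)
render_slice <- function(p, k) {
  w <- p$width; h <- p$height
  a <- p$hemisphere_radii_px[k, 1]; b <- p$hemisphere_radii_px[k, 2]
  s <- sqrt(p$swelling_factor)
  ar <- a * s; br <- b * s
  midx <- w / 2; cy <- h / 2
  xl <- midx - (a + 4); xr <- midx + (ar + 4)
  # pixel centers
  x <- matrix(rep(seq_len(w) - 0.5, each = h), nrow = h)
  y <- matrix(rep(seq_len(h) - 0.5, times = w), nrow = h)
  left <- ((x - xl) / a)^2 + ((y - cy) / b)^2 <= 1
  u <- (x - xr) / ar; v <- (y - cy) / br
  r2 <- u^2 + v^2
  right <- r2 <= 1
  # lateral (away from midline) wedge: parametric sector of the ellipse,
  # whose area fraction equals its parametric angle fraction exactly
  half <- pi * p$infarct_fraction
  ang <- atan2(v, u)
  infarct <- right & p$infarct_fraction > 0 & ang > -half & ang <= half
  eb <- infarct & p$eb_fraction > 0 & r2 <= p$eb_fraction
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    m <- matrix(p$colors$background[ch], h, w)
    m[left | right] <- p$colors$viable[ch]
    m[infarct] <- p$colors$infarct[ch]
    m[eb] <- p$colors$eb[ch]
    px[, , ch] <- m
  }
  list(pixels = px,
       masks = list(left = left, right = right, infarct = infarct, eb = eb))
}

#' Generate a phantom brain with ground truth
#'
#' Renders `n_slices` phantom slice images and records the painted pixel
#' counts before noise, plus the true brain-level metrics computed from
#' those counts with the package's own formulas.
#'
#' @param params a [phantom_params()].
#' @return list with `images` (list of [slice_image()]) and `truth`: a list
#'   holding `per_slice` (painted left/right/infarct/eb counts),
#'   `infarct_percent`, `edema_percent`, `bbb_percent` (both
#'   normalizations for infarct), and `params`.
#' @export
generate_brain <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(params$seed, {
    images <- vector("list", params$n_slices)
    rows <- vector("list", params$n_slices)
    for (k in seq_len(params$n_slices)) {
      r <- render_slice(params, k)
      px <- r$pixels
      if (params$noise_sd > 0) {
        px <- px + array(rnorm(length(px), 0, params$noise_sd), dim = dim(px))
        px <- clamp(round(px), 0, 255)
      }
      images[[k]] <- slice_image(px, slice_index = k)
      rows[[k]] <- data.frame(
        slice_index = k,
        left_area_px = sum(r$masks$left),
        right_area_px = sum(r$masks$right),
        infarct_area_px = sum(r$masks$infarct),
        blue_area_px = sum(r$masks$eb))
    }
    per_slice <- do.call(rbind, rows)
    bm <- suppressWarnings(aggregate_slices(per_slice, brain_id = "truth"))
    truth <- list(
      per_slice = per_slice,
      left_total_px = bm$left_total_px,
      right_total_px = bm$right_total_px,
      infarct_total_px = bm$infarct_total_px,
      eb_total_px = bm$blue_total_px,
      infarct_percent = infarct_percent(bm, "total_brain"),
      infarct_percent_contralateral = infarct_percent(bm, "contralateral"),
      edema_percent = edema_percent(bm),
      bbb_percent = bbb_image_percent(bm),
      params = params)
    list(images = images, truth = truth)
  })
}

#' Generate synthetic plate data from known extravasation indices
#'
#' Forward-simulates the fluorometric workflow: each sample's true ng/g
#' index is converted to the concentration of its diluted supernatant
#' (`index * weight / (dilution * volume)`), pushed through a linear
#' fluorescence response, and read with additive Gaussian noise. A standard
#' series (0--2000 ng per 200 uL well) is emitted alongside.
#'
#' @param truth_ng_per_g numeric vector of true indices (ng/g).
#' @param tissue_weight_g sample weights in g (recycled).
#' @param curve_slope,curve_intercept linear response (a.u. per ng/mL,
#'   a.u.).
#' @param noise_sd additive read noise sd (a.u.).
#' @param dilution_factor,homogenate_volume_ml as in
#'   [extravasation_index()].
#' @param standards_ng amounts for the standard series (ng per well).
#' @param well_volume_ml standard well volume (mL).
#' @param ttc_effect multiplicative perturbation of sample fluorescence
#'   (1 = none), emulating TTC interference.
#' @param ttc_condition condition label attached to the emitted rows.
#' @param seed integer seed.
#' @return list with `standards`, `samples` and `truth` data.frames.
#' @export
generate_plate_data <- function(truth_ng_per_g,
                                tissue_weight_g = 0.5,
                                curve_slope = 3, curve_intercept = 40,
                                noise_sd = 0,
                                dilution_factor = 4,
                                homogenate_volume_ml = 1,
                                standards_ng = c(0, 50, 100, 250, 500,
                                                 1000, 1500, 2000),
                                well_volume_ml = 0.2,
                                ttc_effect = 1,
                                ttc_condition = "0%",
                                seed = NULL) {
  if (any(truth_ng_per_g < 0))
    stop("true indices must be non-negative", call. = FALSE)
  if (curve_slope <= 0) stop("`curve_slope` must be positive", call. = FALSE)
  if (any(tissue_weight_g <= 0) || homogenate_volume_ml <= 0)
    stop("weights and volumes must be positive", call. = FALSE)
  n <- length(truth_ng_per_g)
  tissue_weight_g <- rep_len(tissue_weight_g, n)
  with_seed(seed, {
    sc <- standards_ng / well_volume_ml
    standards <- data.frame(
      well = sprintf("S%02d", seq_along(standards_ng)),
      role = "standard", amount_ng = standards_ng, concentration = sc,
      fluorescence = curve_slope * sc + curve_intercept +
        rnorm(length(sc), 0, noise_sd),
      ttc_condition = ttc_condition, stringsAsFactors = FALSE)
    conc <- truth_ng_per_g * tissue_weight_g /
      (dilution_factor * homogenate_volume_ml)
    samples <- data.frame(
      sample_id = sprintf("sample%02d", seq_len(n)),
      role = "sample",
      fluorescence = ttc_effect * (curve_slope * conc + curve_intercept) +
        rnorm(n, 0, noise_sd),
      tissue_weight_g = tissue_weight_g,
      ttc_condition = ttc_condition, stringsAsFactors = FALSE)
    truth <- data.frame(sample_id = samples$sample_id,
                        ng_per_g = truth_ng_per_g,
                        tissue_weight_g = tissue_weight_g)
    list(standards = standards, samples = samples, truth = truth)
  })
}

#' Generate paired readings for the TTC interference assay
#'
#' Simulates matched samples read at baseline (0% TTC) and under each
#' condition: sample `i` has a latent true index drawn once, the baseline
#' read adds measurement noise, and each condition read multiplies the
#' latent value by that condition's effect before adding noise. An effect
#' of 1 everywhere gives pure null data.
#'
#' @param n_pairs samples per condition (paired with baseline).
#' @param mean_index,between_sd latent index distribution (ng/g); defaults
#'   emulate the post-MCAO index scale.
#' @param noise_sd measurement noise sd (ng/g equivalent).
#' @param effects named numeric vector of multiplicative TTC effects, one
#'   per condition label.
#' @param seed integer seed.
#' @return list with `baseline` (numeric) and `conditions` (named list).
#' @export
generate_interference_readings <- function(n_pairs = 10,
                                           mean_index = 2350,
                                           between_sd = 600,
                                           noise_sd = 25,
                                           effects = c("0.05%" = 1,
                                                       "0.25%" = 1,
                                                       "0.5%" = 1,
                                                       "1%" = 1,
                                                       "2%" = 1),
                                           seed = NULL) {
  stopifnot(n_pairs >= 2, mean_index > 0, between_sd >= 0, noise_sd >= 0)
  if (is.null(names(effects)) || any(!nzchar(names(effects))))
    stop("`effects` must be a named vector of condition labels", call. = FALSE)
  with_seed(seed, {
    latent <- pmax(rnorm(n_pairs, mean_index, between_sd), mean_index * 0.05)
    baseline <- latent + rnorm(n_pairs, 0, noise_sd)
    conditions <- lapply(effects, function(eff)
      eff * latent + rnorm(n_pairs, 0, noise_sd))
    names(conditions) <- names(effects)
    list(baseline = baseline, conditions = conditions)
  })
}
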