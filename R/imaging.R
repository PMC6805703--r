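# Slice-image handling: decode, blue channel-mixer filter, tissue and
# hemisphere segmentation, infarct and blue-area classification.

#' Construct a slice image
#'
#' An RGB scan of one coronal brain slice, stored as an integer array with
#' values in 0--255.
#'
#' @param pixels numeric array of dimension H x W x 3, values in 0--255.
#' @param slice_index ordinal position of the slice within the brain (1-6
#'   for a standard 6-slice, 2 mm sectioning).
#' @param scale optional mm-per-pixel scale factor (metadata only; all area
#'   computations are in pixels).
#' @return An object of class `slice_image`.
#' @export
slice_image <- function(pixels, slice_index, scale = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  d <- dim(pixels)
  if (d[1] < 16L || d[2] < 16L)
    stop("slice image must be at least 16 x 16 pixels", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  slice_index <- as.integer(slice_index)
  if (length(slice_index) != 1L || is.na(slice_index) || slice_index < 1L)
    stop("`slice_index` must be a positive integer", call. = FALSE)
  structure(
    list(pixels = pixels, slice_index = slice_index, scale = scale),
    class = "slice_image"
  )
}

#' @export
print.slice_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slice_image> %d x %d px, slice %d\n", d[1], d[2], x$slice_index))
  invisible(x)
}

#' Read a slice scan from PNG or TIFF
#'
#' Decodes an 8- or 16-bit, RGB, RGBA or grayscale PNG/TIFF file into a
#' [slice_image()]. Grayscale images are promoted to RGB; an alpha channel
#' is composited onto a white background and dropped; 16-bit data are
#' rescaled to 0--255.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams slice_image
#' @return A `slice_image`.
#' @export
load_slice_image <- function(path, slice_index, scale = NULL) {
  if (!file.exists(path))
    stop("cannot read slice image: file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
    ),
    error = function(e) stop("failed to decode ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  # readPNG/readTIFF normalize both 8- and 16-bit data to [0,1]
  if (length(dim(raw)) == 2L) raw <- array(raw, dim = c(dim(raw), 1L))
  nc <- dim(raw)[3]
  if (nc == 1L) {
    rgb <- array(raw[, , 1L], dim = c(dim(raw)[1:2], 3L))
  } else if (nc == 2L) {                     # gray + alpha
    a <- raw[, , 2L]
    g <- raw[, , 1L] * a + (1 - a)
    rgb <- array(g, dim = c(dim(raw)[1:2], 3L))
  } else if (nc == 3L) {
    rgb <- raw
  } else if (nc == 4L) {                     # composite onto white
    a <- raw[, , 4L]
    rgb <- array(0, dim = c(dim(raw)[1:2], 3L))
    for (k in 1:3) rgb[, , k] <- raw[, , k] * a + (1 - a)
  } else {
    stop("unsupported channel count (", nc, ") in ", path, call. = FALSE)
  }
  slice_image(round(rgb * 255), slice_index = slice_index, scale = scale)
}

#' Apply a channel-mixer filter
#'
#' Linear recombination of the R, G, B channels into one monochrome image,
#' mirroring a channel-mixer "blue filter". With the default coefficients
#' (0, 0, 1) the output is the blue channel, so Evans-blue-stained pixels
#' map bright (infarct-like) and TTC-red viable tissue maps dark --
#' staining with the dye then no longer darkens pale infarcted areas in the
#' thresholded image.
#'
#' @param img a [slice_image()].
#' @param coefficients numeric length-3 weights for (R, G, B), each within
#'   \[-2, 2\] (the usual channel-mixer range); conventionally they sum to 1.
#' @return A `gray_image`: an H x W numeric matrix with values in \[0, 1\].
#' @export
apply_blue_filter <- function(img, coefficients = c(0, 0, 1)) {
  stopifnot(inherits(img, "slice_image"))
  if (length(coefficients) != 3L || anyNA(coefficients) ||
      !all(is.finite(coefficients)))
    stop("`coefficients` must be three finite numbers", call. = FALSE)
  if (any(coefficients < -2 | coefficients > 2))
    stop("channel-mixer coefficients must lie in [-2, 2]", call. = FALSE)
  p <- img$pixels
  mixed <- coefficients[1] * p[, , 1] + coefficients[2] * p[, , 2] +
    coefficients[3] * p[, , 3]
  gray_image(clamp(mixed, 0, 255) / 255)
}

#' Convert a slice image to luminance grayscale
#'
#' Standard Rec. 601 luminance (0.299, 0.587, 0.114). This is the
#' conversion an unfiltered black-and-white scan pipeline would use; under
#' it Evans-blue pixels are *dark* and are thresholded as viable tissue,
#' which is exactly the bias the blue filter removes.
#'
#' @inheritParams apply_blue_filter
#' @return A `gray_image` matrix in \[0, 1\].
#' @export
to_grayscale <- function(img) {
  apply_blue_filter(img, c(0.299, 0.587, 0.114))
}

gray_image <- function(m) {
  stopifnot(is.matrix(m), min(m) >= 0, max(m) <= 1)
  structure(m, class = c("gray_image", "matrix", "array"))
}

#' Construct a tissue mask
#'
#' @param mask logical H x W matrix, `TRUE` on tissue.
#' @return A `tissue_mask` with an `area_px` attribute.
#' @export
tissue_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(mask, area_px = sum(mask), class = c("tissue_mask", "matrix", "array"))
}

#' Pixel area of a mask
#' @param mask a `tissue_mask` or logical matrix.
#' @return integer pixel count.
#' @export
area_px <- function(mask) sum(mask)

#' Segment tissue from the scanner background
#'
#' Foreground pixels are those whose maximum per-channel distance from the
#' declared background color (white or black) exceeds `tolerance`.
#' Connected components smaller than `min_object_px` are discarded as
#' debris and holes in the remaining tissue are filled, so that pale
#' infarcted regions inside a slice stay part of the mask.
#'
#' @inheritParams apply_blue_filter
#' @param background `"white"` (default, light scanner lid) or `"black"`.
#' @param min_object_px smallest connected component kept, in pixels.
#' @param tolerance max-channel distance (0--1 scale) from the background
#'   color beyond which a pixel counts as tissue; default 30/255.
#' @return A [tissue_mask()].
#' @export
segment_tissue <- function(img, background = c("white", "black"),
                           min_object_px = 64, tolerance = 30 / 255) {
  stopifnot(inherits(img, "slice_image"))
  background <- match.arg(background)
  if (min_object_px < 0) stop("`min_object_px` must be >= 0", call. = FALSE)
  bg <- if (background == "white") 255 else 0
  p <- img$pixels
  dist <- pmax(abs(p[, , 1] - bg), abs(p[, , 2] - bg), abs(p[, , 3] - bg)) / 255
  fg <- dist > tolerance
  if (!any(fg))
    stop("no tissue detected (slice ", img$slice_index, ")", call. = FALSE)
  if (min_object_px > 0) {
    lab <- EBImage::bwlabel(fg * 1L)
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= min_object_px)
    fg <- matrix(as.integer(lab) %in% keep, nrow = nrow(fg))
    if (!any(fg))
      stop("no tissue detected (slice ", img$slice_index,
           "): all components below min_object_px", call. = FALSE)
  }
  filled <- EBImage::imageData(EBImage::fillHull(fg * 1L)) > 0
  tissue_mask(filled)
}

#' Split a tissue mask into left and right hemispheres
#'
#' The midline is a vertical line through the tissue centroid column unless
#' given explicitly. `orientation` maps image sides to anatomical sides:
#' `"left_is_left"` (default) takes the image-left half as the anatomical
#' left (contralateral) hemisphere; `"flipped"` mirrors that assignment,
#' for scans laid down with the dorsal side reversed.
#'
#' @param mask a [tissue_mask()].
#' @param orientation `"left_is_left"` or `"flipped"`.
#' @param midline optional column coordinate of the dividing line; pixels in
#'   columns strictly left of it go to the image-left hemisphere.
#' @return list with `tissue_mask` elements `left` and `right` (anatomical).
#' @export
split_hemispheres <- function(mask, orientation = c("left_is_left", "flipped"),
                              midline = NULL) {
  stopifnot(inherits(mask, "tissue_mask"))
  orientation <- match.arg(orientation)
  w <- ncol(mask)
  if (!is.null(midline) && (midline < 1 || midline > w))
    stop("`midline` outside image columns [1, ", w, "]", call. = FALSE)
  if (orientation == "flipped") {
    m2 <- tissue_mask(mask[, w:1, drop = FALSE])
    ml2 <- if (is.null(midline)) NULL else w + 1 - midline
    sp <- split_hemispheres(m2, "left_is_left", ml2)
    return(list(left = tissue_mask(unclass(sp$left)[, w:1, drop = FALSE]),
                right = tissue_mask(unclass(sp$right)[, w:1, drop = FALSE])))
  }
  if (is.null(midline)) {
    cols <- col(mask)[mask]
    if (length(cols) == 0L) stop("empty tissue mask", call. = FALSE)
    midline <- mean(cols)
  }
  left <- mask & (col(mask) < midline)
  right <- mask & !(col(mask) < midline)
  if (!any(left) || !any(right))
    stop("degenerate hemisphere split: one side is empty", call. = FALSE)
  list(left = tissue_mask(left), right = tissue_mask(right))
}

#' Otsu threshold of a set of gray values
#'
#' Classic histogram-based Otsu: the 256-bin within-set histogram is cut at
#' the level maximizing between-class variance; ties resolve to the lowest
#' cut. Returns a threshold `t` such that values `>= t` form the bright
#' class.
#'
#' @param values numeric vector in \[0, 1\].
#' @return threshold in (0, 1), or `NA` if the values are all one level.
#' @export
otsu_threshold <- function(values) {
  stopifnot(length(values) > 0, min(values) >= 0, max(values) <= 1)
  bins <- round(values * 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  nz <- which(counts > 0L)
  if (length(nz) < 2L) return(NA_real_)
  lev <- 0:255
  n <- sum(counts)
  w0 <- cumsum(counts)                    # class 0 = bins <= cut
  m0 <- cumsum(counts * lev)
  mt <- m0[256]
  cut <- 1:255                            # candidate cuts between bins
  w0c <- w0[cut]; w1c <- n - w0c
  ok <- w0c > 0 & w1c > 0
  bcv <- rep(-Inf, 255)
  mu0 <- m0[cut][ok] / w0c[ok]
  mu1 <- (mt - m0[cut][ok]) / w1c[ok]
  bcv[ok] <- w0c[ok] * w1c[ok] * (mu0 - mu1)^2
  best <- which.max(bcv)                  # lowest cut on ties
  (best - 0.5) / 255                      # halfway between bins best-1, best
}

#' Classify infarcted (pale) pixels within tissue
#'
#' Within the tissue mask, pixels at or above an intensity threshold are
#' infarct: after the blue filter, unstained pale tissue and Evans-blue
#' staining are both bright, while TTC-red viable tissue is dark. The
#' threshold comes from Otsu's method on the within-tissue histogram, or a
#' fixed level.
#'
#' If the within-tissue histogram is degenerate (a single gray level) or
#' the two Otsu classes differ in mean by less than `min_contrast` --- a
#' unimodal histogram, as in an infarct-free sham brain, where any cut
#' merely bisects the noise --- the slice is declared infarct-free and
#' flagged.
#'
#' @param gray a `gray_image` (from [apply_blue_filter()] or
#'   [to_grayscale()]).
#' @param tissue a [tissue_mask()] of the same shape.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param level required threshold in (0, 1) when `method = "fixed"`.
#' @param min_contrast minimum difference between the bright- and
#'   dark-class mean gray values (0--1 scale) for an Otsu split to count as
#'   a real infarct boundary; default 0.25.
#' @return list with `mask` (logical, infarct pixels), `threshold`, and
#'   `flagged` (`TRUE` when the degenerate fallback fired).
#' @export
classify_infarct <- function(gray, tissue, method = c("otsu", "fixed"),
                             level = NULL, min_contrast = 0.25) {
  method <- match.arg(method)
  stopifnot(is.matrix(gray), inherits(tissue, "tissue_mask"),
            all(dim(gray) == dim(tissue)))
  vals <- gray[tissue]
  empty <- function(flag) list(
    mask = matrix(FALSE, nrow(gray), ncol(gray)),
    threshold = NA_real_, flagged = flag)
  if (method == "fixed") {
    if (is.null(level) || level <= 0 || level >= 1)
      stop("`level` in (0,1) is required for method = \"fixed\"", call. = FALSE)
    thr <- level
  } else {
    thr <- otsu_threshold(vals)
    if (is.na(thr)) return(empty(TRUE))
    hi <- vals >= thr
    if (!any(hi) || all(hi) ||
        (mean(vals[hi]) - mean(vals[!hi])) < min_contrast)
      return(empty(TRUE))
  }
  mask <- gray >= thr & tissue
  list(mask = mask, threshold = thr, flagged = FALSE)
}

#' Detect Evans-blue-stained pixels
#'
#' A tissue pixel is blue-stained when its blue channel dominates both red
#' and green by more than `blue_margin`: `(B - max(R, G))/255 > blue_margin`.
#' This hue-free rule is monotone in the stain intensity and insensitive to
#' overall brightness.
#'
#' @inheritParams segment_tissue
#' @param tissue a [tissue_mask()].
#' @param blue_margin dominance margin on the 0--1 scale, default 30/255.
#' @return list with `mask` (logical) and `area_px`.
#' @export
detect_blue_area <- function(img, tissue, blue_margin = 30 / 255) {
  stopifnot(inherits(img, "slice_image"), inherits(tissue, "tissue_mask"))
  if (blue_margin <= 0 || blue_margin >= 1)
    stop("`blue_margin` must lie in (0, 1)", call. = FALSE)
  p <- img$pixels
  dom <- (p[, , 3] - pmax(p[, , 1], p[, , 2])) / 255
  mask <- (dom > blue_margin) & tissue
  list(mask = mask, area_px = sum(mask))
}

#' Imaging configuration for one slice
#'
#' Collects the tunables of the per-slice measurement pipeline with their
#' defaults.
#'
#' @param orientation image-to-anatomy mapping, see [split_hemispheres()].
#' @param background scanner background, see [segment_tissue()].
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold_level fixed threshold level (only for `"fixed"`).
#' @param blue_margin blue-dominance margin, see [detect_blue_area()].
#' @param filter_coefficients channel-mixer weights, see
#'   [apply_blue_filter()].
#' @param min_object_px debris-removal size for [segment_tissue()].
#' @param tolerance background tolerance for [segment_tissue()].
#' @param min_contrast Otsu contrast guard, see [classify_infarct()].
#' @param ipsilateral occluded side, `"right"` (default: right-sided MCAO)
#'   or `"left"`.
#' @param blue_scope count blue pixels over the `"ipsilateral"` hemisphere
#'   (default) or the whole `"slice"`.
#' @param use_blue_filter if `FALSE`, threshold plain luminance instead of
#'   the blue-filtered image (the ablation that reproduces the Evans-blue
#'   bias).
#' @return named list of class `slice_config`.
#' @export
slice_config <- function(orientation = "left_is_left",
                         background = "white",
                         threshold_method = "otsu",
                         threshold_level = NULL,
                         blue_margin = 30 / 255,
                         filter_coefficients = c(0, 0, 1),
                         min_object_px = 64,
                         tolerance = 30 / 255,
                         min_contrast = 0.25,
                         ipsilateral = "right",
                         blue_scope = "ipsilateral",
                         use_blue_filter = TRUE) {
  cfg <- list(orientation = orientation, background = background,
              threshold_method = threshold_method,
              threshold_level = threshold_level, blue_margin = blue_margin,
              filter_coefficients = filter_coefficients,
              min_object_px = min_object_px, tolerance = tolerance,
              min_contrast = min_contrast, ipsilateral = ipsilateral,
              blue_scope = blue_scope, use_blue_filter = use_blue_filter)
  stopifnot(ipsilateral %in% c("right", "left"),
            blue_scope %in% c("ipsilateral", "slice"))
  class(cfg) <- "slice_config"
  cfg
}

#' Measure one slice: hemisphere, infarct and blue areas
#'
#' Runs the full per-slice pipeline: tissue segmentation, hemisphere split,
#' blue-area detection on the unfiltered RGB image, blue channel-mixer
#' filtering, and infarct thresholding. Infarct pixels are counted over the
#' whole tissue; blue pixels over the ipsilateral hemisphere (configurable).
#'
#' @param img a [slice_image()].
#' @param config a [slice_config()].
#' @return A one-row `data.frame` (class `slice_measurement`) with columns
#'   `slice_index`, `left_area_px`, `right_area_px`, `infarct_area_px`,
#'   `blue_area_px`, `threshold`, `flags`.
#' @export
measure_slice <- function(img, config = slice_config()) {
  stopifnot(inherits(img, "slice_image"))
  step <- function(expr) tryCatch(expr, error = function(e)
    stop("slice ", img$slice_index, ": ", conditionMessage(e), call. = FALSE))
  tissue <- step(segment_tissue(img, config$background,
                                config$min_object_px, config$tolerance))
  hemi <- step(split_hemispheres(tissue, config$orientation))
  blue <- step(detect_blue_area(img, tissue, config$blue_margin))
  gray <- if (isTRUE(config$use_blue_filter))
    apply_blue_filter(img, config$filter_coefficients)
  else
    to_grayscale(img)
  inf <- step(classify_infarct(gray, tissue, config$threshold_method,
                               config$threshold_level, config$min_contrast))
  ipsi_mask <- if (config$ipsilateral == "right") hemi$right else hemi$left
  blue_n <- if (config$blue_scope == "slice") blue$area_px
            else sum(blue$mask & ipsi_mask)
  out <- data.frame(
    slice_index = img$slice_index,
    left_area_px = area_px(hemi$left),
    right_area_px = area_px(hemi$right),
    infarct_area_px = sum(inf$mask),
    blue_area_px = blue_n,
    threshold = inf$threshold,
    flags = if (inf$flagged) "low_contrast" else "",
    stringsAsFactors = FALSE
  )
  class(out) <- c("slice_measurement", class(out))
  out
}
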