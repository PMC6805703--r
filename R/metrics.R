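# Brain-level metrics: aggregate per-slice areas and apply the three
# injury formulas (swelling-corrected infarct %, Kaplan edema %, image-based
# BBB %), plus the same ratio formulas applied to ADC maps.

#' Aggregate per-slice measurements into a brain measurement
#'
#' Sums the per-slice pixel areas over the ordered slice set ("numeric
#' integration": each slice stands for a constant-thickness 2 mm slab, so
#' summed areas are volume proxies). Per-slice rows are retained for
#' slice-wise reporting.
#'
#' @param slices a `data.frame` of slice measurements (rows as returned by
#'   [measure_slice()]) or a list of such rows.
#' @param brain_id optional label.
#' @return A `brain_measurement`: list with `brain_id`, `slices`
#'   (data.frame), totals `left_total_px`, `right_total_px`,
#'   `infarct_total_px`, `blue_total_px`, and `flags` (character; contains
#'   `"slice_count"` when the set is not the expected 6 slices).
#' @export
aggregate_slices <- function(slices, brain_id = "brain") {
  if (is.list(slices) && !is.data.frame(slices))
    slices <- do.call(rbind, slices)
  if (!is.data.frame(slices) || nrow(slices) == 0L)
    stop("`slices` must contain at least one slice measurement", call. = FALSE)
  req <- c("slice_index", "left_area_px", "right_area_px",
           "infarct_area_px", "blue_area_px")
  miss <- setdiff(req, names(slices))
  if (length(miss))
    stop("slice table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(slices$slice_index))
    stop("duplicate slice_index in slice set", call. = FALSE)
  slices <- slices[order(slices$slice_index), , drop = FALSE]
  flags <- character(0)
  if (nrow(slices) != 6L) {
    warning("expected 6 slices, got ", nrow(slices), call. = FALSE)
    flags <- "slice_count"
  }
  structure(list(
    brain_id = brain_id,
    slices = slices,
    left_total_px = sum(slices$left_area_px),
    right_total_px = sum(slices$right_area_px),
    infarct_total_px = sum(slices$infarct_area_px),
    blue_total_px = sum(slices$blue_area_px),
    flags = flags
  ), class = "brain_measurement")
}

#' @export
print.brain_measurement <- function(x, ...) {
  cat(sprintf("<brain_measurement> %s: %d slices; L %d px, R %d px, infarct %d px, blue %d px\n",
              x$brain_id, nrow(x$slices), x$left_total_px, x$right_total_px,
              x$infarct_total_px, x$blue_total_px))
  invisible(x)
}

totals <- function(bm, ipsilateral = "right") {
  stopifnot(inherits(bm, "brain_measurement"),
            ipsilateral %in% c("right", "left"))
  ipsi <- if (ipsilateral == "right") bm$right_total_px else bm$left_total_px
  contra <- if (ipsilateral == "right") bm$left_total_px else bm$right_total_px
  # numeric: pixel-count products overflow 32-bit integers
  list(ipsi = as.numeric(ipsi), contra = as.numeric(contra),
       infarct = as.numeric(bm$infarct_total_px),
       blue = as.numeric(bm$blue_total_px))
}

#' Swelling-corrected infarct volume percentage
#'
#' Corrects the raw infarct area for edema inflation of the ipsilateral
#' hemisphere:
#' `corrected = infarct * contralateral / ipsilateral`,
#' then normalizes: `"total_brain"` divides by (left + right), and
#' `"contralateral"` divides by twice the contralateral hemisphere (an
#' edema-free whole-brain estimate).
#'
#' @param bm a [aggregate_slices()] result.
#' @param normalization `"total_brain"` (default) or `"contralateral"`.
#' @param ipsilateral occluded side, `"right"` (default) or `"left"`.
#' @return infarct volume as a percentage.
#' @export
infarct_percent <- function(bm, normalization = c("total_brain", "contralateral"),
                            ipsilateral = "right") {
  normalization <- match.arg(normalization)
  t <- totals(bm, ipsilateral)
  if (t$ipsi <= 0 || t$contra <= 0)
    stop("hemisphere totals must be positive", call. = FALSE)
  corrected <- t$infarct * t$contra / t$ipsi
  denom <- switch(normalization,
                  total_brain = t$ipsi + t$contra,
                  contralateral = 2 * t$contra)
  100 * corrected / denom
}

#' Hemispheric edema percentage (Kaplan method)
#'
#' `100 * (ipsilateral - contralateral) / contralateral`; with the default
#' right-sided occlusion this is `(right - left)/left`. Negative values
#' indicate an ipsilateral hemisphere smaller than the contralateral one.
#'
#' @inheritParams infarct_percent
#' @return edema extent as a percentage (may be negative).
#' @export
edema_percent <- function(bm, ipsilateral = "right") {
  t <- totals(bm, ipsilateral)
  if (t$contra <= 0)
    stop("contralateral hemisphere total must be positive", call. = FALSE)
  100 * (t$ipsi - t$contra) / t$contra
}

#' Image-based BBB disruption percentage
#'
#' `100 * (contralateral - (ipsilateral - blue)) / contralateral`: the
#' blue-stained area of the ipsilateral hemisphere, expressed against the
#' contralateral hemisphere, with hemispheric swelling entering with
#' opposite sign (with no dye the formula reduces to minus the edema
#' ratio).
#'
#' @inheritParams infarct_percent
#' @param per_slice if `TRUE`, return the per-slice percentages as a
#'   data.frame instead of the brain-level value.
#' @return percentage (scalar), or a data.frame with `slice_index` and
#'   `bbb_percent` when `per_slice = TRUE`.
#' @export
bbb_image_percent <- function(bm, ipsilateral = "right", per_slice = FALSE) {
  t <- totals(bm, ipsilateral)
  if (t$contra <= 0)
    stop("contralateral hemisphere total must be positive", call. = FALSE)
  if (per_slice) {
    s <- bm$slices
    ipsi <- if (ipsilateral == "right") s$right_area_px else s$left_area_px
    contra <- if (ipsilateral == "right") s$left_area_px else s$right_area_px
    if (any(contra <= 0))
      stop("contralateral slice area must be positive", call. = FALSE)
    return(data.frame(
      slice_index = s$slice_index,
      bbb_percent = 100 * (contra - (ipsi - s$blue_area_px)) / contra))
  }
  100 * (t$contra - (t$ipsi - t$blue)) / t$contra
}

#' All three brain-level metrics at once
#'
#' @inheritParams infarct_percent
#' @return one-row data.frame with `brain_id`, `infarct_percent`,
#'   `edema_percent`, `bbb_image_percent`, `normalization`, `flags`.
#' @export
brain_metrics <- function(bm, normalization = "total_brain",
                          ipsilateral = "right") {
  data.frame(
    brain_id = bm$brain_id,
    infarct_percent = infarct_percent(bm, normalization, ipsilateral),
    edema_percent = edema_percent(bm, ipsilateral),
    bbb_image_percent = bbb_image_percent(bm, ipsilateral),
    normalization = normalization,
    flags = paste(c(bm$flags, if (!is.null(bm$slices$flags))
                    unique(bm$slices$flags[nzchar(bm$slices$flags)])),
                  collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Lesion percentage from an ADC map
#'
#' Applies the viability threshold (default 0.53e-3 mm^2/s) to an apparent
#' diffusion coefficient map: tissue pixels with ADC strictly below
#' threshold form the ischemic lesion, which then goes through the same
#' swelling-corrected percentage computation as [infarct_percent()]. This
#' lets the ratio formulas be applied to MRI-derived maps.
#'
#' @param adc_map numeric H x W matrix, ADC in mm^2/s.
#' @param tissue a [tissue_mask()].
#' @param left,right hemisphere `tissue_mask`s (anatomical sides), e.g.
#'   from [split_hemispheres()].
#' @param threshold viability threshold in mm^2/s.
#' @param normalization,ipsilateral as in [infarct_percent()].
#' @return lesion volume percentage.
#' @export
adc_lesion_percent <- function(adc_map, tissue, left, right,
                               threshold = 0.53e-3,
                               normalization = "total_brain",
                               ipsilateral = "right") {
  stopifnot(is.matrix(adc_map), inherits(tissue, "tissue_mask"),
            all(dim(adc_map) == dim(tissue)))
  vals <- adc_map[tissue]
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("ADC map must be finite and non-negative over tissue", call. = FALSE)
  lesion <- sum(adc_map < threshold & tissue)
  bm <- suppressWarnings(aggregate_slices(data.frame(
    slice_index = 1L, left_area_px = area_px(left),
    right_area_px = area_px(right), infarct_area_px = lesion,
    blue_area_px = 0L)))
  infarct_percent(bm, normalization, ipsilateral)
}
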