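# Fluorometric Evans blue quantification: standard-curve calibration,
# inverse prediction to ng/mL, the ng/g extravasation index, and the
# TTC-interference assay.

#' Fit an Evans blue standard curve
#'
#' Ordinary least squares of fluorescence on concentration. Standards are
#' specified as ng of dye per well; with the default 200 uL well volume the
#' concentration in ng/mL is `amount_ng / 0.2`. The blank (0 ng) is an
#' ordinary point; the intercept is not forced through zero.
#'
#' @param points data.frame with columns `amount_ng` and `fluorescence`
#'   (arbitrary units). A `concentration` column (ng/mL) may be supplied
#'   instead of `amount_ng`.
#' @param well_volume_ml volume in which `amount_ng` is dissolved (mL).
#' @return A `standard_curve`: list with `slope` (a.u. per ng/mL),
#'   `intercept` (a.u.), `r_squared`, `valid_range` (ng/mL), `n`.
#' @export
fit_standard_curve <- function(points, well_volume_ml = 0.2) {
  stopifnot(is.data.frame(points))
  if (!"concentration" %in% names(points)) {
    if (!"amount_ng" %in% names(points))
      stop("`points` needs an `amount_ng` or `concentration` column",
           call. = FALSE)
    if (well_volume_ml <= 0) stop("`well_volume_ml` must be positive",
                                  call. = FALSE)
    points$concentration <- points$amount_ng / well_volume_ml
  }
  if (!"fluorescence" %in% names(points))
    stop("`points` needs a `fluorescence` column", call. = FALSE)
  points <- points[complete.cases(points[, c("concentration", "fluorescence")]), ]
  if (nrow(points) < 3L)
    stop("standard curve needs at least 3 points", call. = FALSE)
  if (length(unique(points$concentration)) < 2L)
    stop("standard curve needs at least 2 distinct concentrations",
         call. = FALSE)
  fit <- lm(fluorescence ~ concentration, data = points)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    valid_range = range(points$concentration),
    n = nrow(points)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> F = %.4g * C + %.4g (R^2 = %.4f, n = %d, range %g-%g ng/mL)\n",
              x$slope, x$intercept, x$r_squared, x$n,
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Invert a standard curve: fluorescence to concentration
#'
#' `(f - intercept) / slope`, vectorized. Readings implying a negative
#' concentration, or outside the calibration range, are handled by
#' `extrapolation_policy`: `"clamp"` truncates into `[0, Inf)` and leaves
#' out-of-range values as computed, `"allow"` returns raw values (possibly
#' negative), `"error"` rejects values outside the curve's valid range.
#'
#' @param fluorescence numeric vector of readings (a.u.).
#' @param curve a [fit_standard_curve()] result.
#' @param extrapolation_policy `"clamp"` (default), `"allow"` or `"error"`.
#' @return concentrations in ng/mL.
#' @export
concentration_from_fluorescence <- function(fluorescence, curve,
    extrapolation_policy = c("clamp", "allow", "error")) {
  stopifnot(inherits(curve, "standard_curve"))
  extrapolation_policy <- match.arg(extrapolation_policy)
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stop("standard curve slope must be positive for inverse prediction",
         call. = FALSE)
  conc <- (fluorescence - curve$intercept) / curve$slope
  if (extrapolation_policy == "error") {
    out <- conc < curve$valid_range[1] | conc > curve$valid_range[2]
    if (any(out))
      stop("reading outside calibration range [",
           curve$valid_range[1], ", ", curve$valid_range[2], "] ng/mL",
           call. = FALSE)
  } else if (extrapolation_policy == "clamp") {
    conc <- pmax(conc, 0)
  }
  conc
}

#' Evans blue extravasation index (ng dye per g tissue)
#'
#' Converts a fluorescence reading of the diluted tissue supernatant into
#' nanograms of dye per gram of brain tissue: the inverse-predicted
#' concentration of the diluted read is scaled back by the dilution factor
#' and the homogenate volume, then divided by tissue weight.
#'
#' The default `dilution_factor = 4` encodes the 1:3 supernatant:ethanol
#' dilution read as 1 volume + 3 volumes.
#'
#' @inheritParams concentration_from_fluorescence
#' @param tissue_weight_g tissue wet weight in grams.
#' @param dilution_factor total dilution of the supernatant before reading.
#' @param homogenate_volume_ml homogenization volume in mL (default 1 mL
#'   of 50% trichloroacetic acid per sample).
#' @return index in ng/g, vectorized over readings/weights.
#' @export
extravasation_index <- function(fluorescence, tissue_weight_g, curve,
                                dilution_factor = 4,
                                homogenate_volume_ml = 1,
                                extrapolation_policy = "clamp") {
  if (any(tissue_weight_g <= 0))
    stop("`tissue_weight_g` must be positive", call. = FALSE)
  if (any(dilution_factor < 1) || any(homogenate_volume_ml <= 0))
    stop("dilution factor must be >= 1 and volume positive", call. = FALSE)
  conc <- concentration_from_fluorescence(fluorescence, curve,
                                          extrapolation_policy)
  conc * dilution_factor * homogenate_volume_ml / tissue_weight_g
}

#' TTC interference assay on paired extravasation readings
#'
#' Compares Evans blue readings from samples incubated at each TTC
#' concentration against matched baseline (0% TTC) readings. Each pair is
#' expressed as percent of baseline (`100 * condition / baseline`); the
#' baseline row itself normalizes each replicate against the baseline mean,
#' so it reproduces mean 100 with a nonzero SEM. Conditions are tested
#' against baseline with the two-sided Wilcoxon signed-rank test.
#'
#' @param baseline numeric readings at 0% TTC.
#' @param conditions named list of numeric vectors, one per TTC
#'   concentration label, each paired with (same length and order as)
#'   `baseline`.
#' @param alpha significance level for the `significant` flag.
#' @param standards optional data.frame of standard points with a
#'   `ttc_condition` column (plus `amount_ng`/`fluorescence`); when given,
#'   a per-condition standard curve R^2 column is added.
#' @return data.frame with one row per condition (baseline first):
#'   `condition`, `n`, `percent_of_baseline`, `sem`, `p_value`,
#'   `significant`, and `r_squared` when standards are supplied. Rows with
#'   fewer than 5 pairs carry an `underpowered` flag.
#' @export
interference_assay <- function(baseline, conditions, alpha = 0.05,
                               standards = NULL) {
  stopifnot(is.numeric(baseline), length(baseline) >= 1,
            is.list(conditions), length(conditions) >= 1)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("`conditions` must be a named list of TTC concentration labels",
         call. = FALSE)
  rows <- list()
  b_pct <- 100 * baseline / mean(baseline)
  rows[["baseline"]] <- data.frame(
    condition = "0%", n = length(baseline),
    percent_of_baseline = mean(b_pct),
    sem = sd(b_pct) / sqrt(length(b_pct)),
    p_value = NA_real_, significant = FALSE,
    flags = if (length(baseline) < 5) "underpowered" else "",
    stringsAsFactors = FALSE)
  for (lab in names(conditions)) {
    x <- conditions[[lab]]
    if (length(x) != length(baseline))
      stop("condition '", lab, "' is not paired with baseline (",
           length(x), " vs ", length(baseline), " readings)", call. = FALSE)
    pct <- 100 * x / baseline
    p <- if (all(x == baseline)) 1 else suppressWarnings(
      wilcox.test(x, baseline, paired = TRUE, exact = NULL)$p.value)
    rows[[lab]] <- data.frame(
      condition = lab, n = length(x),
      percent_of_baseline = mean(pct),
      sem = sd(pct) / sqrt(length(pct)),
      p_value = p, significant = is.finite(p) && p < alpha,
      flags = if (length(x) < 5) "underpowered" else "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(standards)) {
    stopifnot(is.data.frame(standards), "ttc_condition" %in% names(standards))
    r2 <- vapply(out$condition, function(lab) {
      pts <- standards[standards$ttc_condition == lab, , drop = FALSE]
      if (nrow(pts) < 3L) return(NA_real_)
      fit_standard_curve(pts)$r_squared
    }, numeric(1))
    out$r_squared <- unname(r2)
  }
  out
}

#' Per-condition standard curves
#'
#' Fits one standard curve per TTC condition label, mirroring the layout of
#' a multi-condition calibration table.
#'
#' @param points data.frame of standards with `amount_ng`, `fluorescence`
#'   and `ttc_condition` columns.
#' @param well_volume_ml see [fit_standard_curve()].
#' @return data.frame with `condition`, `slope`, `intercept`, `r_squared`,
#'   `n`.
#' @export
ttc_standard_curves <- function(points, well_volume_ml = 0.2) {
  stopifnot(is.data.frame(points), "ttc_condition" %in% names(points))
  labs <- unique(points$ttc_condition)
  do.call(rbind, lapply(labs, function(lab) {
    cv <- fit_standard_curve(points[points$ttc_condition == lab, ],
                             well_volume_ml)
    data.frame(condition = lab, slope = cv$slope, intercept = cv$intercept,
               r_squared = cv$r_squared, n = cv$n, stringsAsFactors = FALSE)
  }))
}
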