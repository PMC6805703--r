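# File-format plumbing: YAML run configuration, brain directories and
# manifests, plate/tissue CSVs, PNG output.

#' Default run configuration
#'
#' Nested list mirroring the YAML config schema. Unknown keys in a user
#' config are rejected by [read_config()].
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    imaging = list(
      orientation = "left_is_left",
      background = "white",
      threshold = list(method = "otsu", level = NULL),
      blue_margin = 30 / 255,
      filter_coefficients = c(0, 0, 1),
      min_object_px = 64,
      tolerance = 30 / 255,
      min_contrast = 0.25
    ),
    metrics = list(
      normalization = "total_brain",
      ipsilateral = "right",
      blue_scope = "ipsilateral"
    ),
    spectro = list(
      dilution_factor = 4,
      homogenate_volume_ml = 1,
      well_volume_ml = 0.2,
      extrapolation_policy = "clamp"
    ),
    seed = NULL
  )
}

check_keys <- function(user, ref, path = "") {
  if (!is.list(user)) return(invisible(NULL))
  unknown <- setdiff(names(user), names(ref))
  if (length(unknown))
    stop("unknown config key", if (length(unknown) > 1) "s", ": ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  for (k in names(user))
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
      check_keys(user[[k]], ref[[k]], paste0(path, k, "."))
  invisible(NULL)
}

merge_config <- function(user, ref) {
  for (k in names(user)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(user[[k]]))
      ref[[k]] <- merge_config(user[[k]], ref[[k]])
    else ref[[k]] <- user[[k]]
  }
  ref
}

#' Read and validate a YAML run configuration
#'
#' Missing keys take their defaults; keys not in the schema are rejected.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return nested config list.
#' @export
read_config <- function(path = NULL) {
  ref <- default_config()
  if (is.null(path)) return(ref)
  user <- yaml::read_yaml(path)
  check_keys(user, ref)
  merge_config(user, ref)
}

config_slice_config <- function(config, use_blue_filter = TRUE) {
  im <- config$imaging; me <- config$metrics
  slice_config(
    orientation = im$orientation, background = im$background,
    threshold_method = im$threshold$method,
    threshold_level = im$threshold$level,
    blue_margin = im$blue_margin,
    filter_coefficients = unlist(im$filter_coefficients),
    min_object_px = im$min_object_px, tolerance = im$tolerance,
    min_contrast = im$min_contrast,
    ipsilateral = me$ipsilateral, blue_scope = me$blue_scope,
    use_blue_filter = use_blue_filter)
}

#' Locate slice images of one or more brains in a directory
#'
#' Files must be named `<brainid>_s<k>.<ext>` with `k` the slice index and
#' extension png/tif/tiff.
#'
#' @param dir directory to scan.
#' @return data.frame with `brain_id`, `slice_index`, `path`.
#' @export
find_brain_slices <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = "_s[0-9]+\\.(png|tif|tiff)$",
                      ignore.case = TRUE)
  if (length(files) == 0L)
    stop("no slice images (<brainid>_s<k>.png/tiff) found in ", dir,
         call. = FALSE)
  base <- sub("\\.[^.]+$", "", files)
  out <- data.frame(
    brain_id = sub("_s[0-9]+$", "", base),
    slice_index = as.integer(sub("^.*_s([0-9]+)$", "\\1", base)),
    path = file.path(dir, files), stringsAsFactors = FALSE)
  out[order(out$brain_id, out$slice_index), , drop = FALSE]
}

#' Read an explicit slice manifest
#'
#' @param path CSV with columns `brain_id`, `slice_index`, `path`
#'   (relative paths resolve against the manifest's directory).
#' @return data.frame with the same columns.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("brain_id", "slice_index", "path")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop("manifest ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  rel <- !file.exists(m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Write a slice image as PNG
#'
#' @param img a [slice_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_slice_png <- function(img, path) {
  stopifnot(inherits(img, "slice_image"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Read a plate CSV
#'
#' Long-format plate export with one row per well: columns `role`
#' (`"standard"`, `"sample"` or `"blank"`) and `fluorescence` are required;
#' standards additionally need `amount_ng`, samples `sample_id`. An
#' optional `ttc_condition` column labels interference conditions
#' (defaults to `"0%"`).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_plate_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(df, c("role", "fluorescence"), paste0("plate CSV ", path))
  if (!"ttc_condition" %in% names(df)) df$ttc_condition <- "0%"
  std <- df$role == "standard"
  if (any(std))
    require_columns(df[std, , drop = FALSE], "amount_ng",
                    paste0("plate CSV ", path, " (standard rows)"))
  if (any(df$role == "sample"))
    require_columns(df[df$role == "sample", , drop = FALSE], "sample_id",
                    paste0("plate CSV ", path, " (sample rows)"))
  df
}

#' Read a tissue-sample CSV
#'
#' @param path CSV with columns `sample_id`, `hemisphere`, `weight_g`,
#'   `fluorescence`.
#' @return data.frame.
#' @export
read_tissue_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(df, c("sample_id", "hemisphere", "weight_g",
                        "fluorescence"), paste0("tissue CSV ", path))
  df
}
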