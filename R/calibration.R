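# Two-point Hounsfield-unit calibration. Raw reconstruction gray values are
# mapped by the affine transform anchored at water -> 0 HU and air -> -1000 HU,
# the standard laboratory micro-CT density calibration against a distilled
# water phantom.

#' Fit a two-point HU calibration from water and air reference regions
#'
#' Computes the arithmetic means of the water- and air-labeled voxels and the
#' unique affine map sending them to 0 HU and -1000 HU respectively:
#' `slope = 1000 / (water_mean - air_mean)`,
#' `intercept = -slope * water_mean`.
#'
#' The references may sit inside the sample volume or come from a separate
#' phantom scan acquired with identical settings; `acquisition_id` is a
#' free-text audit field for the latter case.
#'
#' @param volume A [voxel_volume()] in `RAW_GRAY` units.
#' @param mask A [label_mask()] with water and air regions.
#' @param water_label,air_label Label codes or names of the reference regions.
#' @param acquisition_id Optional free-text scan identifier.
#' @return An object of class `hu_calibration` with fields `raw_water_mean`,
#'   `raw_air_mean`, `slope`, `intercept`, `acquisition_id`.
#' @export
fit_calibration <- function(volume, mask, water_label, air_label,
                            acquisition_id = NULL) {
  stopifnot(is_voxel_volume(volume), is_label_mask(mask))
  require_units(volume, "RAW_GRAY")
  check_same_geometry(volume, mask)
  water_label <- resolve_label(mask, water_label)
  air_label <- resolve_label(mask, air_label)
  wv <- volume$data[mask$data == water_label]
  av <- volume$data[mask$data == air_label]
  if (!length(wv) || !length(av))
    stop("missing reference: water/air label empty in mask", call. = FALSE)
  w <- mean(wv); a <- mean(av)
  if (w <= a)
    stop(sprintf(
      "inverted reference: water mean (%.6g) must exceed air mean (%.6g)",
      w, a), call. = FALSE)
  slope <- 1000 / (w - a)
  structure(
    list(raw_water_mean = w, raw_air_mean = a, slope = slope,
         intercept = -slope * w, acquisition_id = acquisition_id),
    class = "hu_calibration")
}

#' @export
print.hu_calibration <- function(x, ...) {
  cat(sprintf(
    "<hu_calibration> HU = %.6g * raw %+.6g  (water %.6g -> 0, air %.6g -> -1000)\n",
    x$slope, x$intercept, x$raw_water_mean, x$raw_air_mean))
  invisible(x)
}

#' Apply a fitted HU calibration to a raw-gray volume
#'
#' Per-voxel affine map `slope * x + intercept`; shape and voxel size are
#' preserved and the result is tagged `HU`. Because the map is affine, ROI
#' means may be calibrated before or after averaging with identical results.
#'
#' @param volume A [voxel_volume()] in `RAW_GRAY` units.
#' @param model A `hu_calibration` from [fit_calibration()].
#' @return A [voxel_volume()] in `HU` units.
#' @export
apply_calibration <- function(volume, model) {
  stopifnot(is_voxel_volume(volume), inherits(model, "hu_calibration"))
  if (identical(volume$units, "HU"))
    stop("double calibration: volume is already in HU", call. = FALSE)
  voxel_volume(model$slope * volume$data + model$intercept,
               volume$voxel_size_um, units = "HU")
}

#' Apply a calibration model to scalar raw-gray values
#'
#' @param model A `hu_calibration`.
#' @param x Numeric raw gray value(s).
#' @return HU value(s).
#' @export
calibrate_values <- function(model, x) {
  stopifnot(inherits(model, "hu_calibration"))
  model$slope * x + model$intercept
}

#' Fold ratio of two mass attenuation coefficients
#'
#' Dimensionless ratio `mu_rho_label / mu_rho_tissue`, used as a physics
#' sanity check of label contrast: e.g. the bromine atoms in the
#' X-gal reaction product (mass attenuation coefficient 6.832 at 40 kV)
#' against brain gray matter (0.270) give a roughly 25-fold contrast.
#'
#' @param mu_rho_label,mu_rho_tissue Positive mass attenuation coefficients.
#' @return The fold ratio.
#' @export
attenuation_fold_ratio <- function(mu_rho_label, mu_rho_tissue) {
  if (!is.numeric(mu_rho_label) || !is.numeric(mu_rho_tissue) ||
      any(mu_rho_label <= 0) || any(mu_rho_tissue <= 0))
    stop("mass attenuation coefficients must be positive", call. = FALSE)
  mu_rho_label / mu_rho_tissue
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model A `hu_calibration`.
#' @param path JSON file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns the `hu_calibration`.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "hu_calibration"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(raw_water_mean = x$raw_water_mean,
                 raw_air_mean = x$raw_air_mean,
                 slope = x$slope, intercept = x$intercept,
                 acquisition_id = x$acquisition_id),
            class = "hu_calibration")
}
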