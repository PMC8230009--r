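#' Voxel volume container
#'
#' A `voxel_volume` is the universal image carrier of the package: a 3D grid
#' of grayscale (or Hounsfield-unit) values together with its isotropic voxel
#' size. Axis order is fixed as (slice, row, column).
#'
#' @param data Numeric 3D array of intensities, shape (n_slices, n_rows,
#'   n_cols). All values must be finite.
#' @param voxel_size_um Positive scalar, isotropic voxel edge length in
#'   micrometres.
#' @param units Intensity units, `"RAW_GRAY"` (native reconstruction gray
#'   values) or `"HU"` (Hounsfield units).
#' @return An object of class `voxel_volume` with fields `data`,
#'   `voxel_size_um` and `units`.
#' @export
voxel_volume <- function(data, voxel_size_um, units = c("RAW_GRAY", "HU")) {
  units <- match.arg(units)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (slice, row, column)", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("all three extents of `data` must be positive", call. = FALSE)
  if (!is.numeric(data))
    stop("`data` must be numeric", call. = FALSE)
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values (NaN/Inf not accepted)",
         call. = FALSE)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive finite scalar", call. = FALSE)
  storage.mode(data) <- "double"
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         units = units),
    class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, %.4g um/voxel, units %s\n",
              d[1L], d[2L], d[3L], x$voxel_size_um, x$units))
  cat(sprintf("  range [%.6g, %.6g]\n", min(x$data), max(x$data)))
  invisible(x)
}

is_voxel_volume <- function(x) inherits(x, "voxel_volume")

#' Stop unless a volume carries the required units
#'
#' Operations defined on Hounsfield units refuse raw-gray input and vice
#' versa; this is the shared guard.
#'
#' @param volume A [voxel_volume()].
#' @param units Required units string.
#' @keywords internal
#' @noRd
require_units <- function(volume, units) {
  if (!identical(volume$units, units))
    stop(sprintf("volume has units %s; %s required", volume$units, units),
         call. = FALSE)
  invisible(volume)
}

#' Label mask container
#'
#' Integer-labeled 3D grid naming regions of interest, calibration regions or
#' grades. Label 0 is reserved for "unassigned"; every nonzero value in the
#' grid must appear in the label map.
#'
#' @param data 3D array of non-negative integers (same axis convention as
#'   [voxel_volume()]).
#' @param labels Named character vector or list mapping label codes to names,
#'   e.g. `c("1" = "cortex", "2" = "hippocampus")`. May be empty for an
#'   all-unassigned mask.
#' @return An object of class `label_mask` with fields `data` (integer array)
#'   and `labels` (named character vector, names are the integer codes).
#' @export
label_mask <- function(data, labels = character()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (!is.numeric(data) || any(!is.finite(data)))
    stop("mask `data` must be finite numeric", call. = FALSE)
  if (any(data < 0) || any(data != round(data)))
    stop("mask `data` must contain non-negative integers", call. = FALSE)
  labels <- unlist(labels)
  if (length(labels)) {
    if (is.null(names(labels)) || any(names(labels) == ""))
      stop("`labels` must be named by integer code", call. = FALSE)
    codes <- suppressWarnings(as.integer(names(labels)))
    if (any(is.na(codes)) || any(codes <= 0L))
      stop("label codes must be positive integers", call. = FALSE)
    labels <- stats::setNames(as.character(labels), as.character(codes))
  } else {
    labels <- stats::setNames(character(), character())
  }
  present <- sort(unique(as.vector(data)))
  present <- present[present != 0]
  unknown <- setdiff(as.character(present), names(labels))
  if (length(unknown))
    stop(sprintf("mask contains unknown label value(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  storage.mode(data) <- "integer"
  structure(list(data = data, labels = labels), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_mask> %d x %d x %d voxels, %d label(s)\n",
              d[1L], d[2L], d[3L], length(x$labels)))
  for (code in names(x$labels)) {
    n <- sum(x$data == as.integer(code))
    cat(sprintf("  %s -> %s (%d voxels)\n", code, x$labels[[code]], n))
  }
  invisible(x)
}

is_label_mask <- function(x) inherits(x, "label_mask")

#' Check that a volume and a mask share geometry
#'
#' Every operation taking a (volume, mask) pair rejects a shape mismatch
#' before computing anything.
#'
#' @param volume A [voxel_volume()].
#' @param mask A [label_mask()] (or second volume).
#' @keywords internal
#' @noRd
check_same_geometry <- function(volume, mask) {
  da <- dim(volume$data); db <- dim(mask$data)
  if (!identical(da, db))
    stop(sprintf("geometry mismatch: volume %s vs mask %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

#' Resolve a label code from a code or name
#' @keywords internal
#' @noRd
resolve_label <- function(mask, label) {
  if (is.character(label)) {
    hit <- names(mask$labels)[mask$labels == label]
    if (!length(hit))
      stop(sprintf("label name '%s' not present in mask", label),
           call. = FALSE)
    return(as.integer(hit[[1L]]))
  }
  as.integer(label)
}

#' Name of a label code (falls back to the code itself)
#' @keywords internal
#' @noRd
label_name <- function(mask, code) {
  nm <- mask$labels[as.character(code)]
  if (is.na(nm)) as.character(code) else unname(nm)
}
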