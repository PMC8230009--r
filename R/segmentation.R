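# Paraffin/background exclusion by Otsu thresholding, plus display helpers
# (maximum intensity projection, LUT windowing) for visual QC.

#' Build an equal-width intensity histogram
#'
#' @param values Numeric vector of intensities (or a [voxel_volume()], in
#'   which case all voxels are used).
#' @param n_bins Number of equal-width bins (default 256, the 8-bit display
#'   convention of desktop CT analysis software).
#' @param limits Optional `c(lo, hi)` range; defaults to the data min-max.
#' @return An object of class `intensity_histogram` with fields `bin_edges`
#'   (length `n_bins + 1`) and `counts` (length `n_bins`).
#' @export
intensity_histogram <- function(values, n_bins = 256L, limits = NULL) {
  if (is_voxel_volume(values)) values <- as.vector(values$data)
  stopifnot(is.numeric(values), length(values) >= 1L, n_bins >= 1L)
  if (is.null(limits)) limits <- range(values)
  lo <- limits[1L]; hi <- limits[2L]
  if (!(hi > lo))
    stop("degenerate histogram: all values identical", call. = FALSE)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts),
            class = "intensity_histogram")
}

#' Otsu threshold of a histogram
#'
#' Selects the bin edge maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over all interior edges, with bin centers as
#' class values. Voxels at or above the returned threshold belong to the
#' upper ("tissue") class; voxels strictly below are the excluded
#' ("paraffin") class. Among tied candidates the highest edge is returned,
#' i.e. the lower edge of the first occupied upper-class bin, which keeps the
#' at-threshold inclusion rule from eating into the gap between classes.
#'
#' @param histogram An [intensity_histogram()].
#' @return The threshold (a bin edge), with the between-class variance curve
#'   attached as attribute `"criterion"`.
#' @export
otsu_threshold <- function(histogram) {
  stopifnot(inherits(histogram, "intensity_histogram"))
  counts <- as.numeric(histogram$counts)
  edges <- histogram$bin_edges
  n_bins <- length(counts)
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  total <- sum(counts)
  occupied <- which(counts > 0)
  if (length(occupied) < 2L)
    stop("degenerate histogram: fewer than two nonempty bins", call. = FALSE)
  # candidate thresholds: interior edges; class 0 = bins 1..k (strictly below
  # edge k+1), class 1 = the rest
  w0 <- cumsum(counts)[-n_bins] / total
  w1 <- 1 - w0
  m0 <- cumsum(counts * centers)[-n_bins] / total
  mt <- sum(counts * centers) / total
  valid <- w0 > 0 & w1 > 0
  crit <- rep(-Inf, n_bins - 1L)
  mu0 <- m0[valid] / w0[valid]
  mu1 <- (mt - m0[valid]) / w1[valid]
  crit[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  best <- max(crit)
  k <- max(which(crit == best))   # ties -> highest edge
  structure(edges[k + 1L], criterion = crit)
}

#' Exclude paraffin background within an ROI by Otsu thresholding
#'
#' Builds an equal-width histogram of the ROI voxels (min-max range), takes
#' the Otsu threshold and marks ROI voxels at or above it as tissue. The
#' returned include mask partitions the ROI exactly: every ROI voxel is
#' either tissue or excluded.
#'
#' @param volume A [voxel_volume()].
#' @param roi Optional [label_mask()]; `NULL` treats the whole volume as ROI
#'   (the histogram becomes global, matching a whole-dataset exclusion).
#' @param label Label code or name of the ROI within `roi` (`NULL` with a
#'   mask: all nonzero labels).
#' @param n_bins Histogram bins (default 256).
#' @return A binary [label_mask()] (1 = `"tissue"`) with the threshold in
#'   attribute `"threshold"` and the histogram in attribute `"histogram"`.
#' @export
exclude_background <- function(volume, roi = NULL, label = NULL,
                               n_bins = 256L) {
  stopifnot(is_voxel_volume(volume))
  if (is.null(roi)) {
    in_roi <- array(TRUE, dim(volume$data))
  } else {
    stopifnot(is_label_mask(roi))
    check_same_geometry(volume, roi)
    in_roi <- if (is.null(label)) roi$data > 0L
              else roi$data == resolve_label(roi, label)
  }
  if (!any(in_roi)) stop("empty ROI", call. = FALSE)
  h <- intensity_histogram(volume$data[in_roi], n_bins = n_bins)
  thr <- otsu_threshold(h)
  inc <- array(0L, dim(volume$data))
  inc[in_roi & volume$data >= thr] <- 1L
  out <- label_mask(inc, c("1" = "tissue"))
  attr(out, "threshold") <- as.numeric(thr)
  attr(out, "histogram") <- h
  out
}

#' Maximum intensity projection
#'
#' Per-pixel maximum along one volume axis; the workhorse QC view of
#' radiodense reporter deposits.
#'
#' @param volume A [voxel_volume()].
#' @param axis Axis to project over: 1 (slice), 2 (row) or 3 (column).
#' @return A numeric matrix with the voxel size attached as attribute
#'   `"voxel_size_um"` (for scale bars).
#' @export
max_intensity_projection <- function(volume, axis = 1L) {
  stopifnot(is_voxel_volume(volume))
  if (!(axis %in% 1:3)) stop("axis must be 1, 2 or 3", call. = FALSE)
  keep <- setdiff(1:3, axis)
  out <- apply(volume$data, keep, max)
  attr(out, "voxel_size_um") <- volume$voxel_size_um
  out
}

#' Linear display window (LUT)
#'
#' Clips to `[low, high]` and maps linearly to `[0, 1]`, the lookup-table
#' windowing used for figure display (e.g. a 0-155 gray value window).
#'
#' @param x Numeric array, matrix or [voxel_volume()] (data is windowed,
#'   geometry kept).
#' @param low,high Window bounds, `low < high`.
#' @return Same shape as the input, values in `[0, 1]`.
#' @export
window_display <- function(x, low, high) {
  if (!(is.numeric(low) && is.numeric(high) && low < high))
    stop("window error: need low < high", call. = FALSE)
  f <- function(v) pmin(pmax((v - low) / (high - low), 0), 1)
  if (is_voxel_volume(x)) {
    x$data <- f(x$data)
    return(x)
  }
  f(x)
}

#' Export a histogram as a CSV table
#'
#' Columns `bin_lo`, `bin_hi`, `count`.
#'
#' @param histogram An [intensity_histogram()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(histogram, path) {
  stopifnot(inherits(histogram, "intensity_histogram"))
  n <- length(histogram$counts)
  utils::write.csv(
    data.frame(bin_lo = histogram$bin_edges[-(n + 1L)],
               bin_hi = histogram$bin_edges[-1L],
               count = histogram$counts),
    path, row.names = FALSE)
  invisible(path)
}
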