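# Core quantification machinery: per-ROI grayscale statistics, wild-type
# background correction (mean + 1 SD subtraction), and SD-graded relative
# expression classification with volume-fraction reporting.

GRADE_OUTSIDE <- 255L
GRADE_NAMES <- c("background", "low", "intermediate", "high")

#' Per-ROI grayscale statistics
#'
#' Population mean and SD (divide by n: the ROI is the entire voxel
#' population considered), min, max and voxel count per label, over the
#' voxels retained by the optional include mask. Voxels are consumed in
#' ascending flat-index order through R's long-double accumulating
#' summation, so results are reproducible across runs.
#'
#' @param volume A [voxel_volume()].
#' @param roi A [label_mask()].
#' @param include Optional binary include mask (a [label_mask()] or logical
#'   array), e.g. from [exclude_background()].
#' @param labels Label codes or names to report (default: all labels of
#'   `roi`).
#' @return A data.frame with columns `label`, `name`, `n_voxels`, `mean`,
#'   `sd`, `min`, `max` and attribute `"units"`.
#' @export
roi_stats <- function(volume, roi, include = NULL, labels = NULL) {
  stopifnot(is_voxel_volume(volume), is_label_mask(roi))
  check_same_geometry(volume, roi)
  keep <- include_array(include, volume)
  codes <- if (is.null(labels)) as.integer(names(roi$labels))
           else vapply(labels, function(l) resolve_label(roi, l), integer(1))
  rows <- lapply(codes, function(code) {
    sel <- roi$data == code & keep
    v <- volume$data[sel]
    if (!length(v))
      stop(sprintf("empty ROI: label %d has no included voxels", code),
           call. = FALSE)
    m <- mean(v)
    data.frame(label = code, name = label_name(roi, code),
               n_voxels = length(v), mean = m,
               sd = sqrt(mean((v - m)^2)),
               min = min(v), max = max(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "units") <- volume$units
  out
}

include_array <- function(include, volume) {
  if (is.null(include)) return(array(TRUE, dim(volume$data)))
  if (is_label_mask(include)) {
    check_same_geometry(volume, include)
    return(include$data > 0L)
  }
  if (is.logical(include) && identical(dim(include), dim(volume$data)))
    return(include)
  stop("`include` must be a label_mask or logical array matching the volume",
       call. = FALSE)
}

#' Wild-type background-correction threshold
#'
#' The background correction threshold is the sum of the mean and one
#' standard deviation of the wild-type gray values of a region.
#'
#' @param wt_stats One or more rows of [roi_stats()] output.
#' @return Named numeric vector `mean + sd`, one entry per ROI.
#' @export
wt_background_threshold <- function(wt_stats) {
  stopifnot(is.data.frame(wt_stats), all(c("mean", "sd") %in% names(wt_stats)))
  stats::setNames(wt_stats$mean + wt_stats$sd, wt_stats$name)
}

#' Background-corrected region means
#'
#' For each ROI (matched by name between the two tables), subtracts the
#' wild-type threshold (WT mean + 1 SD) from the reporter-line ROI mean.
#' Negative differences are clamped to 0 by default, since only positive
#' brightness differences are reported; `clamp = FALSE` keeps the signed
#' value for diagnostics.
#'
#' @param lacz_stats,wt_stats [roi_stats()] tables for the reporter and
#'   wild-type volumes covering the same ROI names.
#' @param clamp Clamp negative corrected values at 0 (default `TRUE`).
#' @return data.frame with columns `roi`, `lacz_mean`, `wt_threshold`,
#'   `corrected`.
#' @export
corrected_region_means <- function(lacz_stats, wt_stats, clamp = TRUE) {
  if (!setequal(lacz_stats$name, wt_stats$name) ||
      anyDuplicated(lacz_stats$name) || anyDuplicated(wt_stats$name))
    stop("pairing error: ROI names must match one-to-one between the two tables",
         call. = FALSE)
  wt_thr <- wt_background_threshold(wt_stats)
  corrected <- lacz_stats$mean - wt_thr[lacz_stats$name]
  if (clamp) corrected <- pmax(corrected, 0)
  data.frame(roi = lacz_stats$name, lacz_mean = lacz_stats$mean,
             wt_threshold = unname(wt_thr[lacz_stats$name]),
             corrected = unname(corrected))
}

#' Per-voxel background-corrected image
#'
#' Within each ROI, subtracts that ROI's wild-type threshold (WT mean + 1 SD)
#' from every voxel; voxels outside all ROIs are set to 0. Negative values
#' are clamped at 0 unless `clamp = FALSE`.
#'
#' @param lacz_volume A [voxel_volume()].
#' @param roi A [label_mask()].
#' @param wt_stats [roi_stats()] table whose `name` column covers every ROI
#'   label of `roi`.
#' @param clamp Clamp negative values at 0.
#' @return A [voxel_volume()] of corrected values.
#' @export
corrected_voxel_image <- function(lacz_volume, roi, wt_stats, clamp = TRUE) {
  stopifnot(is_voxel_volume(lacz_volume), is_label_mask(roi))
  check_same_geometry(lacz_volume, roi)
  missing_rois <- setdiff(unname(roi$labels), wt_stats$name)
  if (length(missing_rois))
    stop("pairing error: no wild-type stats for ROI(s): ",
         paste(missing_rois, collapse = ", "), call. = FALSE)
  wt_thr <- wt_background_threshold(wt_stats)
  out <- array(0, dim(lacz_volume$data))
  for (code in names(roi$labels)) {
    sel <- roi$data == as.integer(code)
    out[sel] <- lacz_volume$data[sel] - wt_thr[[roi$labels[[code]]]]
  }
  if (clamp) out[out < 0] <- 0
  out[roi$data == 0L] <- 0
  voxel_volume(out, lacz_volume$voxel_size_um, lacz_volume$units)
}

#' SD-graded classification thresholds
#'
#' Thresholds at mean + 1, 2 and 3 standard deviations of a source ROI.
#' Values below `t1` are background; `[t1, t2)` low, `[t2, t3)` intermediate,
#' and `>= t3` (up to the maximum) high. The source may be the reporter
#' dataset itself (`"SELF"`, the relative-quantification regime) or a
#' wild-type reference (`"WT"`).
#'
#' @param stats A single row of [roi_stats()] output.
#' @param source `"SELF"` or `"WT"`.
#' @return Object of class `grade_thresholds` with fields `source`, `t1`,
#'   `t2`, `t3`, `mean`, `sd`.
#' @export
grade_thresholds <- function(stats, source = c("SELF", "WT")) {
  source <- match.arg(source)
  stopifnot(is.data.frame(stats), nrow(stats) == 1L)
  if (stats$sd == 0)
    warning("degenerate SD = 0: all three grade thresholds coincide at the mean",
            call. = FALSE)
  structure(list(source = source, t1 = stats$mean + stats$sd,
                 t2 = stats$mean + 2 * stats$sd,
                 t3 = stats$mean + 3 * stats$sd,
                 mean = stats$mean, sd = stats$sd),
            class = "grade_thresholds")
}

#' @export
print.grade_thresholds <- function(x, ...) {
  cat(sprintf("<grade_thresholds> source %s: t1 %.6g | t2 %.6g | t3 %.6g\n",
              x$source, x$t1, x$t2, x$t3))
  invisible(x)
}

#' Grade a volume into background/low/intermediate/high expression classes
#'
#' Assigns each graded voxel the code 0 (background, `< t1`), 1 (low,
#' `[t1, t2)`), 2 (intermediate, `[t2, t3)`) or 3 (high, `>= t3`); voxels
#' outside the ROI or excluded by the include mask carry 255. The same
#' thresholds object can be applied to a second (e.g. wild-type) volume for a
#' like-for-like comparison.
#'
#' @param volume A [voxel_volume()].
#' @param thresholds A [grade_thresholds()].
#' @param roi Optional [label_mask()] restricting grading; `NULL` grades the
#'   whole volume.
#' @param label Optional single label of `roi` to grade.
#' @param include Optional binary include mask (see [roi_stats()]).
#' @return Object of class `grade_map`: `data` (integer array of codes),
#'   `thresholds` (named list, per ROI name), `counts`, `fractions`
#'   (named by grade), `n_graded`.
#' @export
grade_volume <- function(volume, thresholds, roi = NULL, label = NULL,
                         include = NULL) {
  stopifnot(is_voxel_volume(volume), inherits(thresholds, "grade_thresholds"))
  keep <- include_array(include, volume)
  roi_name <- "volume"
  if (!is.null(roi)) {
    stopifnot(is_label_mask(roi))
    check_same_geometry(volume, roi)
    if (!is.null(label)) {
      code <- resolve_label(roi, label)
      keep <- keep & roi$data == code
      roi_name <- label_name(roi, code)
    } else {
      keep <- keep & roi$data > 0L
      if (length(roi$labels) == 1L) roi_name <- unname(roi$labels[[1L]])
    }
  }
  if (!any(keep)) stop("empty ROI: nothing to grade", call. = FALSE)
  codes <- array(GRADE_OUTSIDE, dim(volume$data))
  v <- volume$data[keep]
  g <- (v >= thresholds$t1) + (v >= thresholds$t2) + (v >= thresholds$t3)
  codes[keep] <- as.integer(g)
  new_grade_map(codes, stats::setNames(list(thresholds), roi_name),
                volume$voxel_size_um)
}

new_grade_map <- function(codes, thresholds, voxel_size_um) {
  counts <- vapply(0:3, function(k) sum(codes == k), numeric(1))
  names(counts) <- GRADE_NAMES
  n_graded <- sum(counts)
  stopifnot(n_graded == sum(codes != GRADE_OUTSIDE))  # conservation
  structure(list(data = codes, thresholds = thresholds, counts = counts,
                 fractions = counts / n_graded, n_graded = n_graded,
                 voxel_size_um = voxel_size_um),
            class = "grade_map")
}

#' @export
print.grade_map <- function(x, ...) {
  cat(sprintf("<grade_map> %d graded voxels (%s)\n", x$n_graded,
              paste(names(x$thresholds), collapse = ", ")))
  for (k in seq_along(x$counts))
    cat(sprintf("  %-12s %10d  (%.3f%%)\n", names(x$counts)[k],
                as.integer(x$counts[k]), 100 * x$fractions[k]))
  invisible(x)
}

#' Merge grade maps computed over disjoint ROIs
#'
#' Voxelwise union of per-ROI grade maps (each ROI graded with its own
#' thresholds, then assembled into a single volume image). Any voxel graded
#' in more than one map is an error; per-ROI threshold provenance is
#' retained.
#'
#' @param maps List of [grade_volume()] outputs over disjoint ROIs with the
#'   same geometry.
#' @return A merged `grade_map`.
#' @export
merge_roi_grades <- function(maps) {
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, logical(1), "grade_map")))
  dims <- dim(maps[[1L]]$data)
  codes <- array(GRADE_OUTSIDE, dims)
  thresholds <- list()
  for (m in maps) {
    if (!identical(dim(m$data), dims))
      stop("geometry mismatch between grade maps", call. = FALSE)
    sel <- m$data != GRADE_OUTSIDE
    if (any(codes[sel] != GRADE_OUTSIDE))
      stop("overlap error: grade maps cover overlapping voxels",
           call. = FALSE)
    codes[sel] <- m$data[sel]
    thresholds <- c(thresholds, m$thresholds)
  }
  new_grade_map(codes, thresholds, maps[[1L]]$voxel_size_um)
}

#' Export a grade map as a u8 TIFF stack plus JSON report
#'
#' @param map A `grade_map`.
#' @param tiff_path Output TIFF (codes 0-3, 255 = outside/excluded).
#' @param json_path Output JSON report (thresholds, counts, fractions).
#' @return `tiff_path`, invisibly.
#' @export
write_grade_map <- function(map, tiff_path, json_path = NULL) {
  stopifnot(inherits(map, "grade_map"))
  pages <- lapply(seq_len(dim(map$data)[1L]), function(i) map$data[i, , ])
  tiff_codec_write(pages, tiff_path, "u8")
  if (!is.null(json_path)) {
    thr <- lapply(map$thresholds, function(t)
      list(source = t$source, t1 = t$t1, t2 = t$t2, t3 = t$t3))
    jsonlite::write_json(
      list(thresholds = thr, counts = as.list(map$counts),
           fractions = as.list(map$fractions), n_graded = map$n_graded),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tiff_path)
}
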