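# Line-profile densitometry across tissue layers: parallel 1-voxel-wide
# stretches sampled on the voxel grid, paraffin background subtraction,
# 3-sample binning and mean +/- SEM versus physical distance.

parse_direction <- function(direction) {
  if (is.character(direction)) {
    axes <- c(slice = 1L, row = 2L, col = 3L)
    parts <- strsplit(gsub("-", "+-", direction, fixed = TRUE),
                      "+", fixed = TRUE)[[1L]]
    parts <- parts[nzchar(parts)]
    d <- c(0, 0, 0)
    for (p in parts) {
      sign <- 1
      if (startsWith(p, "-")) { sign <- -1; p <- substring(p, 2L) }
      if (!(p %in% names(axes)))
        stop("direction components must be slice/row/col", call. = FALSE)
      d[axes[[p]]] <- sign
    }
    direction <- d
  }
  direction <- as.numeric(direction)
  n_nonzero <- sum(direction != 0)
  if (length(direction) != 3L || !all(direction %in% c(-1, 0, 1)) ||
      n_nonzero < 1L || n_nonzero > 2L)
    stop("direction must be one grid axis or a 45-degree in-plane diagonal",
         call. = FALSE)
  direction
}

#' Extract a 1-voxel-wide line profile
#'
#' Samples the volume along a grid axis (or 45-degree two-axis diagonal) at
#' voxel-size steps with nearest-voxel lookup; raw values are untouched.
#' Distances are physical offsets from the start voxel, so a 300 um stretch
#' at 5 um/voxel yields `floor(300/5) + 1 = 61` samples.
#'
#' @param volume A [voxel_volume()].
#' @param start Integer voxel index `c(slice, row, col)` (1-based).
#' @param direction Axis spec: string such as `"col"`, `"-row"`,
#'   `"row+col"`, or an integer vector with components in `{-1, 0, 1}`.
#' @param length_um Physical length of the stretch in micrometres.
#' @return Object of class `line_profile` with fields `start`, `direction`,
#'   `step_um`, `values`, `distances_um`, `indices` (n x 3 matrix).
#' @export
extract_profile <- function(volume, start, direction, length_um) {
  stopifnot(is_voxel_volume(volume), length(start) == 3L, length_um >= 0)
  d <- parse_direction(direction)
  step_um <- volume$voxel_size_um
  n <- floor(length_um / step_um) + 1L
  unit <- d / sqrt(sum(d^2))
  t_vox <- (seq_len(n) - 1L) * 1  # steps of one voxel size along the line
  idx <- round(outer(t_vox, unit) +
               matrix(start, n, 3L, byrow = TRUE))
  dims <- dim(volume$data)
  if (any(idx < 1L) || any(idx[, 1L] > dims[1L]) || any(idx[, 2L] > dims[2L]) ||
      any(idx[, 3L] > dims[3L]))
    stop("bounds error: stretch exits the volume", call. = FALSE)
  values <- volume$data[idx]
  structure(list(start = as.integer(start), direction = d, step_um = step_um,
                 values = values,
                 distances_um = (seq_len(n) - 1L) * step_um,
                 indices = idx),
            class = "line_profile")
}

#' Extract several parallel line profiles
#'
#' Convenience wrapper mirroring the three-parallel-stretches protocol:
#' `n_lines` profiles with identical direction and length, with consecutive
#' start voxels offset by `separation_voxels` along `offset_direction`.
#'
#' @inheritParams extract_profile
#' @param n_lines Number of parallel lines (default 3).
#' @param separation_voxels Offset between adjacent lines (default 2 voxels).
#' @param offset_direction Axis spec of the offset (must be independent of
#'   `direction`).
#' @return List of [extract_profile()] results.
#' @export
extract_parallel_profiles <- function(volume, start, direction, length_um,
                                      n_lines = 3L, separation_voxels = 2L,
                                      offset_direction) {
  off <- parse_direction(offset_direction)
  lapply(seq_len(n_lines) - 1L, function(i)
    extract_profile(volume, start + i * separation_voxels * off,
                    direction, length_um))
}

#' Mean paraffin background from a reference stretch
#'
#' Arithmetic mean of a line profile sampled in an area occupied by paraffin
#' only. When a ground-truth or user mask is supplied the sampled voxels are
#' checked against `paraffin_label` and a warning is emitted on misuse.
#'
#' @inheritParams extract_profile
#' @param mask Optional [label_mask()] for the QC check.
#' @param paraffin_label Label code or name of paraffin in `mask`.
#' @return Scalar mean background intensity.
#' @export
paraffin_reference <- function(volume, start, direction, length_um,
                               mask = NULL, paraffin_label = "paraffin") {
  p <- extract_profile(volume, start, direction, length_um)
  if (!is.null(mask)) {
    check_same_geometry(volume, mask)
    code <- resolve_label(mask, paraffin_label)
    if (any(mask$data[p$indices] != code))
      warning("paraffin reference stretch crosses non-paraffin voxels",
              call. = FALSE)
  }
  mean(p$values)
}

#' Subtract a background value from parallel profiles
#'
#' Valuewise subtraction of the paraffin background from every sample of
#' every stretch; no clamping (corrected profiles may dip toward or below 0).
#'
#' @param profiles List of equal-length [extract_profile()] results.
#' @param background Scalar background intensity.
#' @return List of corrected `line_profile`s.
#' @export
correct_profiles <- function(profiles, background) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "line_profile")))
  lens <- vapply(profiles, function(p) length(p$values), integer(1))
  if (length(unique(lens)) != 1L)
    stop("length mismatch between parallel profiles", call. = FALSE)
  lapply(profiles, function(p) { p$values <- p$values - background; p })
}

#' Bin parallel profiles into mean +/- SEM versus distance
#'
#' In `"triplet"` mode (the default) each line is reduced to non-overlapping
#' means of `bin_width` consecutive samples; at each bin position, the
#' per-line means are combined into a mean and SEM (sample SD / sqrt(n_lines)).
#' Trailing samples short of a full bin are dropped, and the bin center is
#' the mean distance of the contributing samples. In `"across"` mode the
#' lines are instead combined sample-by-sample (mean and SEM over the
#' n_lines pixels at each position; no binning along the line).
#'
#' @param profiles List of equal-length corrected [extract_profile()]s.
#' @param bin_width Samples per bin along each line (default 3).
#' @param mode `"triplet"` or `"across"`.
#' @return Object of class `binned_profile` with fields `bin_centers_um`,
#'   `means`, `sems`, `n_per_bin`, `mode`.
#' @export
bin_profiles <- function(profiles, bin_width = 3L, mode = c("triplet",
                                                            "across")) {
  mode <- match.arg(mode)
  stopifnot(length(profiles) >= 2L,
            all(vapply(profiles, inherits, logical(1), "line_profile")))
  lens <- vapply(profiles, function(p) length(p$values), integer(1))
  if (length(unique(lens)) != 1L)
    stop("length mismatch between parallel profiles", call. = FALSE)
  n <- lens[1L]
  n_lines <- length(profiles)
  dist <- profiles[[1L]]$distances_um
  vals <- vapply(profiles, function(p) p$values, numeric(n))  # n x n_lines
  if (mode == "across") {
    means <- rowMeans(vals)
    sems <- apply(vals, 1L, stats::sd) / sqrt(n_lines)
    return(structure(list(bin_centers_um = dist, means = means, sems = sems,
                          n_per_bin = rep(n_lines, n), mode = mode),
                     class = "binned_profile"))
  }
  if (n < bin_width)
    stop("too short: need at least one full bin of samples", call. = FALSE)
  n_bins <- n %/% bin_width
  used <- seq_len(n_bins * bin_width)
  bin_of <- rep(seq_len(n_bins), each = bin_width)
  line_bin_means <- apply(vals[used, , drop = FALSE], 2L, function(v)
    tapply(v, bin_of, mean))
  line_bin_means <- matrix(line_bin_means, nrow = n_bins)
  means <- rowMeans(line_bin_means)
  sems <- apply(line_bin_means, 1L, stats::sd) / sqrt(n_lines)
  centers <- tapply(dist[used], bin_of, mean)
  structure(list(bin_centers_um = unname(centers), means = unname(means),
                 sems = unname(sems), n_per_bin = rep(n_lines, n_bins),
                 mode = mode),
            class = "binned_profile")
}

#' Peak of a binned profile
#'
#' Argmax of the bin means; ties resolve to the smallest distance.
#'
#' @param binned A [bin_profiles()] result.
#' @return Named numeric `c(distance_um = ..., value = ...)`.
#' @export
profile_peak <- function(binned) {
  stopifnot(inherits(binned, "binned_profile"), length(binned$means) >= 1L)
  i <- which.max(binned$means)
  c(distance_um = binned$bin_centers_um[i], value = binned$means[i])
}

#' Export a binned profile as CSV
#'
#' Columns `distance_um`, `mean`, `sem`, `n`.
#'
#' @param binned A [bin_profiles()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(binned, path) {
  stopifnot(inherits(binned, "binned_profile"))
  utils::write.csv(
    data.frame(distance_um = binned$bin_centers_um, mean = binned$means,
               sem = binned$sems, n = binned$n_per_bin),
    path, row.names = FALSE)
  invisible(path)
}

#' Plot a binned profile (mean +/- SEM vs distance)
#'
#' @param x A [bin_profiles()] result.
#' @param ... Passed to [plot()].
#' @export
plot.binned_profile <- function(x, ...) {
  graphics::plot(x$bin_centers_um, x$means, type = "b", pch = 16,
                 xlab = "distance (um)", ylab = "corrected gray value", ...)
  graphics::arrows(x$bin_centers_um, x$means - x$sems,
                   x$bin_centers_um, x$means + x$sems,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}
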