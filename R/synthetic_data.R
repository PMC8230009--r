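# Synthetic phantom generator. Emulates the statistical structure of a
# reconstructed micro-CT scan of an X-gal-stained, paraffin-embedded brain:
# a low-density noisy paraffin block, embedded tissue regions of higher
# endogenous radiodensity, reporter deposits that add density proportional to
# an abstract activity parameter, water/air calibration regions, and a
# two-layer "cerebellum" phantom with a density band at the layer boundary.
# Every phantom carries a ground-truth table so each pipeline stage can be
# checked against what was actually simulated.

#' Box geometry (voxel coordinates, inclusive bounds)
#' @param lo,hi Integer vectors `c(slice, row, col)`.
#' @return Geometry spec for [phantom_spec()].
#' @export
geom_box <- function(lo, hi) {
  stopifnot(length(lo) == 3L, length(hi) == 3L, all(hi >= lo), all(lo >= 1))
  list(type = "box", lo = as.integer(lo), hi = as.integer(hi))
}

#' Ellipsoid geometry (voxel coordinates)
#' @param center,radii Numeric vectors `c(slice, row, col)`.
#' @return Geometry spec for [phantom_spec()].
#' @export
geom_ellipsoid <- function(center, radii) {
  stopifnot(length(center) == 3L, length(radii) == 3L, all(radii > 0))
  list(type = "ellipsoid", center = as.numeric(center),
       radii = as.numeric(radii))
}

geometry_indicator <- function(geom, shape) {
  if (geom$type == "box") {
    if (any(geom$hi > shape))
      stop("spec error: geometry exceeds phantom shape", call. = FALSE)
    ind <- array(FALSE, shape)
    ind[geom$lo[1L]:geom$hi[1L], geom$lo[2L]:geom$hi[2L],
        geom$lo[3L]:geom$hi[3L]] <- TRUE
    return(ind)
  }
  if (geom$type == "ellipsoid") {
    if (any(geom$center + geom$radii > shape + 0.5) ||
        any(geom$center - geom$radii < 0.5))
      stop("spec error: geometry exceeds phantom shape", call. = FALSE)
    i <- slice.index(array(0L, shape), 1L)
    j <- slice.index(array(0L, shape), 2L)
    k <- slice.index(array(0L, shape), 3L)
    return(((i - geom$center[1L]) / geom$radii[1L])^2 +
           ((j - geom$center[2L]) / geom$radii[2L])^2 +
           ((k - geom$center[3L]) / geom$radii[3L])^2 <= 1)
  }
  stop("unknown geometry type", call. = FALSE)
}

#' Phantom specification
#'
#' Describes a synthetic raw-gray micro-CT phantom. The defaults define a
#' paraffin block (mean 20, SD 2) holding two ellipsoidal tissue regions of
#' distinct endogenous radiodensity ("cerebrum" mean 80, "hindbrain" mean 95,
#' SD 8 — an 8-bit-like gray scale), one reporter deposit inside the cerebrum
#' adding `kappa * activity` gray units (default activity 24 = 3 tissue SDs),
#' and water (mean 200, SD 2) / air (mean 10, SD 1) calibration slabs. Voxel
#' noise is independent Gaussian per region — regions are characterized by a
#' mean and an SD only — with a Student-t option for robustness checks.
#'
#' @param shape Volume extents `c(slices, rows, cols)`.
#' @param voxel_size_um Isotropic voxel size (default 20 um, the whole-brain
#'   scan resolution; the layer phantom defaults to 5 um).
#' @param paraffin `c(mean, sd)` of the paraffin background.
#' @param tissue_rois List of `list(name, geometry, mean, sd)`.
#' @param deposits List of `list(roi_name, geometry, activity)`; the added
#'   mean density is `delta = kappa * activity` and each deposit geometry
#'   must lie inside its ROI.
#' @param kappa Proportionality between reporter activity and added density
#'   (default 1; densities are directly proportional to reporter activity).
#' @param calibration `list(water = list(mean, sd, geometry), air = ...)`;
#'   water mean must exceed air mean.
#' @param layer_phantom Optional two-layer cerebellum spec, see
#'   [generate_layer_phantom()]; use [layer_phantom_spec()].
#' @param noise `"gaussian"` (default) or `"student_t"` (df 6, scaled to the
#'   stated SD).
#' @param seed Integer RNG seed; phantoms are bit-reproducible from it.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(40L, 80L, 80L),
                         voxel_size_um = 20,
                         paraffin = c(mean = 20, sd = 2),
                         tissue_rois = list(
                           list(name = "cerebrum",
                                geometry = geom_ellipsoid(c(20, 40, 28),
                                                          c(14, 24, 17)),
                                mean = 80, sd = 8),
                           list(name = "hindbrain",
                                geometry = geom_ellipsoid(c(20, 40, 62),
                                                          c(10, 16, 12)),
                                mean = 95, sd = 8)),
                         deposits = list(
                           list(roi_name = "cerebrum",
                                geometry = geom_ellipsoid(c(20, 40, 28),
                                                          c(6, 10, 8)),
                                activity = 24)),
                         kappa = 1,
                         calibration = list(
                           water = list(mean = 200, sd = 2,
                                        geometry = geom_box(c(1, 1, 1),
                                                            c(shape[1], 6, shape[3]))),
                           air = list(mean = 10, sd = 1,
                                      geometry = geom_box(c(1, shape[2] - 5, 1),
                                                          c(shape[1], shape[2], shape[3])))),
                         layer_phantom = NULL,
                         noise = c("gaussian", "student_t"),
                         seed = 1L) {
  noise <- match.arg(noise)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), voxel_size_um > 0,
            paraffin[["sd"]] >= 0, kappa > 0)
  if (!is.null(calibration)) {
    if (calibration$water$mean <= calibration$air$mean)
      stop("spec error: water mean must exceed air mean", call. = FALSE)
  }
  for (r in tissue_rois) stopifnot(r$sd >= 0)
  roi_names <- vapply(tissue_rois, `[[`, character(1), "name")
  for (d in deposits) {
    if (!(d$roi_name %in% roi_names))
      stop("spec error: deposit names unknown ROI ", d$roi_name,
           call. = FALSE)
  }
  structure(list(shape = shape, voxel_size_um = voxel_size_um,
                 paraffin = paraffin, tissue_rois = tissue_rois,
                 deposits = deposits, kappa = kappa,
                 calibration = calibration, layer_phantom = layer_phantom,
                 noise = noise, seed = as.integer(seed)),
            class = "phantom_spec")
}

draw_noise <- function(n, mean, sd, noise) {
  if (sd == 0) return(rep(mean, n))
  if (noise == "student_t") {
    df <- 6
    return(mean + sd * stats::rt(n, df) / sqrt(df / (df - 2)))
  }
  stats::rnorm(n, mean, sd)
}

#' Generate a phantom volume with ground truth
#'
#' Voxel values are drawn independently: paraffin noise everywhere,
#' overwritten by the water/air and tissue ROI distributions, then each
#' deposit adds `delta = kappa * activity` to the realized values inside its
#' geometry. The result is bit-reproducible from `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `phantom`: `volume` ([voxel_volume()], `RAW_GRAY`),
#'   `mask` ([label_mask()] with paraffin/water/air/ROI labels), `truth`
#'   (list with `regions` and `deposits` data.frames and `deposit_mask`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shape <- spec$shape
  n <- prod(shape)
  vol <- array(draw_noise(n, spec$paraffin[["mean"]], spec$paraffin[["sd"]],
                          spec$noise), shape)
  mask <- array(1L, shape)
  labels <- c("1" = "paraffin")
  next_code <- 2L
  regions <- list(list(name = "paraffin", label = 1L,
                       true_mean = spec$paraffin[["mean"]],
                       true_sd = spec$paraffin[["sd"]]))
  fill_region <- function(name, geom, mean, sd) {
    ind <- geometry_indicator(geom, shape)
    vol[ind] <<- draw_noise(sum(ind), mean, sd, spec$noise)
    mask[ind] <<- next_code
    labels[as.character(next_code)] <<- name
    regions[[length(regions) + 1L]] <<-
      list(name = name, label = next_code, true_mean = mean, true_sd = sd)
    next_code <<- next_code + 1L
    ind
  }
  if (!is.null(spec$calibration)) {
    fill_region("water", spec$calibration$water$geometry,
                spec$calibration$water$mean, spec$calibration$water$sd)
    fill_region("air", spec$calibration$air$geometry,
                spec$calibration$air$mean, spec$calibration$air$sd)
  }
  roi_ind <- list()
  for (r in spec$tissue_rois)
    roi_ind[[r$name]] <- fill_region(r$name, r$geometry, r$mean, r$sd)
  # deposits add density on top of the realized tissue noise
  dep_mask <- array(0L, shape)
  dep_labels <- character()
  dep_rows <- list()
  for (i in seq_along(spec$deposits)) {
    d <- spec$deposits[[i]]
    ind <- geometry_indicator(d$geometry, shape)
    if (any(ind & !roi_ind[[d$roi_name]]))
      stop("spec error: deposit geometry extends outside its ROI",
           call. = FALSE)
    delta <- spec$kappa * d$activity
    vol[ind] <- vol[ind] + delta
    dep_mask[ind] <- i
    dep_labels[as.character(i)] <- paste0("deposit_", i, "_", d$roi_name)
    dep_rows[[i]] <- list(deposit = i, roi = d$roi_name, delta = delta,
                          activity = d$activity, n_voxels = sum(ind))
  }
  region_df <- do.call(rbind, lapply(regions, as.data.frame))
  region_df$n_voxels <- vapply(region_df$label,
                               function(l) sum(mask == l), numeric(1))
  truth <- list(
    regions = region_df,
    deposits = if (length(dep_rows))
      do.call(rbind, lapply(dep_rows, as.data.frame))
    else data.frame(deposit = integer(), roi = character(),
                    delta = numeric(), activity = numeric(),
                    n_voxels = numeric()),
    deposit_mask = label_mask(dep_mask, dep_labels))
  structure(list(volume = voxel_volume(vol, spec$voxel_size_um, "RAW_GRAY"),
                 mask = label_mask(mask, labels),
                 truth = truth),
            class = "phantom")
}

#' Generate a matched reporter / wild-type phantom pair
#'
#' Emulates a littermate design: two phantoms sharing geometry and endogenous
#' distributions, differing only in the deposits (the wild type has none).
#' Noise seeds for the two volumes are derived deterministically from
#' `spec$seed`, so the pair is reproducible but the noise fields are
#' independent.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `lacz` and `wt`, each a `phantom`.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max, 2L)
  lacz_spec <- spec; lacz_spec$seed <- seeds[1L]
  wt_spec <- spec; wt_spec$seed <- seeds[2L]; wt_spec$deposits <- list()
  list(lacz = generate_phantom(lacz_spec), wt = generate_phantom(wt_spec))
}

#' Two-layer cerebellum phantom specification
#'
#' A tissue slab in a paraffin margin, split along the column axis into a
#' "molecular" layer (low endogenous density) and a "granular" layer (high),
#' with an optional deposit band of Gaussian cross-section straddling the
#' boundary — the density peak sits at the molecular/granular boundary, the
#' shape reported for reporter deposition in the cerebellar lobe. Distance 0
#' of a profile taken along the column axis is its start sample on the
#' molecular side, increasing toward the granular layer.
#'
#' @param shape Volume extents (default `c(12, 40, 100)`).
#' @param voxel_size_um Default 5 um (the cerebellar scan resolution).
#' @param paraffin,molecular,granular `c(mean, sd)` intensity pairs.
#' @param boundary_col First granular column (layer boundary).
#' @param band `list(center_col, width_voxels, delta)` or `NULL`; the band
#'   adds `delta * exp(-(col - center)^2 / (2 width^2))` inside the tissue.
#' @param margin_voxels Paraffin margin thickness around the tissue slab.
#' @param seed Integer RNG seed.
#' @return Object of class `layer_phantom_spec`.
#' @export
layer_phantom_spec <- function(shape = c(16L, 40L, 100L),
                               voxel_size_um = 5,
                               paraffin = c(mean = 20, sd = 2),
                               molecular = c(mean = 60, sd = 5),
                               granular = c(mean = 90, sd = 5),
                               boundary_col = 55L,
                               band = list(center_col = 55, width_voxels = 4,
                                           delta = 60),
                               margin_voxels = 6L,
                               seed = 1L) {
  shape <- as.integer(shape)
  m <- margin_voxels
  stopifnot(length(shape) == 3L, all(shape >= 2L * m + 1L),
            boundary_col > m, boundary_col <= shape[3L] - m)
  structure(list(shape = shape, voxel_size_um = voxel_size_um,
                 paraffin = paraffin, molecular = molecular,
                 granular = granular, boundary_col = as.integer(boundary_col),
                 band = band, margin_voxels = as.integer(m),
                 seed = as.integer(seed)),
            class = "layer_phantom_spec")
}

#' Generate a two-layer cerebellum phantom
#'
#' @param spec A [layer_phantom_spec()] (or a [phantom_spec()] whose
#'   `layer_phantom` field holds one).
#' @return List of class `phantom`: `volume`, `mask` (labels paraffin /
#'   molecular / granular), `truth` (layer table, boundary and band
#'   parameters, tissue bounds).
#' @export
generate_layer_phantom <- function(spec) {
  if (inherits(spec, "phantom_spec")) {
    if (is.null(spec$layer_phantom))
      stop("spec error: no layer_phantom present", call. = FALSE)
    spec <- spec$layer_phantom
  }
  stopifnot(inherits(spec, "layer_phantom_spec"))
  set.seed(spec$seed)
  shape <- spec$shape
  m <- spec$margin_voxels
  vol <- array(draw_noise(prod(shape), spec$paraffin[["mean"]],
                          spec$paraffin[["sd"]], "gaussian"), shape)
  mask <- array(1L, shape)
  tis_lo <- c(1L + m, 1L + m, 1L + m)
  tis_hi <- shape - m
  k <- slice.index(array(0L, shape), 3L)
  in_tissue <- array(FALSE, shape)
  in_tissue[tis_lo[1L]:tis_hi[1L], tis_lo[2L]:tis_hi[2L],
            tis_lo[3L]:tis_hi[3L]] <- TRUE
  mol <- in_tissue & k < spec$boundary_col
  gran <- in_tissue & k >= spec$boundary_col
  vol[mol] <- draw_noise(sum(mol), spec$molecular[["mean"]],
                         spec$molecular[["sd"]], "gaussian")
  vol[gran] <- draw_noise(sum(gran), spec$granular[["mean"]],
                          spec$granular[["sd"]], "gaussian")
  mask[mol] <- 2L
  mask[gran] <- 3L
  if (!is.null(spec$band) && spec$band$delta != 0) {
    bump <- spec$band$delta *
      exp(-(k - spec$band$center_col)^2 / (2 * spec$band$width_voxels^2))
    vol[in_tissue] <- vol[in_tissue] + bump[in_tissue]
  }
  truth <- list(
    layers = data.frame(
      layer = c("molecular", "granular"),
      true_mean = c(spec$molecular[["mean"]], spec$granular[["mean"]]),
      true_sd = c(spec$molecular[["sd"]], spec$granular[["sd"]]),
      n_voxels = c(sum(mol), sum(gran))),
    boundary_col = spec$boundary_col,
    band = spec$band,
    tissue_lo = tis_lo, tissue_hi = tis_hi)
  structure(list(volume = voxel_volume(vol, spec$voxel_size_um, "RAW_GRAY"),
                 mask = label_mask(mask, c("1" = "paraffin",
                                           "2" = "molecular",
                                           "3" = "granular")),
                 truth = truth),
            class = "phantom")
}

#' Write a phantom's ground truth tables to JSON
#'
#' @param phantom A `phantom`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom"))
  truth <- phantom$truth
  truth$deposit_mask <- NULL
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
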