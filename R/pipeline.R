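# Pipeline orchestration: read -> (optional) HU calibration -> per-ROI Otsu
# paraffin exclusion -> ROI statistics -> SD thresholds -> grading -> merge ->
# report bundle, and the line-profile route. Every run writes a manifest
# (config hash, package version, seed) and identical configs yield
# byte-identical reports.

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Load a run configuration from YAML (or pass a list through)
#'
#' @param config YAML file path or a configuration list.
#' @return The configuration list.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

resolve_volume <- function(x, voxel_size_um = NULL) {
  if (is_voxel_volume(x)) return(x)
  read_volume(x, voxel_size_um = voxel_size_um)
}

resolve_mask <- function(x, labels = character()) {
  if (is_label_mask(x)) return(x)
  read_mask(x, labels)
}

write_manifest <- function(config, out_dir, outputs) {
  jsonlite::write_json(
    list(package = "xgalvox",
         version = as.character(utils::packageVersion("xgalvox")),
         config = config, config_md5 = config_hash(config),
         seed = config$seed, outputs = outputs),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
}

#' Run the SD-graded quantification workflow
#'
#' Executes the full relative-quantification route on a reporter volume (and
#' optionally a matched wild-type volume): optional two-point HU calibration,
#' per-ROI Otsu paraffin exclusion, per-ROI statistics, mean + k SD grade
#' thresholds (regime `"SELF"`: thresholds from the reporter dataset itself;
#' regime `"WT"`: from the wild-type), per-ROI grading, assembly into a
#' single grade volume, and — when a wild-type volume is present —
#' background-corrected region means. All tables, the grade TIFF stack and a
#' manifest are written under `out_dir`.
#'
#' Configuration fields: `volume` (path or [voxel_volume()]), `wt_volume`
#' (optional), `mask` (path or [label_mask()]), `mask_labels` (label map if
#' `mask` is a path), `rois` (character vector of ROI names), `regime`
#' (`"SELF"` or `"WT"`), `calibrate` (`list(water_label, air_label)` or
#' omitted), `otsu` (`list(enabled, n_bins)`), `voxel_size_um` (override),
#' `seed`.
#'
#' @param config Configuration list or YAML path (see [load_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `lacz_stats`, `wt_stats`, `corrected`,
#'   `grade_map`, `wt_grade_map`, `thresholds`, `calibration`, `units`,
#'   `outputs`.
#' @export
run_quantification <- function(config, out_dir) {
  config <- load_run_config(config)
  regime <- toupper(config$regime %||% "SELF")
  pipeline_stage("validate", {
    if (!(regime %in% c("SELF", "WT")))
      stop("regime must be SELF or WT", call. = FALSE)
    if (is.null(config$volume)) stop("config$volume missing", call. = FALSE)
    if (is.null(config$mask)) stop("config$mask missing", call. = FALSE)
    if (regime == "WT" && is.null(config$wt_volume))
      stop("regime WT requires a wt_volume", call. = FALSE)
    if (is.null(config$rois) || !length(config$rois))
      stop("config$rois must name at least one ROI", call. = FALSE)
  })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  vol <- pipeline_stage("read",
    resolve_volume(config$volume, config$voxel_size_um))
  mask <- pipeline_stage("read",
    resolve_mask(config$mask, config$mask_labels %||% character()))
  pipeline_stage("validate", {
    check_same_geometry(vol, mask)
    missing_rois <- setdiff(config$rois, unname(mask$labels))
    if (length(missing_rois))
      stop("ROI label(s) not in mask: ",
           paste(missing_rois, collapse = ", "), call. = FALSE)
  })
  wt <- if (!is.null(config$wt_volume))
    pipeline_stage("read", resolve_volume(config$wt_volume,
                                          config$voxel_size_um))

  model <- NULL
  if (!is.null(config$calibrate)) {
    model <- pipeline_stage("calibrate",
      fit_calibration(vol, mask, config$calibrate$water_label,
                      config$calibrate$air_label,
                      acquisition_id = config$calibrate$acquisition_id))
    vol <- apply_calibration(vol, model)
    if (!is.null(wt)) wt <- pipeline_stage("calibrate",
                                           apply_calibration(wt, model))
  }

  otsu_on <- isTRUE((config$otsu %||% list(enabled = TRUE))$enabled %||% TRUE)
  n_bins <- (config$otsu %||% list())$n_bins %||% 256L
  maps <- list(); wt_maps <- list()
  lacz_rows <- list(); wt_rows <- list()
  for (roi in config$rois) {
    inc <- if (otsu_on)
      pipeline_stage("otsu",
        exclude_background(vol, mask, label = roi, n_bins = n_bins))
    wt_inc <- if (otsu_on && !is.null(wt))
      pipeline_stage("otsu",
        exclude_background(wt, mask, label = roi, n_bins = n_bins))
    ls <- pipeline_stage("stats",
      roi_stats(vol, mask, include = inc, labels = roi))
    lacz_rows[[roi]] <- ls
    ws <- if (!is.null(wt))
      pipeline_stage("stats", roi_stats(wt, mask, include = wt_inc,
                                        labels = roi))
    if (!is.null(ws)) wt_rows[[roi]] <- ws
    thr <- pipeline_stage("thresholds",
      grade_thresholds(if (regime == "SELF") ls else ws, source = regime))
    maps[[roi]] <- pipeline_stage("grade",
      grade_volume(vol, thr, roi = mask, label = roi, include = inc))
    if (!is.null(wt))
      wt_maps[[roi]] <- pipeline_stage("grade",
        grade_volume(wt, thr, roi = mask, label = roi, include = wt_inc))
  }
  merged <- pipeline_stage("merge", merge_roi_grades(unname(maps)))
  wt_merged <- if (length(wt_maps))
    pipeline_stage("merge", merge_roi_grades(unname(wt_maps)))

  lacz_stats <- do.call(rbind, unname(lacz_rows))
  wt_stats <- if (length(wt_rows)) do.call(rbind, unname(wt_rows))
  corrected <- if (!is.null(wt_stats))
    corrected_region_means(lacz_stats, wt_stats)

  outputs <- character()
  emit <- pipeline_stage("export", {
    p <- file.path(out_dir, "roi_stats_lacz.csv")
    utils::write.csv(lacz_stats, p, row.names = FALSE)
    outputs <- p
    if (!is.null(wt_stats)) {
      p <- file.path(out_dir, "roi_stats_wt.csv")
      utils::write.csv(wt_stats, p, row.names = FALSE)
      outputs <- c(outputs, p)
    }
    if (!is.null(corrected)) {
      p <- file.path(out_dir, "corrected_means.csv")
      utils::write.csv(corrected, p, row.names = FALSE)
      outputs <- c(outputs, p)
    }
    write_grade_map(merged, file.path(out_dir, "grade_map.tif"),
                    file.path(out_dir, "grade_report.json"))
    outputs <- c(outputs, file.path(out_dir, "grade_map.tif"),
                 file.path(out_dir, "grade_report.json"))
    if (!is.null(wt_merged)) {
      write_grade_map(wt_merged, file.path(out_dir, "grade_map_wt.tif"),
                      file.path(out_dir, "grade_report_wt.json"))
      outputs <- c(outputs, file.path(out_dir, "grade_map_wt.tif"),
                   file.path(out_dir, "grade_report_wt.json"))
    }
    if (!is.null(model)) {
      p <- file.path(out_dir, "calibration.json")
      write_calibration(model, p)
      outputs <- c(outputs, p)
    }
    outputs
  })
  write_manifest(config, out_dir, basename(emit))
  invisible(list(lacz_stats = lacz_stats, wt_stats = wt_stats,
                 corrected = corrected, grade_map = merged,
                 wt_grade_map = wt_merged, calibration = model,
                 units = vol$units, outputs = emit))
}

#' Run the line-profile densitometry workflow
#'
#' Extracts parallel 1-voxel-wide stretches, computes the paraffin reference,
#' subtracts it, bins the corrected profiles and locates the peak; writes a
#' CSV per requested mode, a peak JSON and a manifest.
#'
#' Configuration fields: `volume` (path or [voxel_volume()]),
#' `voxel_size_um` (override), `profile` = `list(start, direction, length_um,
#' n_lines, separation_voxels, offset_direction)`, `paraffin_ref` =
#' `list(start, direction, length_um)`, `bin_width` (default 3), `modes`
#' (default `"triplet"`), `seed`.
#'
#' @param config Configuration list or YAML path.
#' @param out_dir Output directory.
#' @return Invisibly, a list with per-mode `binned` profiles, `peaks`,
#'   `background` and `outputs`.
#' @export
run_profile <- function(config, out_dir) {
  config <- load_run_config(config)
  pipeline_stage("validate", {
    if (is.null(config$volume)) stop("config$volume missing", call. = FALSE)
    if (is.null(config$profile)) stop("config$profile missing", call. = FALSE)
    if (is.null(config$paraffin_ref))
      stop("config$paraffin_ref missing", call. = FALSE)
    if ((config$profile$length_um %||% 0) <= 0)
      stop("profile length_um must be positive", call. = FALSE)
  })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vol <- pipeline_stage("read",
    resolve_volume(config$volume, config$voxel_size_um))
  pr <- config$profile
  profiles <- pipeline_stage("extract",
    extract_parallel_profiles(vol, unlist(pr$start), pr$direction,
                              pr$length_um, n_lines = pr$n_lines %||% 3L,
                              separation_voxels = pr$separation_voxels %||% 2L,
                              offset_direction = pr$offset_direction))
  bg <- pipeline_stage("paraffin_reference",
    paraffin_reference(vol, unlist(config$paraffin_ref$start),
                       config$paraffin_ref$direction,
                       config$paraffin_ref$length_um))
  corrected <- pipeline_stage("correct", correct_profiles(profiles, bg))
  modes <- config$modes %||% "triplet"
  outputs <- character()
  binned <- list(); peaks <- list()
  for (mode in modes) {
    b <- pipeline_stage("bin",
      bin_profiles(corrected, bin_width = config$bin_width %||% 3L,
                   mode = mode))
    binned[[mode]] <- b
    peaks[[mode]] <- as.list(profile_peak(b))
    p <- file.path(out_dir, sprintf("profile_%s.csv", mode))
    write_profile_csv(b, p)
    outputs <- c(outputs, p)
  }
  pj <- file.path(out_dir, "profile_peaks.json")
  jsonlite::write_json(list(background = bg, peaks = peaks), pj,
                       auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, pj)
  write_manifest(config, out_dir, basename(outputs))
  invisible(list(binned = binned, peaks = peaks, background = bg,
                 outputs = outputs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
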