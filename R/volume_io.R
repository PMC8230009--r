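# Volume and mask IO: multi-page grayscale TIFF (or a directory of
# single-page TIFFs) plus a JSON sidecar carrying voxel size and units.

sidecar_path <- function(path) {
  if (dir.exists(path)) return(file.path(path, "volume.json"))
  paste0(tools::file_path_sans_ext(path), ".json")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' List the TIFF slice files of a directory in lexicographic order
#' @keywords internal
#' @noRd
slice_files <- function(path) {
  files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                      full.names = TRUE)
  sort(files, method = "radix")
}

read_tiff_pages <- function(path) {
  tryCatch(
    tiff_codec_read(path),
    xgalvox_tiff_unsupported = function(cnd) {
      img <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
      if (!is.list(img)) img <- list(img)
      lapply(img, function(m) {
        if (length(dim(m)) == 3L)
          stop("multichannel (RGB) TIFF pages are not grayscale volumes",
               call. = FALSE)
        storage.mode(m) <- "double"
        m
      })
    })
}

#' Read a volume from a TIFF stack
#'
#' Accepts either a multi-page grayscale TIFF file or a directory of
#' equally-shaped single-page grayscale TIFFs. Directory slices are assembled
#' in lexicographic filename order along axis 1 (slice axis); multi-page
#' files in page order. Integer pixel data are widened to double without any
#' rescaling: threshold arithmetic throughout the package operates on native
#' reconstruction gray values.
#'
#' A JSON sidecar (`<stem>.json` next to a file, `volume.json` inside a
#' directory) supplies `voxel_size_um` and optionally `units`; explicit
#' arguments override it. `units` defaults to `"RAW_GRAY"`.
#'
#' @param path TIFF file or slice directory.
#' @param voxel_size_um Voxel size override (required if no sidecar).
#' @param units Units override (`"RAW_GRAY"` or `"HU"`).
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, voxel_size_um = NULL, units = NULL) {
  meta <- read_sidecar(path)
  if (is.null(voxel_size_um)) voxel_size_um <- meta$voxel_size_um
  if (is.null(units)) units <- if (!is.null(meta$units)) meta$units
                               else "RAW_GRAY"
  if (is.null(voxel_size_um))
    stop("voxel_size_um not given and no sidecar metadata found",
         call. = FALSE)
  if (dir.exists(path)) {
    files <- slice_files(path)
    if (!length(files))
      stop("empty input: no TIFF slices found in directory", call. = FALSE)
    pages <- unlist(lapply(files, read_tiff_pages), recursive = FALSE)
  } else {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    pages <- read_tiff_pages(path)
  }
  if (!length(pages))
    stop("empty input: TIFF contains zero slices", call. = FALSE)
  shapes <- vapply(pages, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("geometry error: slices have mixed shapes", call. = FALSE)
  data <- array(0, dim = c(length(pages), shapes[1, 1], shapes[2, 1]))
  for (i in seq_along(pages)) data[i, , ] <- pages[[i]]
  voxel_volume(data, voxel_size_um, units)
}

#' Write a volume as a multi-page TIFF with JSON sidecar
#'
#' `"f32"` stores IEEE single-precision samples, exact for values already
#' representable in single precision. `"u8"`/`"u16"` round half-to-even and
#' refuse values outside the representable range after rounding.
#'
#' @param volume A [voxel_volume()].
#' @param path Output TIFF path.
#' @param bit_depth `"u8"`, `"u16"` or `"f32"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, bit_depth = c("f32", "u16", "u8")) {
  bit_depth <- match.arg(bit_depth)
  stopifnot(is_voxel_volume(volume))
  data <- volume$data
  if (bit_depth != "f32") {
    maxv <- if (bit_depth == "u8") 255 else 65535
    data <- round(data)  # round half to even
    if (any(data < 0) || any(data > maxv))
      stop(sprintf("range error: values outside [0, %d] cannot be stored as %s",
                   maxv, bit_depth), call. = FALSE)
  }
  pages <- lapply(seq_len(dim(data)[1L]), function(i) data[i, , ])
  tiff_codec_write(pages, path, bit_depth)
  jsonlite::write_json(
    list(voxel_size_um = volume$voxel_size_um, units = volume$units),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label mask from an integer TIFF stack
#'
#' @param path TIFF file or slice directory (as [read_volume()]).
#' @param labels Label map, named by integer code (see [label_mask()]); may
#'   also be the path of a JSON file `{"1": "cortex", ...}`.
#' @return A [label_mask()].
#' @export
read_mask <- function(path, labels = character()) {
  if (is.character(labels) && length(labels) == 1L && is.null(names(labels)) &&
      file.exists(labels) && grepl("\\.json$", labels)) {
    labels <- unlist(jsonlite::read_json(labels, simplifyVector = TRUE))
  }
  vol <- read_volume(path, voxel_size_um = 1)
  if (any(vol$data != round(vol$data)))
    stop("format error: mask TIFF contains non-integer pixel values",
         call. = FALSE)
  label_mask(vol$data, labels)
}

#' Write a label mask as an integer TIFF stack with JSON label map
#'
#' Uses 8-bit samples when all codes fit, 16-bit otherwise.
#'
#' @param mask A [label_mask()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is_label_mask(mask))
  depth <- if (max(mask$data) <= 255L) "u8" else "u16"
  pages <- lapply(seq_len(dim(mask$data)[1L]), function(i) mask$data[i, , ])
  tiff_codec_write(pages, path, depth)
  jsonlite::write_json(as.list(mask$labels),
                       paste0(tools::file_path_sans_ext(path), "_labels.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
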