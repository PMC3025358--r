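# File interfaces: NIfTI and multi-page TIFF volumes, CSV/JSON point and
# flow tables, and reproducible run configurations.
#
# Axis convention: in memory, volumes are arrays indexed [x, y, z], voxel
# indices 1-based. NIfTI arrays map directly. TIFF pages are z-slices whose
# matrix rows are y and columns are x, so slices are transposed on read and
# write. Exported CSV coordinates are 0-based (voxel and refined positions
# alike); readers add 1 back.

volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
  else stop("unrecognized volume format: ", path, call. = FALSE)
}

#' Read a 3D volume from NIfTI or multi-page TIFF
#'
#' @param path file path; `.nii`/`.nii.gz` or `.tif`/`.tiff`.
#' @return 3D numeric array indexed `[x, y, z]`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    a <- as.array(RNifti::readNifti(path))
    if (length(dim(a)) != 3L)
      stop(sprintf("expected a 3D volume, got %dD; use read_sequence() for 4D",
                   length(dim(a))), call. = FALSE)
    a
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 3L)
      stop("TIFF has fewer than 3 pages; not a 3D volume", call. = FALSE)
    if (length(dim(pages[[1L]])) != 2L)
      stop("multi-channel TIFF pages are not supported", call. = FALSE)
    aperm(simplify2array(pages), c(2L, 1L, 3L))
  }
}

#' Write a 3D volume to NIfTI or multi-page TIFF
#'
#' NIfTI volumes are stored as float64 (bit-exact round trip); TIFF as
#' 32-bit float pages (round trip exact to single precision).
#'
#' @param volume 3D numeric array.
#' @param path destination; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  check_volume(volume)
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    RNifti::writeNifti(volume, path, datatype = "double")
  } else {
    pages <- lapply(seq_len(dim(volume)[3L]),
                    function(k) t(volume[, , k]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read an ordered volume sequence
#'
#' Accepts a 4D NIfTI file (4th dimension = time) or a directory of 3D
#' volume files (sorted by file name).
#'
#' @param path 4D NIfTI file or directory of volumes.
#' @return a [volume_sequence()].
#' @export
read_sequence <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(nii(\\.gz)?|tiff?)$",
                             full.names = TRUE, ignore.case = TRUE))
    if (length(files) < 3L)
      stop("directory contains fewer than 3 volume files", call. = FALSE)
    return(volume_sequence(lapply(files, read_volume)))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) != 4L)
    stop("expected a 4D NIfTI or a directory of 3D volumes", call. = FALSE)
  volume_sequence(lapply(seq_len(dim(a)[4L]), function(t) a[, , , t]))
}

#' Write a volume sequence as one file per frame
#'
#' @param sequence a [volume_sequence()] or list of 3D arrays.
#' @param dir destination directory (created if missing).
#' @param prefix file name prefix.
#' @param format `"nifti"` or `"tiff"`.
#' @return character vector of file paths, invisibly.
#' @export
write_sequence <- function(sequence, dir, prefix = "frame",
                           format = c("nifti", "tiff")) {
  format <- match.arg(format)
  frames <- if (inherits(sequence, "volume_sequence")) sequence$frames else
    sequence
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "nifti") ".nii.gz" else ".tif"
  paths <- file.path(dir, sprintf("%s_%03d%s", prefix,
                                  seq_along(frames) - 1L, ext))
  for (i in seq_along(frames)) write_volume(frames[[i]], paths[i])
  invisible(paths)
}

# ---- run configuration ----------------------------------------------------

#' Reproducible run configuration
#'
#' A named list of the parameters that determine a run; written as a JSON
#' sidecar next to every exported table so that any output can be
#' regenerated from its sidecar alone.
#'
#' @param ... named parameters (scale, mode, polarity, thresholds, seed,
#'   paths, ...).
#' @return list of class `run_config` (includes the package version).
#' @export
run_config <- function(...) {
  cfg <- list(...)
  cfg$package <- "winding3d"
  cfg$version <- as.character(utils::packageVersion("winding3d"))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config` (or plain named list).
#' @param path JSON destination.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_config")
}

sidecar_path <- function(path) sub("\\.[A-Za-z]+$", ".json", path)

# ---- point / flow tables --------------------------------------------------

#' Export critical points as CSV (+ JSON sidecar)
#'
#' Columns: `voxel_x, voxel_y, voxel_z` (0-based integer voxel), `x, y, z`
#' (0-based refined continuous position; equal to the voxel when not
#' refined), `nu, k, sign_det_h, index, type, scale`, and the flags
#' `degenerate, divergent, converged`. A JSON sidecar with the
#' configuration and package version is written next to the CSV.
#'
#' @param points a [detect_critical_points()] /
#'   [refine_critical_points()] table.
#' @param path CSV destination.
#' @param config optional [run_config()] for the sidecar.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path, config = run_config()) {
  has_ref <- "rx" %in% names(points)
  out <- data.frame(
    voxel_x = points$x - 1L, voxel_y = points$y - 1L,
    voxel_z = points$z - 1L,
    x = (if (has_ref) points$rx else points$x) - 1,
    y = (if (has_ref) points$ry else points$y) - 1,
    z = (if (has_ref) points$rz else points$z) - 1,
    nu = points$nu, k = points$k, sign_det_h = points$sign_det_h,
    index = points$index, type = points$type, scale = points$scale,
    degenerate = points$degenerate,
    divergent = if (has_ref) points$divergent else FALSE,
    converged = if (has_ref) points$converged else FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  config$columns <- "coordinates are 0-based"
  write_config(config, sidecar_path(path))
  invisible(path)
}

#' Export / import a flow field as CSV (+ JSON sidecar)
#'
#' Columns: `frame` (1-based frame index), `x, y, z` (0-based refined
#' position), `u, v, w` (voxels/frame), `cond_h`, `valid`, `reason`.
#'
#' @param flow a [track_and_flow()] result.
#' @param path CSV destination.
#' @param config optional [run_config()] for the sidecar.
#' @return `path`, invisibly.
#' @export
write_flow <- function(flow, path, config = run_config()) {
  out <- as.data.frame(flow)
  out$x <- out$x - 1; out$y <- out$y - 1; out$z <- out$z - 1
  utils::write.csv(out, path, row.names = FALSE)
  config$columns <- "coordinates are 0-based"
  write_config(config, sidecar_path(path))
  invisible(path)
}

#' @rdname write_flow
#' @export
read_flow <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$x <- out$x + 1; out$y <- out$y + 1; out$z <- out$z + 1
  if (is.null(out$reason)) out$reason <- ""
  out$reason[is.na(out$reason)] <- ""
  class(out) <- c("flow_field", "data.frame")
  out
}
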