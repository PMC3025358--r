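# Blob counting: winding-number extrema inside an optional mask, with
# optional scale-normalized Laplacian enhancement, plus the 26-neighbor
# comparison baseline.

#' Count blob-like structures in a masked volume
#'
#' Pipeline: optional scale-normalized Laplacian enhancement at scale `s`;
#' derivative jet at scale `s` (of the enhanced volume when enhancement is
#' on); winding field in degree mode; critical-point detection; polarity
#' filter (keep minima or maxima); mask filter (points whose voxel falls
#' outside the mask are dropped); Newton subpixel refinement.
#'
#' The scale trades off noise suppression against resolution: too small a
#' scale detects intensity grains, too large a scale merges or misses small
#' blobs. A scale matched to the blob size (`s = sigma_blob^2 / 2`, i.e.
#' smoothing sigma equal to the blob sigma) is a good starting point. Note
#' that with `enhance = TRUE` the polarity refers to extrema of the
#' enhanced volume: bright blobs give negative Laplacian response and are
#' counted as minima, dark blobs as maxima.
#'
#' @param volume 3D numeric array.
#' @param s scale parameter (kernel variance `2 s`); or give `sigma`.
#' @param polarity `"minima"` or `"maxima"`.
#' @param mask optional logical/0-1 array of the same dimensions; points
#'   outside it are discarded.
#' @param enhance apply scale-normalized Laplacian blob enhancement first.
#' @param sigma alternative bandwidth parameterization, see
#'   [smooth_volume()].
#' @param min_contrast optional contrast filter: keep only points whose
#'   smoothed intensity differs from the volume's median smoothed intensity
#'   by at least this amount. `NULL` (default) disables it.
#' @param drop_degenerate drop points flagged degenerate. Default `TRUE`.
#' @return list of class `blob_count`: `count`, `points` (the refined
#'   [detect_critical_points()] table), and `parameters`.
#' @export
count_blobs <- function(volume, s = NULL, polarity = c("minima", "maxima"),
                        mask = NULL, enhance = FALSE, sigma = NULL,
                        min_contrast = NULL, drop_degenerate = TRUE) {
  check_volume(volume)
  polarity <- match.arg(polarity)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(volume)))
      stop("mask dimensions do not match the volume", call. = FALSE)
    mask <- mask > 0
    if (!any(mask)) {
      warning("mask is empty; count is 0")
      return(structure(list(count = 0L, points = empty_critical_points(),
                            parameters = list(s = s, sigma = sigma,
                                              polarity = polarity,
                                              enhance = enhance,
                                              masked = TRUE)),
                       class = "blob_count"))
    }
  }
  work <- if (enhance) scale_normalized_laplacian(volume, s = s,
                                                  sigma = sigma) else volume
  jet <- gaussian_jet(work, s = s, sigma = sigma)
  field <- winding_field(jet, mode = "degree")
  pts <- detect_critical_points(field, jet)
  want <- if (polarity == "minima") "minimum" else "maximum"
  pts <- pts[pts$type == want, , drop = FALSE]
  if (drop_degenerate) pts <- pts[!pts$degenerate, , drop = FALSE]
  if (!is.null(mask) && nrow(pts))
    pts <- pts[mask[cbind(pts$x, pts$y, pts$z)], , drop = FALSE]
  pts <- refine_critical_points(pts, jet)
  if (!is.null(min_contrast) && nrow(pts)) {
    med <- stats::median(jet$l)
    depth <- abs(jet$l[cbind(pts$x, pts$y, pts$z)] - med)
    pts <- pts[depth >= min_contrast, , drop = FALSE]
  }
  rownames(pts) <- NULL
  structure(list(count = nrow(pts), points = pts,
                 parameters = list(s = jet$s, sigma = jet$sigma,
                                   polarity = polarity, enhance = enhance,
                                   min_contrast = min_contrast,
                                   masked = !is.null(mask))),
            class = "blob_count")
}

#' @export
print.blob_count <- function(x, ...) {
  p <- x$parameters
  cat(sprintf(
    "<blob_count> %d %s at s = %.4g (sigma = %.4g)%s%s\n",
    x$count, p$polarity, p$s, p$sigma,
    if (isTRUE(p$enhance)) ", Laplacian-enhanced" else "",
    if (isTRUE(p$masked)) ", masked" else ""))
  invisible(x)
}

#' 26-neighbor local extrema (baseline detector)
#'
#' Strict-inequality comparison of every interior voxel against its 26
#' neighbors. Plateaus yield no detection. This is the simple
#' intensity-comparison baseline the winding detector is measured against;
#' unlike the winding number it sees only extrema, never saddles.
#'
#' @param volume 3D numeric array.
#' @param polarity `"minima"` or `"maxima"`.
#' @return integer matrix with one row per extremum (1-based voxel `x, y,
#'   z`).
#' @export
local_extrema_26 <- function(volume, polarity = c("minima", "maxima")) {
  check_volume(volume)
  polarity <- match.arg(polarity)
  d <- dim(volume)
  center <- shift_interior(volume, c(0L, 0L, 0L))
  is_ext <- array(TRUE, d - 2L)
  for (r in seq_len(26L)) {
    off <- surface_offsets_26()[r, ]
    nb <- shift_interior(volume, off)
    is_ext <- is_ext & (if (polarity == "minima") center < nb else
                          center > nb)
  }
  w <- which(is_ext, arr.ind = TRUE)
  w <- w + 1L  # interior -> full-grid indices
  colnames(w) <- c("x", "y", "z")
  w
}
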