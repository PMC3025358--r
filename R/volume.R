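#' @keywords internal
"_PACKAGE"

# Shared validation helpers for 3D scalar volumes.
#
# A volume is a plain 3D numeric array with isotropic unit voxels. Voxel
# indices are 1-based (R convention) throughout the in-memory API; exported
# CSV files use 0-based coordinates (see write_points).

check_volume <- function(volume, arg = "volume") {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop(sprintf("`%s` must be a 3D array", arg), call. = FALSE)
  if (any(dim(volume) < 3L))
    stop(sprintf("`%s` must have at least 3 voxels along every axis", arg),
         call. = FALSE)
  if (!all(is.finite(volume)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  invisible(volume)
}

check_scale <- function(s, arg = "s") {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop(sprintf("`%s` must be a single positive number", arg), call. = FALSE)
  invisible(s)
}

# Resolve the smoothing bandwidth from either the diffusion-type scale
# parameter s (kernel variance 2*s) or an explicit standard deviation sigma.
resolve_sigma <- function(s = NULL, sigma = NULL) {
  if (is.null(sigma)) {
    check_scale(s, "s")
    sigma <- sqrt(2 * s)
  } else {
    check_scale(sigma, "sigma")
  }
  sigma
}
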