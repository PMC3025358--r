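# Synthetic test volumes: quadratic critical-point fixtures, Gaussian blob
# fields, and the expanding sine-grid phantom with closed-form ground-truth
# motion.

#' Sampled quadratic form with a critical point at the grid center
#'
#' Samples `0.5 * (s1 x^2 + s2 y^2 + s3 z^2)` (coordinates centered on the
#' middle voxel) on a cubic grid of odd size. The center voxel is a
#' minimum, 1-saddle, 2-saddle or maximum according to the number of
#' negative signs.
#'
#' @param axis_signs numeric length 3, the signs (or coefficients) per axis.
#' @param size odd integer >= 7.
#' @return 3D array with attribute `center` (1-based center voxel index).
#' @export
quadratic_volume <- function(axis_signs, size = 15L) {
  stopifnot(length(axis_signs) == 3L)
  if (size %% 2L == 0L || size < 7L)
    stop("size must be odd and >= 7", call. = FALSE)
  h <- (size - 1L) / 2L
  cc <- seq.int(-h, h)
  v <- 0.5 * (outer(outer(axis_signs[1L] * cc^2, axis_signs[2L] * cc^2, "+"),
                    axis_signs[3L] * cc^2, "+"))
  attr(v, "center") <- rep(h + 1L, 3L)
  v
}

#' Sum-of-Gaussian-blobs volume with ground truth
#'
#' Builds `background + sum_i amplitude_i * exp(-|x - c_i|^2 / (2 sigma_i^2))`
#' plus optional i.i.d. Gaussian noise. Emulates roughly spherical
#' structures (follicles in ultrasound appear dark on brighter tissue,
#' labeled cell bodies bright on dark background) at known positions, for
#' recovery tests.
#'
#' @param centers n x 3 matrix of blob centers (1-based, may be fractional).
#' @param sigma blob standard deviation(s), scalar or length n.
#' @param amplitude blob amplitude(s); negative for dark blobs.
#' @param background constant background intensity.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed RNG seed for the noise (recorded in the result); required
#'   when `noise_sd > 0` so volumes regenerate bit-identically.
#' @param size grid size per axis (scalar or length 3).
#' @return list of class `blob_field` with `volume`, `centers`, `sigma`,
#'   `amplitude`, `background`, `noise_sd`, `seed`.
#' @export
blob_volume <- function(centers, sigma, amplitude, background = 0,
                        noise_sd = 0, seed = NULL, size = 64L) {
  centers <- matrix(centers, ncol = 3L)
  n <- nrow(centers)
  sigma <- rep_len(sigma, n)
  amplitude <- rep_len(amplitude, n)
  size <- rep_len(as.integer(size), 3L)

  lo <- sweep(centers, 1L, 3 * sigma, "-")
  hi <- sweep(centers, 1L, 3 * sigma, "+")
  if (any(lo < 1) || any(t(hi) > size))
    stop("blob centers need >= 3 sigma clearance from the volume boundary",
         call. = FALSE)
  if (n > 1L) {
    dd <- as.matrix(stats::dist(centers))
    diag(dd) <- Inf
    sep <- outer(3 * sigma, 3 * sigma, "+") / 2
    if (any(dd < sep))
      warning("some blobs are closer than 3 sigma; they may merge")
  }

  xs <- seq_len(size[1L]); ys <- seq_len(size[2L]); zs <- seq_len(size[3L])
  vol <- array(background, size)
  for (i in seq_len(n)) {
    gx <- exp(-(xs - centers[i, 1L])^2 / (2 * sigma[i]^2))
    gy <- exp(-(ys - centers[i, 2L])^2 / (2 * sigma[i]^2))
    gz <- exp(-(zs - centers[i, 3L])^2 / (2 * sigma[i]^2))
    vol <- vol + amplitude[i] * outer(outer(gx, gy), gz)
  }
  if (noise_sd > 0) {
    if (is.null(seed))
      stop("a seed is required when noise_sd > 0", call. = FALSE)
    vol <- vol + with_seed(seed, array(stats::rnorm(prod(size), sd = noise_sd),
                                       size))
  }
  structure(list(volume = vol, centers = centers, sigma = sigma,
                 amplitude = amplitude, background = background,
                 noise_sd = noise_sd, seed = seed),
            class = "blob_field")
}

# Evaluate expr with a local RNG state seeded at `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of the expanding sine-grid phantom
#'
#' The phantom is a chessboard-like sum-of-cosines tag pattern, radially
#' scaled about the voxel with 0-based coordinate `(l, l, l)` by the factor
#' `sigma(t) = (l + m t - n t^2) / l` at frame time `t = 0, 1, ...`. The
#' resulting material velocity field is
#' `V(x, t) = (m - 2 n t) / (l + (m - n t) t) * (x - l)`, so the phantom
#' expands while `t < m / (2 n)` and contracts afterwards. Defaults give a
#' 79^3 volume, 19 frames, tag period 9 voxels, `l = 40`, `m = 4`,
#' `n = 0.2`.
#'
#' @param size voxels per axis.
#' @param frames number of frames (times `t = 0 .. frames - 1`).
#' @param lambda tag period in voxels (>= 4). A pattern period equal to the
#'   printed tag width is the default interpretation; pass `2 * width` if
#'   tags are read as half-periods.
#' @param l center parameter (0-based coordinate of the fixed point).
#' @param m,n rate parameters of the scaling polynomial.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 79L, frames = 19L, lambda = 9,
                         l = 40, m = 4, n = 0.2) {
  spec <- structure(list(size = as.integer(size), frames = as.integer(frames),
                         lambda = lambda, l = l, m = m, n = n),
                    class = "phantom_spec")
  if (lambda < 4) stop("lambda must be >= 4 voxels", call. = FALSE)
  if (any(phantom_scaling(spec, 0:(frames - 1L)) <= 0))
    stop("scaling factor must stay positive over the frame range",
         call. = FALSE)
  spec
}

#' @rdname phantom_spec
#' @param spec a `phantom_spec`.
#' @param t frame time(s), 0-based.
#' @return `phantom_scaling`: the scaling factor `sigma(t)`.
#' @export
phantom_scaling <- function(spec, t) {
  (spec$l + spec$m * t - spec$n * t^2) / spec$l
}

#' Ground-truth phantom velocity
#'
#' Closed-form material velocity of the sine-grid phantom:
#' `V = (m - 2 n t) / (l + (m - n t) t) * (x - c)` with `c` the fixed
#' center. Positions are 1-based voxel coordinates (the package's in-memory
#' convention), so the center is at `(l + 1, l + 1, l + 1)`.
#'
#' @param x position, numeric length 3 or an n x 3 matrix (1-based).
#' @param t frame time, 0-based.
#' @param spec a [phantom_spec()].
#' @return velocity in voxels/frame, same shape as `x`.
#' @export
ground_truth_velocity <- function(x, t, spec = phantom_spec()) {
  denom <- spec$l + (spec$m - spec$n * t) * t
  if (denom <= 0) stop("scaling denominator is non-positive at t = ", t,
                       call. = FALSE)
  fac <- (spec$m - 2 * spec$n * t) / denom
  if (is.matrix(x)) fac * sweep(x, 2L, spec$l + 1, "-")
  else fac * (as.numeric(x) - (spec$l + 1))
}

#' Generate the expanding sine-grid phantom sequence
#'
#' Frame `t` samples
#' `P((x - c) / sigma(t))` with base pattern
#' `P(u) = cos(2 pi u1 / lambda) + cos(2 pi u2 / lambda) + cos(2 pi u3 / lambda)`:
#' the tag crossings (pattern maxima) sit on the lattice `c + lambda
#' sigma(t) Z^3` and move exactly with the closed-form ground-truth
#' velocity. The scaled pattern is evaluated analytically, so no
#' interpolation error enters the generation.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `volume_sequence`: `frames` (list of 3D arrays)
#'   and `spec`. Frame `i` of the list corresponds to time `t = i - 1`.
#' @export
sine_grid_phantom <- function(spec = phantom_spec()) {
  coord <- seq_len(spec$size) - 1 - spec$l   # offsets from center, voxels
  frames <- vector("list", spec$frames)
  for (i in seq_len(spec$frames)) {
    sc <- phantom_scaling(spec, i - 1L)
    cx <- cos(2 * pi * coord / (spec$lambda * sc))
    frames[[i]] <- outer(outer(cx, cx, "+"), cx, "+")
  }
  structure(list(frames = frames, spec = spec), class = "volume_sequence")
}

#' Assemble a volume sequence from a list of arrays
#'
#' @param frames list of 3D arrays of equal dimensions (>= 3 frames for
#'   central temporal differences).
#' @param frame_interval informational frame spacing (e.g. milliseconds).
#' @return list of class `volume_sequence`.
#' @export
volume_sequence <- function(frames, frame_interval = NA_real_) {
  stopifnot(is.list(frames), length(frames) >= 3L)
  d <- dim(frames[[1L]])
  for (f in frames) {
    check_volume(f, "frame")
    if (!identical(dim(f), d)) stop("frames have unequal dimensions",
                                    call. = FALSE)
  }
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "volume_sequence")
}

#' @export
print.volume_sequence <- function(x, ...) {
  cat(sprintf("<volume_sequence> %d frame(s) of %s voxels\n",
              length(x$frames), paste(dim(x$frames[[1L]]), collapse = "x")))
  invisible(x)
}
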