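# Gaussian scale space: smoothing and derivative jets.
#
# The scale convention follows the diffusion form of the Gaussian kernel,
# phi_s(x) ~ exp(-x^2 / (4 s)), so the kernel standard deviation is
# sigma = sqrt(2 s). Every user-facing function accepts either `s` (default
# interpretation) or an explicit `sigma`; kernels are always normalized to
# unit mass so that intensity scale is preserved irrespective of the printed
# normalization constant of the continuous kernel.

#' One-dimensional Gaussian and Gaussian-derivative filter taps
#'
#' Samples a Gaussian (or its first/second derivative) at integer offsets,
#' truncated at 4 sigma, and corrects the discrete moments so that the
#' filters are exact on polynomials: the smoothing kernel has unit mass, the
#' first-derivative kernel has zero mass and unit first moment, and the
#' second-derivative kernel has zero mass, zero first moment and second
#' moment equal to 2. With these corrections a sampled quadratic yields its
#' analytic derivatives exactly in the deep interior.
#'
#' @param sigma kernel standard deviation in voxels.
#' @param order derivative order, 0, 1 or 2.
#' @return numeric vector of taps at offsets `-h:h`, `h = max(1, ceil(4 sigma))`.
#' @keywords internal
gauss_taps <- function(sigma, order = 0L) {
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- seq.int(-h, h)
  g <- exp(-x^2 / (2 * sigma^2))
  if (order == 0L) {
    g / sum(g)
  } else if (order == 1L) {
    t1 <- x * g                      # ~ -G'(-x); odd, zero-sum by symmetry
    t1 / sum(x * t1)                 # unit first moment: ramp -> slope
  } else if (order == 2L) {
    t2 <- (x^2 / sigma^2 - 1) * g    # ~ G''; even
    t2 <- t2 - sum(t2) / length(t2)  # zero mass: constants -> 0
    t2 * (2 / sum(x^2 * t2))         # x^2 -> 2
  } else stop("order must be 0, 1 or 2")
}

# Dense matrix applying a symmetric-extension (reflect, edge repeated)
# convolution along one axis of length n. n is small in practice (< 10^3)
# so a dense operator multiplied against the unfolded array uses BLAS and
# avoids interpreted loops over voxels.
conv_matrix <- function(n, taps) {
  h <- (length(taps) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (o in seq.int(-h, h)) {
    w <- taps[o + h + 1L]
    if (w == 0) next
    for (i in seq_len(n)) {
      j <- i + o
      while (j < 1L || j > n) {
        if (j < 1L) j <- 1L - j
        if (j > n) j <- 2L * n + 1L - j
      }
      M[i, j] <- M[i, j] + w
    }
  }
  M
}

# Convolve along one axis of a 3D array via the dense per-axis operator.
conv_along <- function(a, taps, axis) {
  d <- dim(a)
  M <- conv_matrix(d[axis], taps)
  if (axis == 1L) {
    out <- M %*% matrix(a, d[1L])
    dim(out) <- d
    out
  } else {
    perm <- switch(axis, NULL, c(2L, 1L, 3L), c(3L, 2L, 1L))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    out <- M %*% matrix(ap, dp[1L])
    dim(out) <- dp
    aperm(out, perm)
  }
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable convolution with a unit-mass sampled Gaussian kernel, truncated
#' at 4 sigma, with reflected (edge-repeated) boundary handling.
#'
#' @param volume 3D numeric array.
#' @param s scale parameter; the kernel variance is `2 * s` per axis
#'   (`sigma = sqrt(2 s)`).
#' @param sigma alternatively, the kernel standard deviation in voxels;
#'   overrides `s` when given.
#' @return smoothed array of the same dimensions.
#' @examples
#' v <- array(rnorm(16^3), c(16, 16, 16))
#' vs <- smooth_volume(v, s = 2)
#' @export
smooth_volume <- function(volume, s = NULL, sigma = NULL) {
  check_volume(volume)
  sigma <- resolve_sigma(s, sigma)
  t0 <- gauss_taps(sigma, 0L)
  conv_along(conv_along(conv_along(volume, t0, 1L), t0, 2L), t0, 3L)
}

new_jet3d <- function(channels, s, sigma, dims) {
  structure(c(channels, list(s = s, sigma = sigma, dim = dims)),
            class = "jet3d")
}

#' Gaussian derivative jet of a 3D volume
#'
#' Computes, at a single scale, the smoothed intensity, the three first
#' derivatives and the six independent second derivatives of the volume by
#' convolution with sampled Gaussian-derivative kernels (moment-corrected,
#' reflect boundary). The mixed partials are symmetric by construction:
#' each unordered pair is computed once.
#'
#' @inheritParams smooth_volume
#' @param what `"full"` for intensity + gradient + Hessian, `"gradient"`
#'   for intensity + gradient only (cheaper; used by the temporal
#'   differencing of the motion module).
#' @return an object of class `jet3d`: a list with smoothed intensity `l`,
#'   gradient channels `gx, gy, gz`, Hessian channels
#'   `hxx, hxy, hxz, hyy, hyz, hzz` (absent for `what = "gradient"`), and
#'   the scale (`s`, `sigma`) and grid dimensions.
#' @examples
#' v <- array(rnorm(16^3), c(16, 16, 16))
#' j <- gaussian_jet(v, s = 1.5)
#' dim(j$gx)
#' @export
gaussian_jet <- function(volume, s = NULL, sigma = NULL,
                         what = c("full", "gradient")) {
  check_volume(volume)
  what <- match.arg(what)
  sg <- resolve_sigma(s, sigma)
  if (is.null(s)) s <- sg^2 / 2
  t0 <- gauss_taps(sg, 0L); t1 <- gauss_taps(sg, 1L); t2 <- gauss_taps(sg, 2L)

  z0 <- conv_along(volume, t0, 3L)
  z1 <- conv_along(volume, t1, 3L)
  y0z0 <- conv_along(z0, t0, 2L)
  y1z0 <- conv_along(z0, t1, 2L)
  y0z1 <- conv_along(z1, t0, 2L)

  ch <- list(
    l  = conv_along(y0z0, t0, 1L),
    gx = conv_along(y0z0, t1, 1L),
    gy = conv_along(y1z0, t0, 1L),
    gz = conv_along(y0z1, t0, 1L)
  )
  if (what == "full") {
    z2 <- conv_along(volume, t2, 3L)
    y2z0 <- conv_along(z0, t2, 2L)
    y1z1 <- conv_along(z1, t1, 2L)
    y0z2 <- conv_along(z2, t0, 2L)
    ch <- c(ch, list(
      hxx = conv_along(y0z0, t2, 1L),
      hxy = conv_along(y1z0, t1, 1L),
      hxz = conv_along(y0z1, t1, 1L),
      hyy = conv_along(y2z0, t0, 1L),
      hyz = conv_along(y1z1, t0, 1L),
      hzz = conv_along(y0z2, t0, 1L)
    ))
  }
  new_jet3d(ch, s = s, sigma = sg, dims = dim(volume))
}

#' @export
print.jet3d <- function(x, ...) {
  cat(sprintf("<jet3d> %s grid, s = %.4g (sigma = %.4g), channels: %s\n",
              paste(x$dim, collapse = "x"), x$s, x$sigma,
              paste(setdiff(names(x), c("s", "sigma", "dim")), collapse = " ")))
  invisible(x)
}

# Construct a jet directly from precomputed channel arrays (no smoothing).
# Used for analytic fields whose derivatives are known in closed form.
#' Assemble a derivative jet from explicit channel arrays
#'
#' Builds a `jet3d` object from user-supplied derivative channels, e.g. the
#' closed-form derivatives of an analytic test field. No smoothing is
#' applied. Missing Hessian channels default to zero.
#'
#' @param gx,gy,gz gradient component arrays (equal dimensions).
#' @param hxx,hxy,hxz,hyy,hyz,hzz Hessian component arrays; default 0.
#' @param l smoothed-intensity array; defaults to zeros (only used by
#'   intensity-based classification).
#' @param s nominal scale attached to the jet.
#' @return a `jet3d` object.
#' @export
jet_from_channels <- function(gx, gy, gz,
                              hxx = 0, hxy = 0, hxz = 0,
                              hyy = 0, hyz = 0, hzz = 0,
                              l = NULL, s = NA_real_) {
  dims <- dim(gx)
  if (is.null(dims) || length(dims) != 3L)
    stop("gradient channels must be 3D arrays")
  full <- function(a) {
    if (length(a) == 1L) array(a, dims)
    else { stopifnot(identical(dim(a), dims)); a }
  }
  if (is.null(l)) l <- array(0, dims)
  new_jet3d(list(l = full(l), gx = full(gx), gy = full(gy), gz = full(gz),
                 hxx = full(hxx), hxy = full(hxy), hxz = full(hxz),
                 hyy = full(hyy), hyz = full(hyz), hzz = full(hzz)),
            s = s, sigma = if (is.na(s)) NA_real_ else sqrt(2 * s),
            dims = dims)
}

#' Scale-normalized Laplacian of a volume
#'
#' Returns `2 s * (Lxx + Lyy + Lzz)` at scale `s`, i.e. the Laplacian of the
#' smoothed volume multiplied by the kernel variance `sigma^2 = 2 s`. Bright
#' blobs of radius comparable to `sigma` give a strong negative response at
#' their centers (and dark blobs a positive one), so blob enhancement turns
#' bright blobs into minima of the response; this is the enhancement step
#' used before extremum detection in cell counting.
#'
#' @inheritParams smooth_volume
#' @return array of the same dimensions.
#' @export
scale_normalized_laplacian <- function(volume, s = NULL, sigma = NULL) {
  check_volume(volume)
  sg <- resolve_sigma(s, sigma)
  t0 <- gauss_taps(sg, 0L); t2 <- gauss_taps(sg, 2L)
  z0 <- conv_along(volume, t0, 3L)
  y0z0 <- conv_along(z0, t0, 2L)
  lap <- conv_along(y0z0, t2, 1L) +
    conv_along(conv_along(z0, t2, 2L), t0, 1L) +
    conv_along(conv_along(conv_along(volume, t2, 3L), t0, 2L), t0, 1L)
  sg^2 * lap
}
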