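# The 3D winding number.
#
# At a voxel x the winding number nu is the surface integral, over a closed
# cube surface around x, of the degree 2-form built from the image gradient:
# in coordinates, Phi = (grad L_i x grad L_j) . grad L / |grad L|^3 dx^i ^ dx^j.
# nu equals 4*pi*k with integer k: 0 at regular points, +4*pi at minima and
# 2-saddles, -4*pi at 1-saddles and maxima (equivalently nu =
# sign(det H) * 4*pi at a nondegenerate critical point).
#
# NORMALIZATION. Some derivations of the 2-form carry an overall factor 2
# (writing Phi = 2/|grad L|^3 (...)), under which a nondegenerate minimum
# integrates to 8*pi. This package fixes the constant so that the integral
# over a surface enclosing a nondegenerate minimum is exactly +4*pi -- the
# convention of the classification tables and of the divide-by-4*pi
# quantization step -- i.e. the integrand is the standard solid-angle form
# of the normalized gradient map, with no extra factor.
#
# Two integrators are provided:
#  * "degree" (default): the gradient vectors at the surface voxels are
#    normalized onto the unit sphere, the cube surface is triangulated with
#    consistent outward orientation, and nu is the sum of signed spherical
#    triangle solid angles (stable two-argument arctangent formula). The
#    result is 4*pi times an integer up to rounding, and is independent of
#    the integration surface.
#  * "riemann": the literal 9-point unit-weight face sum on the six faces
#    of the 3x3x3 cube, with the full position-dependent integrand evaluated
#    at every sample. The unit-weight samples behave as a midpoint rule on
#    faces extending half a voxel beyond the closed cube, so |nu| at an
#    isolated critical point systematically exceeds 4*pi; the sign and the
#    |nu|/(4*pi) > 1/2 quantization are still reliable.

FLAG_OK <- 0L
FLAG_FLAT <- 1L
FLAG_UNRELIABLE <- 2L

#' Flag codes used in winding fields
#'
#' @return named integer vector mapping flag names (`ok`, `flat`,
#'   `unreliable`) to the codes stored in [winding_field()] output.
#' @export
winding_flags <- function() {
  c(ok = FLAG_OK, flat = FLAG_FLAT, unreliable = FLAG_UNRELIABLE)
}

# Default regularization floor for the gradient norm: 1e-12 times the
# maximum gradient magnitude. Gradients at the level of round-off noise of
# the intensity scale (e.g. on a constant volume, where the analytic
# gradient is zero but the convolution leaves ~1e-17 residues) are treated
# as zero so the floor does not collapse with them.
gradient_floor_default <- function(gn, intensity = NULL) {
  m <- max(gn)
  noise <- 64 * .Machine$double.eps *
    max(if (is.null(intensity)) 0 else max(abs(intensity)), 1)
  1e-12 * (if (m > noise) m else 1)
}

# interior-shifted view: arr[(2+o1):(d1-1+o1), ...], an array of size dim-2.
shift_interior <- function(arr, off) {
  d <- dim(arr)
  arr[(2L + off[1L]):(d[1L] - 1L + off[1L]),
      (2L + off[2L]):(d[2L] - 1L + off[2L]),
      (3L:d[3L]) + off[3L] - 1L, drop = FALSE]
}

# All 26 surface offsets of the 3^3 cube.
surface_offsets_26 <- function() {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  g[rowSums(abs(g)) > 0L, , drop = FALSE]
}

# Outward-oriented triangulation of the surface of the (2r+1)^3 cube.
# Returns a list of 48 r^2 integer 3x3 matrices (rows = vertices, columns =
# x/y/z offsets). Face axes are paired cyclically so that vertex order
# (i,j) -> (i+1,j) -> (i+1,j+1) has outward normal on the side = +r face;
# the order is swapped on the opposite face.
surface_triangles <- function(r = 1L) {
  tris <- vector("list", 48L * r * r)
  n <- 0L
  for (a in 1:3) {
    uv <- switch(a, c(2L, 3L), c(3L, 1L), c(1L, 2L))
    for (side in c(1L, -1L)) {
      pt <- function(i, j) {
        off <- integer(3L)
        off[a] <- side * r
        off[uv[1L]] <- i
        off[uv[2L]] <- j
        off
      }
      for (i in seq.int(-r, r - 1L)) for (j in seq.int(-r, r - 1L)) {
        t1 <- rbind(pt(i, j), pt(i + 1L, j), pt(i + 1L, j + 1L))
        t2 <- rbind(pt(i, j), pt(i + 1L, j + 1L), pt(i, j + 1L))
        if (side < 0L) {
          t1 <- t1[c(1L, 3L, 2L), ]
          t2 <- t2[c(1L, 3L, 2L), ]
        }
        tris[[n + 1L]] <- t1
        tris[[n + 2L]] <- t2
        n <- n + 2L
      }
    }
  }
  tris
}

jet_requires <- function(jet, channels) {
  miss <- setdiff(channels, names(jet))
  if (length(miss))
    stop("jet lacks channels: ", paste(miss, collapse = ", "), call. = FALSE)
}

#' Face integrand of the winding 2-form
#'
#' Evaluates, at one voxel, the integrand of the winding 2-form for an
#' ordered axis pair: `(grad L_i x grad L_j) . grad L / |grad L|^3`, where
#' `grad L_i` is the gradient of the i-th derivative channel (the i-th
#' column of the Hessian). Swapping the pair flips the sign
#' (antisymmetry of the vector product). The `xy` term is the one surviving
#' on faces of constant z, `yz` on constant x, and `zx` on constant y.
#'
#' @param jet a full [gaussian_jet()].
#' @param voxel integer vector of length 3, 1-based voxel index.
#' @param axis_pair one of `"xy"`, `"yz"`, `"zx"`, `"yx"`, `"zy"`, `"xz"`.
#' @param gradient_floor regularization floor for the gradient norm;
#'   defaults to `1e-12 * max |grad L|`.
#' @return list with `value` and `reliable` (`FALSE` when the gradient norm
#'   at the voxel is below the floor, in which case the norm is clamped).
#' @export
phi_face_integrand <- function(jet, voxel, axis_pair,
                               gradient_floor = NULL) {
  jet_requires(jet, c("gx", "gy", "gz", "hxx", "hxy", "hxz",
                      "hyy", "hyz", "hzz"))
  stopifnot(length(voxel) == 3L)
  pairs <- c("xy", "yz", "zx", "yx", "zy", "xz")
  axis_pair <- match.arg(axis_pair, pairs)
  sgn <- if (axis_pair %in% c("yx", "zy", "xz")) -1 else 1
  canon <- switch(axis_pair, yx = "xy", zy = "yz", xz = "zx", axis_pair)

  i <- voxel[1L]; j <- voxel[2L]; k <- voxel[3L]
  g <- c(jet$gx[i, j, k], jet$gy[i, j, k], jet$gz[i, j, k])
  H <- matrix(c(jet$hxx[i, j, k], jet$hxy[i, j, k], jet$hxz[i, j, k],
                jet$hxy[i, j, k], jet$hyy[i, j, k], jet$hyz[i, j, k],
                jet$hxz[i, j, k], jet$hyz[i, j, k], jet$hzz[i, j, k]), 3L)
  cols <- switch(canon, xy = c(1L, 2L), yz = c(2L, 3L), zx = c(3L, 1L))
  a <- H[, cols[1L]]; b <- H[, cols[2L]]
  cr <- c(a[2L] * b[3L] - a[3L] * b[2L],
          a[3L] * b[1L] - a[1L] * b[3L],
          a[1L] * b[2L] - a[2L] * b[1L])
  gn <- sqrt(sum(g^2))
  floor_val <- if (is.null(gradient_floor)) {
    gradient_floor_default(sqrt(jet$gx^2 + jet$gy^2 + jet$gz^2), jet$l)
  } else gradient_floor
  reliable <- gn >= floor_val
  list(value = sgn * sum(cr * g) / max(gn, floor_val)^3, reliable = reliable)
}

# Signed solid angle of the spherical triangle with unit vertices v1,v2,v3
# (vectorized over rows when the inputs are matrices / arrays of x,y,z
# component arrays). Van Oosterom-Strackee two-argument arctangent form.
solid_angle <- function(v1, v2, v3) {
  num <- v1$x * (v2$y * v3$z - v2$z * v3$y) +
         v1$y * (v2$z * v3$x - v2$x * v3$z) +
         v1$z * (v2$x * v3$y - v2$y * v3$x)
  den <- 1 + (v1$x * v2$x + v1$y * v2$y + v1$z * v2$z) +
             (v2$x * v3$x + v2$y * v3$y + v2$z * v3$z) +
             (v3$x * v1$x + v3$y * v1$y + v3$z * v1$z)
  2 * atan2(num, den)
}

#' Exactly quantized winding number on a cube surface (degree mode)
#'
#' Normalizes the gradient vectors on the surface voxels of the
#' `(2 radius + 1)^3` cube centered at `center` onto the unit sphere,
#' triangulates the cube surface with consistent outward orientation, and
#' sums the signed spherical-triangle solid angles of the mapped vertices.
#' For a surface enclosing only nondegenerate critical points the result is
#' `4 pi k` with integer `k`, independent of `radius`.
#'
#' @inheritParams phi_face_integrand
#' @param center 1-based voxel index (length-3 integer vector).
#' @param radius half-width of the integration cube, `>= 1`.
#' @return list with `nu` (radians), `k = round(nu / 4 pi)`, and `reliable`
#'   (`FALSE` if any surface gradient is below the floor or a mapped
#'   triangle is degenerate).
#' @export
winding_degree <- function(jet, center, radius = 1L, gradient_floor = NULL) {
  jet_requires(jet, c("gx", "gy", "gz"))
  stopifnot(length(center) == 3L, radius >= 1L)
  d <- jet$dim
  if (any(center - radius < 1L) || any(center + radius > d))
    stop("integration cube exceeds the volume", call. = FALSE)
  if (is.null(gradient_floor))
    gradient_floor <- gradient_floor_default(
      sqrt(jet$gx^2 + jet$gy^2 + jet$gz^2), jet$l)

  # unit gradient at a surface offset, memoized
  cache <- new.env(parent = emptyenv())
  reliable <- TRUE
  unit_at <- function(off) {
    key <- paste(off, collapse = ",")
    if (!is.null(v <- cache[[key]])) return(v)
    i <- center[1L] + off[1L]; j <- center[2L] + off[2L]
    k <- center[3L] + off[3L]
    g <- c(jet$gx[i, j, k], jet$gy[i, j, k], jet$gz[i, j, k])
    gn <- sqrt(sum(g^2))
    if (gn < gradient_floor) reliable <<- FALSE
    g <- g / max(gn, gradient_floor)
    v <- list(x = g[1L], y = g[2L], z = g[3L])
    cache[[key]] <- v
    v
  }

  nu <- 0
  for (tri in surface_triangles(radius)) {
    v1 <- unit_at(tri[1L, ]); v2 <- unit_at(tri[2L, ]); v3 <- unit_at(tri[3L, ])
    om <- solid_angle(v1, v2, v3)
    num <- v1$x * (v2$y * v3$z - v2$z * v3$y) +
           v1$y * (v2$z * v3$x - v2$x * v3$z) +
           v1$z * (v2$x * v3$y - v2$y * v3$x)
    den <- 1 + (v1$x * v2$x + v1$y * v2$y + v1$z * v2$z) +
               (v2$x * v3$x + v2$y * v3$y + v2$z * v3$z) +
               (v3$x * v1$x + v3$y * v1$y + v3$z * v1$z)
    if (abs(num) < 1e-14 && den < 1e-9) reliable <- FALSE  # antipodal pair
    nu <- nu + om
  }
  list(nu = nu, k = round(nu / (4 * pi)), reliable = reliable)
}

#' Literal face-sum winding number (Riemann mode)
#'
#' The unit-weight 3x3 sample sum of the full winding integrand on the six
#' faces of the 3x3x3 cube around `center`: for each axis pair the sum on
#' the upper face (offset +1) minus the sum on the lower face (offset -1),
#' with the position-dependent `1/|grad L|^3` normalization evaluated
#' pointwise at every sample. Not exactly quantized (see the module notes on
#' the midpoint-rule over-count); the sign is reliable for isolated
#' critical points.
#'
#' @inheritParams winding_degree
#' @return list with `nu` (radians), `k = nu / (4 pi)` (real), `reliable`.
#' @export
winding_riemann <- function(jet, center, gradient_floor = NULL) {
  jet_requires(jet, c("gx", "gy", "gz", "hxx", "hxy", "hxz",
                      "hyy", "hyz", "hzz"))
  stopifnot(length(center) == 3L)
  d <- jet$dim
  if (any(center < 2L) || any(center > d - 1L))
    stop("center must be at least one voxel from every boundary",
         call. = FALSE)
  if (is.null(gradient_floor))
    gradient_floor <- gradient_floor_default(
      sqrt(jet$gx^2 + jet$gy^2 + jet$gz^2), jet$l)
  reliable <- TRUE
  term <- function(pair, face_axis) {
    s <- 0
    for (a in -1:1) for (b in -1:1) for (side in c(1L, -1L)) {
      off <- integer(3L)
      off[face_axis] <- side
      other <- setdiff(1:3, face_axis)
      off[other[1L]] <- a; off[other[2L]] <- b
      ph <- phi_face_integrand(jet, center + off, pair,
                               gradient_floor = gradient_floor)
      if (!ph$reliable) reliable <<- FALSE
      s <- s + side * ph$value
    }
    s
  }
  nu <- term("xy", 3L) + term("yz", 1L) + term("zx", 2L)
  list(nu = nu, k = nu / (4 * pi), reliable = reliable)
}

#' Winding number at every interior voxel
#'
#' Evaluates the winding number on the 3x3x3 cube around every interior
#' voxel (one-voxel margin excluded) and quantizes it to
#' `k = nu / (4 pi)`. In `"degree"` mode (default) the exactly quantized
#' spherical-triangle integrator is used and `k` is rounded to an integer;
#' in `"riemann"` mode the literal face-sum quadrature is used and `k` is
#' real-valued.
#'
#' @inheritParams phi_face_integrand
#' @param mode `"degree"` or `"riemann"`.
#' @return an object of class `winding_field`: arrays `nu`, `k` and integer
#'   `flags` of the input dimensions (`NA` on the one-voxel margin), plus
#'   the mode and the gradient floor used. Flag codes are given by
#'   [winding_flags()]: voxels whose whole 26-voxel cube surface falls below
#'   the gradient floor are `flat` (nu forced to 0); voxels with some
#'   sub-floor surface samples or degenerate mapped triangles are
#'   `unreliable`.
#' @examples
#' v <- quadratic_volume(c(1, 1, 1), size = 9)
#' wf <- winding_field(gaussian_jet(v, s = 0.5))
#' wf$k[5, 5, 5]   # +1: a minimum
#' @export
winding_field <- function(jet, mode = c("degree", "riemann"),
                          gradient_floor = NULL) {
  mode <- match.arg(mode)
  jet_requires(jet, c("gx", "gy", "gz"))
  if (mode == "riemann")
    jet_requires(jet, c("hxx", "hxy", "hxz", "hyy", "hyz", "hzz"))
  d <- jet$dim
  if (any(d < 3L)) stop("volume must be at least 3 voxels per axis")
  ni <- d - 2L

  gn <- sqrt(jet$gx^2 + jet$gy^2 + jet$gz^2)
  floor_val <- if (is.null(gradient_floor)) gradient_floor_default(gn, jet$l) else
    gradient_floor
  gnc <- pmax(gn, floor_val)

  # surface-sample flags
  offs26 <- surface_offsets_26()
  nbelow <- array(0L, ni)
  for (r in seq_len(nrow(offs26)))
    nbelow <- nbelow + (shift_interior(gn, offs26[r, ]) < floor_val)
  flags <- array(FLAG_OK, ni)
  flags[nbelow > 0L] <- FLAG_UNRELIABLE
  flags[nbelow == 26L] <- FLAG_FLAT

  if (mode == "degree") {
    ux <- jet$gx / gnc; uy <- jet$gy / gnc; uz <- jet$gz / gnc
    cache <- new.env(parent = emptyenv())
    unit_at <- function(off) {
      key <- paste(off, collapse = ",")
      v <- cache[[key]]
      if (is.null(v)) {
        v <- list(x = shift_interior(ux, off),
                  y = shift_interior(uy, off),
                  z = shift_interior(uz, off))
        cache[[key]] <- v
      }
      v
    }
    nu <- array(0, ni)
    for (tri in surface_triangles(1L)) {
      nu <- nu + solid_angle(unit_at(tri[1L, ]), unit_at(tri[2L, ]),
                             unit_at(tri[3L, ]))
    }
    k <- round(nu / (4 * pi))
  } else {
    cross_dot <- function(a1, a2, a3, b1, b2, b3) {
      # (a x b) . grad L, all full arrays
      (a2 * b3 - a3 * b2) * jet$gx +
      (a3 * b1 - a1 * b3) * jet$gy +
      (a1 * b2 - a2 * b1) * jet$gz
    }
    ig3 <- gnc^-3
    i_xy <- cross_dot(jet$hxx, jet$hxy, jet$hxz,
                      jet$hxy, jet$hyy, jet$hyz) * ig3
    i_yz <- cross_dot(jet$hxy, jet$hyy, jet$hyz,
                      jet$hxz, jet$hyz, jet$hzz) * ig3
    i_zx <- cross_dot(jet$hxz, jet$hyz, jet$hzz,
                      jet$hxx, jet$hxy, jet$hxz) * ig3
    nu <- array(0, ni)
    for (a in -1:1) for (b in -1:1) {
      nu <- nu + shift_interior(i_xy, c(a, b, 1L)) -
                 shift_interior(i_xy, c(a, b, -1L)) +
                 shift_interior(i_yz, c(1L, a, b)) -
                 shift_interior(i_yz, c(-1L, a, b)) +
                 shift_interior(i_zx, c(a, 1L, b)) -
                 shift_interior(i_zx, c(a, -1L, b))
    }
    k <- nu / (4 * pi)
  }

  nu[flags == FLAG_FLAT] <- 0
  k[flags == FLAG_FLAT] <- 0

  embed <- function(a, fill = NA_real_) {
    full <- array(fill, d)
    full[2:(d[1L] - 1L), 2:(d[2L] - 1L), 2:(d[3L] - 1L)] <- a
    full
  }
  structure(list(nu = embed(nu), k = embed(k),
                 flags = embed(flags, NA_integer_),
                 mode = mode, gradient_floor = floor_val, dim = d,
                 scale = jet$s),
            class = "winding_field")
}

#' @export
print.winding_field <- function(x, ...) {
  fl <- x$flags[!is.na(x$flags)]
  cat(sprintf(
    "<winding_field> %s grid, mode = %s\n  interior voxels: %d (ok %d, flat %d, unreliable %d)\n  candidate voxels (|k| >= threshold): %d\n",
    paste(x$dim, collapse = "x"), x$mode, length(fl),
    sum(fl == FLAG_OK), sum(fl == FLAG_FLAT), sum(fl == FLAG_UNRELIABLE),
    sum(candidate_mask(x), na.rm = TRUE)))
  invisible(x)
}

# Candidate rule: |k| >= 1 in degree mode, |k| > 1/2 in riemann mode,
# restricted to ok-flagged voxels.
candidate_mask <- function(field) {
  ok <- !is.na(field$flags) & field$flags == FLAG_OK
  if (field$mode == "degree") ok & abs(field$k) >= 1
  else ok & abs(field$k) > 0.5
}
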