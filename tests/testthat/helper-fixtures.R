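# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures.

# Analytic derivative jet of the quadratic form 0.5 * x' A x on a cubic grid
# (coordinates centered on the middle voxel): gradient A x, Hessian A,
# exactly, with no smoothing.
analytic_quadratic_jet <- function(A, size = 9L) {
  h <- (size - 1L) / 2L
  cc <- seq.int(-h, h)
  X <- array(rep(cc, times = size^2), rep(size, 3L))
  Y <- array(rep(rep(cc, each = size), times = size), rep(size, 3L))
  Z <- array(rep(cc, each = size^2), rep(size, 3L))
  lvl <- 0.5 * (A[1, 1] * X^2 + A[2, 2] * Y^2 + A[3, 3] * Z^2) +
    A[1, 2] * X * Y + A[1, 3] * X * Z + A[2, 3] * Y * Z
  jet_from_channels(
    gx = A[1, 1] * X + A[1, 2] * Y + A[1, 3] * Z,
    gy = A[1, 2] * X + A[2, 2] * Y + A[2, 3] * Z,
    gz = A[1, 3] * X + A[2, 3] * Y + A[3, 3] * Z,
    hxx = array(A[1, 1], rep(size, 3L)), hxy = array(A[1, 2], rep(size, 3L)),
    hxz = array(A[1, 3], rep(size, 3L)), hyy = array(A[2, 2], rep(size, 3L)),
    hyz = array(A[2, 3], rep(size, 3L)), hzz = array(A[3, 3], rep(size, 3L)),
    l = lvl)
}

# Random symmetric invertible 3x3 matrix with eigenvalues in
# +-[0.5, 2] (random signs): nondegenerate by construction.
random_symmetric_matrix <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
  lam <- stats::runif(3L, 0.5, 2) * sample(c(-1, 1), 3L, replace = TRUE)
  Q %*% diag(lam) %*% t(Q)
}

# Linear ramp volume a*x + b*y + c*z.
ramp_volume <- function(coef = c(3, 2, 1), size = 15L) {
  idx <- seq_len(size)
  outer(outer(coef[1L] * idx, coef[2L] * idx, "+"), coef[3L] * idx, "+")
}

# Sum-of-cosines tag pattern translating rigidly at `vel` voxels/frame,
# evaluated analytically per frame. Maxima (tag crossings) start on the
# lattice c0 + lam * Z^3 (1-based).
translating_tag_sequence <- function(vel, frames = 5L, size = 40L,
                                     lam = 8, c0 = 21) {
  lapply(0:(frames - 1L), function(t) {
    cx <- cos(2 * pi * ((seq_len(size)) - c0 - vel[1L] * t) / lam)
    cy <- cos(2 * pi * ((seq_len(size)) - c0 - vel[2L] * t) / lam)
    cz <- cos(2 * pi * ((seq_len(size)) - c0 - vel[3L] * t) / lam)
    outer(outer(cx, cy, "+"), cz, "+")
  })
}

# The 15-dark-blob recovery fixture: blobs of sigma 3 on a 20-voxel lattice
# inside a 64^3 volume, amplitude -1 on background 0, Gaussian noise
# sd 0.02. Centers are >= 20 voxels apart and >= 9 from the boundary.
dark_blob_fixture <- function(noise_sd = 0.02) {
  sites <- as.matrix(expand.grid(c(12, 32, 52), c(12, 32, 52),
                                 c(12, 32, 52)))
  pick <- with_test_seed(1, sites[sample(nrow(sites), 15L), ])
  blob_volume(pick, sigma = 3, amplitude = -1, background = 0,
              noise_sd = noise_sd, seed = 42L, size = 64L)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Distance from each true center to the nearest refined point.
recovery_distances <- function(points, centers) {
  vapply(seq_len(nrow(centers)), function(i) {
    min(sqrt((points$rx - centers[i, 1L])^2 +
             (points$ry - centers[i, 2L])^2 +
             (points$rz - centers[i, 3L])^2))
  }, numeric(1L))
}
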