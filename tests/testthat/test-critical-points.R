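# Detection, classification and Newton refinement.

test_that("detection finds isolated bumps and merges their trigger clusters", {
  bf <- blob_volume(matrix(c(11.3, 13.7, 10.5), 1), sigma = 2.5,
                    amplitude = 1, size = 32L)
  j <- gaussian_jet(bf$volume, s = 1)
  pts <- detect_critical_points(winding_field(j), j)
  mx <- pts[pts$type == "maximum", ]
  expect_identical(nrow(mx), 1L)
  expect_identical(mx$k, -1)
  expect_identical(mx$sign_det_h, -1L)
  expect_false(mx$degenerate)

  # two bumps >= 6 sigma apart -> exactly two maxima
  bf2 <- blob_volume(rbind(c(12, 12, 12), c(30, 30, 30)), sigma = 2.5,
                     amplitude = 1, size = 42L)
  j2 <- gaussian_jet(bf2$volume, s = 1)
  pts2 <- detect_critical_points(winding_field(j2), j2)
  expect_identical(sum(pts2$type == "maximum" & !pts2$degenerate), 2L)
})

test_that("negating the volume swaps the paired type labels voxelwise", {
  bf <- blob_volume(rbind(c(12, 12, 12), c(30, 30, 30)), sigma = 2.5,
                    amplitude = 1, size = 42L)
  j <- gaussian_jet(bf$volume, s = 1)
  jn <- gaussian_jet(-bf$volume, s = 1)
  pts <- detect_critical_points(winding_field(j), j)
  ptsn <- detect_critical_points(winding_field(jn), jn)
  swap <- c(minimum = "maximum", saddle1 = "saddle2",
            saddle2 = "saddle1", maximum = "minimum")
  key <- function(p) paste(p$x, p$y, p$z, p$type)
  expect_setequal(key(ptsn),
                  paste(pts$x, pts$y, pts$z, swap[pts$type]))
})

test_that("classification follows the Hessian index and the winding-sign table", {
  cases <- list(
    list(ev = c(2, 2, 2), wind = 1, index = 0L, type = "minimum"),
    list(ev = c(2, 2, -2), wind = -1, index = 1L, type = "saddle1"),
    list(ev = c(2, -2, -2), wind = 1, index = 2L, type = "saddle2"),
    list(ev = c(-2, -2, -2), wind = -1, index = 3L, type = "maximum"))
  for (cs in cases) {
    j <- analytic_quadratic_jet(diag(cs$ev), size = 7L)
    cl <- classify_critical_point(j, c(4L, 4L, 4L), winding_sign = cs$wind)
    expect_identical(cl$index, cs$index)
    expect_identical(cl$type, cs$type)
    expect_false(cl$degenerate)
    expect_identical(cl$sign_det_h, as.integer(sign(prod(cs$ev))))
    # intensity mode agrees given the winding sign alone
    cli <- classify_critical_point(j, c(4L, 4L, 4L), winding_sign = cs$wind,
                                   mode = "intensity")
    expect_identical(cli$type, cs$type)
  }
  # winding sign contradicting sign(det H) flags the point
  j <- analytic_quadratic_jet(diag(c(2, 2, 2)), size = 7L)
  expect_true(classify_critical_point(j, c(4L, 4L, 4L),
                                      winding_sign = -1)$degenerate)
})

test_that("Newton refinement is exact in one step on quadratics", {
  xs <- (1:15) - 8
  v <- 0.5 * outer(outer((xs - 0.3)^2, (xs + 0.2)^2, "+"), (xs - 0.45)^2,
                   "+")
  j <- gaussian_jet(v, s = 0.5)
  res <- refine_newton(j, c(8, 8, 8), max_iter = 1L, tol = 1e-6)
  expect_lt(max(abs(res$position - c(8.3, 7.8, 8.45))), 1e-6)
  expect_identical(res$iterations, 1L)
})

test_that("refinement recovers off-grid bump centers", {
  truth <- c(10.3, 12.7, 9.5)
  bf <- blob_volume(matrix(truth, 1), sigma = 2.5, amplitude = 1,
                    size = 32L)
  j <- gaussian_jet(bf$volume, s = 1)
  pts <- refine_critical_points(
    detect_critical_points(winding_field(j), j), j)
  mx <- pts[pts$type == "maximum", ]
  expect_true(mx$converged)
  expect_lt(sqrt(sum((c(mx$rx, mx$ry, mx$rz) - truth)^2)), 0.05)
  # raster-offset scenario: the detected voxel is not the continuum
  # optimum, the refined position is
  expect_gt(sqrt(sum((c(mx$x, mx$y, mx$z) - truth)^2)), 0.3)
})

test_that("a singular Hessian direction flags the point without moving it", {
  # L = x^4 + y^2 + z^2: Hessian diag(12 x^2, 2, 2) is singular at the
  # critical point
  size <- 9L
  cc <- seq.int(-4L, 4L)
  X <- array(rep(cc, times = size^2), rep(size, 3L))
  Y <- array(rep(rep(cc, each = size), times = size), rep(size, 3L))
  Z <- array(rep(cc, each = size^2), rep(size, 3L))
  j <- jet_from_channels(gx = 4 * X^3, gy = 2 * Y, gz = 2 * Z,
                         hxx = 12 * X^2, hyy = array(2, rep(size, 3L)),
                         hzz = array(2, rep(size, 3L)))
  res <- refine_newton(j, c(5, 5, 5))
  expect_true(res$degenerate)
  expect_identical(res$position, c(5, 5, 5))
})

test_that("every nondegenerate detection satisfies the sign correspondence", {
  for (signs in list(c(1, 1, 1), c(1, 1, -1), c(1, -1, -1), c(-1, -1, -1))) {
    v <- quadratic_volume(signs, size = 15L)
    j <- gaussian_jet(v, s = 0.5)
    pts <- detect_critical_points(winding_field(j), j)
    pts <- pts[!pts$degenerate, ]
    expect_gt(nrow(pts), 0L)
    # k = +1 <-> index in {0, 2}; k = -1 <-> index in {1, 3};
    # and k agrees with sign(det H)
    expect_true(all(ifelse(pts$k > 0, pts$index %in% c(0L, 2L),
                           pts$index %in% c(1L, 3L))))
    expect_identical(as.integer(sign(pts$k)), pts$sign_det_h)
  }
})
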