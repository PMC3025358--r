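# The winding 2-form and the two surface integrators.

test_that("face integrand matches the hand-evaluated cross products", {
  # L = 0.5 (x^2 + y^2 + z^2): at offset (0,0,1) from the critical point the
  # xy-term is [(1,0,0) x (0,1,0)] . (0,0,1) / 1 = 1
  j <- analytic_quadratic_jet(diag(c(1, 1, 1)), size = 9L)
  ctr <- c(5L, 5L, 5L)
  expect_equal(phi_face_integrand(j, ctr + c(0L, 0L, 1L), "xy")$value, 1,
               tolerance = 1e-12)
  # the same point seen by the other pairs: (grad Ly x grad Lz) . (0,0,1) = 0
  expect_equal(phi_face_integrand(j, ctr + c(0L, 0L, 1L), "yz")$value, 0,
               tolerance = 1e-12)

  # antisymmetry under pair swap
  v <- with_test_seed(3, smooth_volume(array(rnorm(13^3), c(13, 13, 13)),
                                       s = 1.5))
  jr <- gaussian_jet(v, s = 1)
  for (p in list(c("xy", "yx"), c("yz", "zy"), c("zx", "xz"))) {
    expect_equal(phi_face_integrand(jr, c(7L, 7L, 7L), p[1L])$value,
                 -phi_face_integrand(jr, c(7L, 7L, 7L), p[2L])$value)
  }

  # constant gradient (ramp): all second derivatives zero -> integrand zero
  jramp <- gaussian_jet(ramp_volume(), s = 1)
  for (p in c("xy", "yz", "zx"))
    expect_equal(phi_face_integrand(jramp, c(8L, 8L, 8L), p)$value, 0,
                 tolerance = 1e-10)
})

test_that("degree mode reproduces the critical-point winding table", {
  cases <- list(list(signs = c(1, 1, 1), k = 1),    # minimum
                list(signs = c(1, 1, -1), k = -1),  # 1-saddle
                list(signs = c(1, -1, -1), k = 1),  # 2-saddle
                list(signs = c(-1, -1, -1), k = -1)) # maximum
  for (cs in cases) {
    v <- quadratic_volume(cs$signs, size = 15L)
    j <- gaussian_jet(v, s = 0.5)
    wd <- winding_degree(j, attr(v, "center"), radius = 1L)
    expect_true(wd$reliable)
    expect_equal(wd$nu, cs$k * 4 * pi, tolerance = 1e-9)
    expect_identical(wd$k, as.numeric(cs$k))
  }
  # regular point: ramp
  jr <- gaussian_jet(ramp_volume(), s = 0.5)
  expect_lt(abs(winding_degree(jr, c(8L, 8L, 8L))$nu), 4 * pi * 1e-9)
})

test_that("winding equals sign(det H) * 4 pi for random quadratic forms", {
  with_test_seed(181, {
    for (rep in 1:100) {
      A <- random_symmetric_matrix()
      j <- analytic_quadratic_jet(A, size = 7L)
      wd <- winding_degree(j, c(4L, 4L, 4L), radius = 1L)
      expect_identical(wd$k, sign(det(A)))
      expect_equal(wd$nu, sign(det(A)) * 4 * pi, tolerance = 1e-9)
    }
  })
})

test_that("riemann face sums match a dense quadrature of the same faces", {
  # The 9 unit-weight samples act as a midpoint rule on faces extending to
  # +-1.5 voxels at distance 1; the dense oracle integrates the analytic
  # integrand of L = 0.5 |x|^2 over those same over-extended faces. The
  # residual difference is the midpoint-rule error at the central peak
  # (~4% here).
  n <- 600L
  u <- (seq_len(n) - 0.5) / n * 3 - 1.5
  face <- sum(1 / (outer(u^2, u^2, "+") + 1)^1.5) * (3 / n)^2
  oracle <- 6 * face   # 3 axis pairs x (upper - lower), lower is negative

  v <- quadratic_volume(c(1, 1, 1), size = 15L)
  j <- gaussian_jet(v, s = 0.5)
  wr <- winding_riemann(j, attr(v, "center"))
  expect_true(wr$reliable)
  expect_gt(wr$nu, 4 * pi)          # over-counts the closed-cube solid angle
  expect_lt(abs(wr$nu - oracle) / oracle, 0.06)

  # parity: integrand is odd in L
  jneg <- gaussian_jet(-v, s = 0.5)
  expect_equal(winding_riemann(jneg, attr(v, "center"))$nu, -wr$nu,
               tolerance = 1e-12)
  # quantization rule still fires
  expect_gt(abs(wr$k), 0.5)
})

test_that("the winding number is surface-independent and additive", {
  # surface independence on an anisotropic 1-saddle (det H = -1 -> k = -1)
  v <- quadratic_volume(c(1, -1, 1), size = 21L)
  j <- gaussian_jet(v, s = 0.5)
  ks <- vapply(1:3, function(r)
    winding_degree(j, attr(v, "center"), radius = r)$k, numeric(1L))
  expect_identical(ks, rep(-1, 3L))

  # additivity: two bright bumps with the 2-saddle between them.
  # A box around one bump plus the saddle: k = -1 + 1 = 0.
  # A box around bump + saddle + bump: k = -1 + 1 - 1 = -1.
  bf <- blob_volume(rbind(c(10, 12, 12), c(18, 12, 12)), sigma = 2,
                    amplitude = 1, size = 25L)
  jb <- gaussian_jet(bf$volume, s = 0.5)
  one_max <- winding_degree(jb, c(10L, 12L, 12L), radius = 2L)
  pair <- winding_degree(jb, c(12L, 12L, 12L), radius = 3L)
  all3 <- winding_degree(jb, c(14L, 12L, 12L), radius = 6L)
  expect_identical(one_max$k, -1)
  expect_identical(pair$k, 0)
  expect_identical(all3$k, -1)
  expect_true(all(one_max$reliable, pair$reliable, all3$reliable))
})

test_that("winding fields flag flat surfaces and respect parity", {
  # constant volume: every interior voxel flat, nu reported 0
  wfc <- winding_field(gaussian_jet(array(1, c(9, 9, 9)), s = 1))
  fl <- wfc$flags[!is.na(wfc$flags)]
  expect_true(all(fl == winding_flags()["flat"]))
  expect_true(all(wfc$nu[!is.na(wfc$nu)] == 0))

  # single off-grid-center bump: exactly one k = -1 cluster among ok voxels
  bf <- blob_volume(matrix(c(11.4, 12.6, 13.5), 1), sigma = 2.5,
                    amplitude = 1, size = 24L)
  j <- gaussian_jet(bf$volume, s = 1)
  wf <- winding_field(j)
  ok <- !is.na(wf$flags) & wf$flags == winding_flags()["ok"]
  neg <- which(ok & wf$k == -1, arr.ind = TRUE)
  expect_gt(nrow(neg), 0L)
  # all triggering voxels within one voxel of each other (one cluster) and
  # adjacent to the raster maximum of the smoothed bump
  expect_lt(max(dist(neg)), sqrt(3) * 2 + 1e-9)
  mx <- local_extrema_26(smooth_volume(bf$volume, s = 1), "maxima")
  expect_lt(sqrt(min(colSums((t(neg) - as.integer(mx[1, ]))^2))), 2)

  # parity: negating the volume negates nu and k voxelwise
  wfn <- winding_field(gaussian_jet(-bf$volume, s = 1))
  expect_equal(wfn$nu, -wf$nu, tolerance = 1e-9)
  expect_equal(wfn$k, -wf$k)
  expect_identical(wfn$flags, wf$flags)
})

test_that("riemann-mode fields agree with the per-voxel face sum", {
  v <- with_test_seed(21, smooth_volume(array(rnorm(11^3), c(11, 11, 11)),
                                        s = 1))
  j <- gaussian_jet(v, s = 1)
  wf <- winding_field(j, mode = "riemann")
  for (ctr in list(c(4L, 5L, 6L), c(6L, 6L, 6L), c(2L, 9L, 3L))) {
    expect_equal(wf$nu[ctr[1L], ctr[2L], ctr[3L]],
                 winding_riemann(j, ctr)$nu, tolerance = 1e-10)
  }
})
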