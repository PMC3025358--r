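# Critical-point optic flow.

test_that("temporal gradient differencing is exact on fields linear in time", {
  base <- with_test_seed(2, smooth_volume(array(rnorm(15^3), c(15, 15, 15)),
                                          s = 1))
  g <- with_test_seed(3, smooth_volume(array(rnorm(15^3), c(15, 15, 15)),
                                       s = 1))
  frames <- lapply(0:3, function(t) base + t * g)
  jets <- lapply(frames, gaussian_jet, s = 1, what = "gradient")
  jg <- gaussian_jet(g, s = 1, what = "gradient")
  for (t in 2:3) {
    dg <- temporal_gradient_derivative(jets, t)
    expect_equal(dg$x, jg$gx, tolerance = 1e-10)
    expect_equal(dg$z, jg$gz, tolerance = 1e-10)
  }
  # static sequence -> zero field
  dg0 <- temporal_gradient_derivative(lapply(1:3, function(i) jets[[1L]]),
                                      2L)
  expect_equal(max(abs(dg0$x), abs(dg0$y), abs(dg0$z)), 0)
  expect_error(temporal_gradient_derivative(jets, 1L), "central")
})

test_that("static sequences give zero velocity at every maximum", {
  fr <- translating_tag_sequence(c(0, 0, 0), frames = 3L, size = 32L,
                                 c0 = 17)
  fl <- track_and_flow(fr, s = 3.5, frame_range = 2L, boundary_margin = 6)
  expect_gt(nrow(fl), 0L)
  expect_true(all(fl$valid))
  expect_lt(max(abs(c(fl$u, fl$v, fl$w))), 1e-9)
})

test_that("translation velocity is recovered at tag crossings", {
  for (sp in c(0.2, 0.5)) {
    fr <- translating_tag_sequence(c(sp, 0, 0))
    fl <- track_and_flow(fr, s = 3.5, frame_range = 3L,
                         boundary_margin = 8)
    expect_gt(nrow(fl), 8L)
    err <- sqrt((fl$u - sp)^2 + fl$v^2 + fl$w^2)
    expect_lt(stats::median(err), 0.05)
  }
  # At 1.0 voxel/frame the central temporal difference of a period-8
  # sinusoid attenuates the estimate by exactly sinc(2 pi v / lambda);
  # after removing that known factor the speed is recovered to < 0.01.
  fr <- translating_tag_sequence(c(1, 0, 0))
  fl <- track_and_flow(fr, s = 3.5, frame_range = 3L, boundary_margin = 8)
  om <- 2 * pi * 1 / 8
  corrected <- stats::median(fl$u) * om / sin(om)
  expect_lt(abs(corrected - 1), 0.01)
  expect_lt(stats::median(abs(fl$u - 1)), 0.12)
})

test_that("velocities are invariant under tag fading and intensity scaling", {
  fr <- translating_tag_sequence(c(0.5, 0, 0))
  fl0 <- track_and_flow(fr, s = 3.5, frame_range = 3L, boundary_margin = 8)
  # exponential fading, T1 = 25 frame intervals: the fading term is
  # annihilated at critical points; central differencing leaves only a
  # cosh(1/T1) - 1 ~ 8e-4 relative residual
  faded <- lapply(seq_along(fr), function(i) fr[[i]] * exp(-(i - 1) / 25))
  flf <- track_and_flow(faded, s = 3.5, frame_range = 3L,
                        boundary_margin = 8)
  expect_identical(nrow(flf), nrow(fl0))
  expect_lt(max(abs(flf$u - fl0$u), abs(flf$v - fl0$v),
                abs(flf$w - fl0$w)), 5e-3)

  # global intensity scaling: H and the temporal term scale together
  fls <- track_and_flow(lapply(fr, function(a) 7.3 * a), s = 3.5,
                        frame_range = 3L, boundary_margin = 8)
  expect_lt(max(abs(fls$u - fl0$u)), 1e-3)
})

test_that("the expanding phantom yields outward flow matching ground truth", {
  spec <- phantom_spec(size = 41L, frames = 9L, lambda = 9, l = 20, m = 2,
                       n = 0.1)
  fl <- track_and_flow(sine_grid_phantom(spec), s = 3.5, frame_range = 5L,
                       boundary_margin = 6)
  ctr <- spec$l + 1
  offc <- sqrt((fl$x - ctr)^2 + (fl$y - ctr)^2 + (fl$z - ctr)^2)
  radial <- (fl$x - ctr) * fl$u + (fl$y - ctr) * fl$v + (fl$z - ctr) * fl$w
  expect_true(all(radial[fl$valid & offc > 1] > 0))
  res <- average_angular_error(
    fl, function(x, f) ground_truth_velocity(x, f - 1, spec))
  expect_lt(res$aae, 0.5)
})

test_that("angular error statistics behave as expected on known flows", {
  flow <- data.frame(frame = c(2L, 2L, 2L), x = c(5, 6, 7), y = 5, z = 5,
                     u = c(1, 0, 1), v = c(0, 1, 0), w = 0,
                     cond_h = 1, valid = TRUE, reason = "")
  truth_u <- function(x, f) c(1, 0, 0)
  same <- average_angular_error(flow[1L, ], truth_u)
  expect_identical(same$aae, 0)
  expect_identical(same$std, 0)
  orth <- average_angular_error(flow[2L, ], truth_u)
  expect_equal(orth$aae, 90)
  diag45 <- average_angular_error(flow[3L, ],
                                  function(x, f) c(1, 1, 0) / sqrt(2))
  expect_equal(diag45$aae, 45)
  # against truth (1,0,0) the three samples score 0, 90 and 0 degrees
  all3 <- average_angular_error(flow, truth_u)
  expect_equal(all3$aae, 30)
  expect_identical(all3$n, 3L)
  expect_true(all3$aae >= 0 && all3$aae <= 180)
  # near-zero vectors are excluded and counted; none left is an error
  z <- flow[1L, ]; z$u <- 0
  expect_error(average_angular_error(z, truth_u), "valid")
  mix <- rbind(flow[1L, ], z)
  res <- average_angular_error(mix, truth_u)
  expect_identical(res$n_excluded, 1L)
  expect_identical(res$n, 1L)
})

test_that("ill-conditioned Hessians produce flagged invalid samples", {
  j <- analytic_quadratic_jet(diag(c(1, 1, 1e-12)), size = 9L)
  dg <- list(x = array(0.1, c(9, 9, 9)), y = array(0, c(9, 9, 9)),
             z = array(0, c(9, 9, 9)))
  vs <- velocity_at(c(5, 5, 5), j, dg)
  expect_false(vs$valid)
  expect_match(vs$reason, "conditioned")
  # well-conditioned case solves the linear system
  j2 <- analytic_quadratic_jet(diag(c(2, 1, 1)), size = 9L)
  vs2 <- velocity_at(c(5, 5, 5), j2, dg)
  expect_true(vs2$valid)
  expect_equal(vs2$velocity, c(-0.05, 0, 0), tolerance = 1e-12)
})
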