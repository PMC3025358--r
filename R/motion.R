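# Critical-point optic flow for 3D volume sequences.
#
# At a tracked intensity maximum the spatial gradient vanishes for all t,
# so differentiating grad L(x(t), t) = 0 in time gives
# H V + d(grad L)/dt = 0, i.e. V = -H^{-1} d(grad L)/dt. Velocities are
# therefore extracted only at detected critical points, where the relation
# holds without any brightness-constancy assumption: a global intensity
# modulation A(t) (e.g. tag fading) rescales H and contributes
# A'(t) grad L to the temporal term, which vanishes at the critical point,
# leaving the velocity unchanged to first order.

#' Temporal derivative of the gradient channels
#'
#' Central difference `(grad L(t+1) - grad L(t-1)) / 2` of per-frame
#' gradient jets.
#'
#' @param jets list of per-frame jets (at least `gx, gy, gz` channels),
#'   indexed by frame.
#' @param t frame index with both neighbors available (`2 .. length - 1`).
#' @return list with arrays `x`, `y`, `z`.
#' @export
temporal_gradient_derivative <- function(jets, t) {
  if (t < 2L || t > length(jets) - 1L)
    stop("central temporal difference needs frames t - 1 and t + 1",
         call. = FALSE)
  jm <- jets[[t - 1L]]; jp <- jets[[t + 1L]]
  list(x = (jp$gx - jm$gx) / 2,
       y = (jp$gy - jm$gy) / 2,
       z = (jp$gz - jm$gz) / 2)
}

#' Velocity of a critical point from the Hessian relation
#'
#' Solves `H V = -d(grad L)/dt` at a continuous position, with the Hessian
#' and the temporal gradient derivative interpolated trilinearly. The
#' linear system is solved directly (no explicit inverse); a Hessian with
#' condition number above `cond_max` yields an invalid sample.
#'
#' @param position 1-based continuous position (length 3).
#' @param jet_t full jet of the current frame.
#' @param dgrad_dt output of [temporal_gradient_derivative()] for the same
#'   frame.
#' @param cond_max condition-number cap.
#' @return list with `velocity` (u, v, w in voxels/frame), `cond_h`,
#'   `valid`, `reason`.
#' @export
velocity_at <- function(position, jet_t, dgrad_dt, cond_max = 1e8) {
  sm <- jet_sample(jet_t, position)
  st <- trilinear_stencil(position, jet_t$dim)
  dg <- c(sum(dgrad_dt$x[st$idx] * st$w),
          sum(dgrad_dt$y[st$idx] * st$w),
          sum(dgrad_dt$z[st$idx] * st$w))
  ev <- eigen(sm$H, symmetric = TRUE, only.values = TRUE)$values
  if (min(abs(ev)) == 0 || max(abs(ev)) / min(abs(ev)) > cond_max) {
    return(list(velocity = rep(NA_real_, 3L),
                cond_h = if (min(abs(ev)) == 0) Inf else
                  max(abs(ev)) / min(abs(ev)),
                valid = FALSE, reason = "ill-conditioned Hessian"))
  }
  v <- -solve(sm$H, dg)
  list(velocity = v, cond_h = max(abs(ev)) / min(abs(ev)),
       valid = TRUE, reason = "")
}

#' Sparse optic flow at tracked maxima of a volume sequence
#'
#' For each frame in `frame_range`: compute the jet at scale `s`, the
#' winding field (degree mode), detect and refine the maxima, discard
#' points within `boundary_margin` voxels of any volume face, and extract
#' the velocity of each remaining point via the Hessian relation with
#' central temporal differences.
#'
#' @param sequence a [volume_sequence()] (or plain list of 3D arrays).
#' @param s scale parameter (or give `sigma`).
#' @param frame_range frame indices to process; must exclude the first and
#'   last frame. Default: all interior frames.
#' @param boundary_margin minimum distance (voxels) of a refined point from
#'   every volume face.
#' @param sigma alternative bandwidth, see [smooth_volume()].
#' @param cond_max condition cap passed to [velocity_at()].
#' @return data.frame of class `flow_field` with columns `frame`, `x, y, z`
#'   (refined 1-based positions), `u, v, w` (voxels/frame), `cond_h`,
#'   `valid`, `reason`.
#' @export
track_and_flow <- function(sequence, s = NULL, frame_range = NULL,
                           boundary_margin = 10, sigma = NULL,
                           cond_max = 1e8) {
  frames <- if (inherits(sequence, "volume_sequence")) sequence$frames else
    sequence
  nt <- length(frames)
  if (nt < 3L) stop("need at least 3 frames", call. = FALSE)
  if (is.null(frame_range)) frame_range <- 2:(nt - 1L)
  if (any(frame_range < 2L) || any(frame_range > nt - 1L))
    stop("frame_range must exclude the first and last frame", call. = FALSE)
  if (boundary_margin < 1) stop("boundary_margin must be >= 1",
                                call. = FALSE)
  d <- dim(frames[[1L]])

  grad_cache <- new.env(parent = emptyenv())
  grad_jet <- function(i) {
    key <- as.character(i)
    j <- grad_cache[[key]]
    if (is.null(j)) {
      j <- gaussian_jet(frames[[i]], s = s, sigma = sigma,
                        what = "gradient")
      grad_cache[[key]] <- j
    }
    j
  }

  rows <- list()
  for (t in frame_range) {
    jet_t <- gaussian_jet(frames[[t]], s = s, sigma = sigma)
    dg <- list(x = (grad_jet(t + 1L)$gx - grad_jet(t - 1L)$gx) / 2,
               y = (grad_jet(t + 1L)$gy - grad_jet(t - 1L)$gy) / 2,
               z = (grad_jet(t + 1L)$gz - grad_jet(t - 1L)$gz) / 2)
    field <- winding_field(jet_t, mode = "degree")
    pts <- detect_critical_points(field, jet_t)
    pts <- pts[pts$type == "maximum" & !pts$degenerate, , drop = FALSE]
    pts <- refine_critical_points(pts, jet_t)
    pts <- pts[pts$converged & !pts$divergent, , drop = FALSE]
    if (nrow(pts)) {
      inside <- pts$rx >= 1 + boundary_margin &
        pts$rx <= d[1L] - boundary_margin &
        pts$ry >= 1 + boundary_margin & pts$ry <= d[2L] - boundary_margin &
        pts$rz >= 1 + boundary_margin & pts$rz <= d[3L] - boundary_margin
      pts <- pts[inside, , drop = FALSE]
    }
    if (nrow(pts) == 0L) {
      warning(sprintf("no usable maxima in frame %d", t))
      next
    }
    for (r in seq_len(nrow(pts))) {
      pos <- c(pts$rx[r], pts$ry[r], pts$rz[r])
      vs <- velocity_at(pos, jet_t, dg, cond_max = cond_max)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = t, x = pos[1L], y = pos[2L], z = pos[3L],
        u = vs$velocity[1L], v = vs$velocity[2L], w = vs$velocity[3L],
        cond_h = vs$cond_h, valid = vs$valid, reason = vs$reason)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
               z = numeric(0), u = numeric(0), v = numeric(0),
               w = numeric(0), cond_h = numeric(0), valid = logical(0),
               reason = character(0))
  rownames(out) <- NULL
  attr(out, "s") <- s
  attr(out, "boundary_margin") <- boundary_margin
  class(out) <- c("flow_field", "data.frame")
  out
}

#' Average angular error of a flow field against ground truth
#'
#' For each valid sample, the angle (degrees) between the estimated and
#' ground-truth velocity vectors: `acos` of the dot product of the
#' normalized 3D vectors. Samples where either vector norm is below `eps`
#' are excluded (and counted); having none left is an error.
#'
#' @param flow a [track_and_flow()] result (or data.frame with `frame`,
#'   `x, y, z`, `u, v, w`, `valid`).
#' @param ground_truth `function(position, frame)` returning the true
#'   velocity (length 3) at a 1-based position for the given frame index.
#' @param eps vector-norm floor below which a sample is excluded.
#' @return list with `aae` (mean, degrees), `std` (sd, degrees), `n`,
#'   `n_excluded`, and the per-sample `angles`.
#' @export
average_angular_error <- function(flow, ground_truth, eps = 1e-8) {
  f <- flow[flow$valid, , drop = FALSE]
  angles <- numeric(0)
  n_excl <- 0L
  for (r in seq_len(nrow(f))) {
    vgt <- ground_truth(c(f$x[r], f$y[r], f$z[r]), f$frame[r])
    ve <- c(f$u[r], f$v[r], f$w[r])
    ngt <- sqrt(sum(vgt^2)); ne <- sqrt(sum(ve^2))
    if (ngt < eps || ne < eps) {
      n_excl <- n_excl + 1L
      next
    }
    cosang <- sum(vgt * ve) / (ngt * ne)
    angles <- c(angles, acos(min(1, max(-1, cosang))) * 180 / pi)
  }
  if (length(angles) == 0L)
    stop("no valid samples with non-negligible velocity", call. = FALSE)
  list(aae = mean(angles),
       std = if (length(angles) > 1L) stats::sd(angles) else 0,
       n = length(angles), n_excluded = n_excl, angles = angles)
}
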