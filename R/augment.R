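# Data augmentation: affine variants, speed warps, and placement of 2D
# character strokes as 3D end-effector traces on writing planes.

#' Augmentation configuration
#'
#' Levels of variation applied to each base trajectory: scaling, rotation,
#' shearing, speed, plus the spatial start-point grid and plane
#' orientations. Defaults are the study's grid.
#'
#' @param scales scale factors.
#' @param rotations rotation angles (rad).
#' @param shears shear angles (rad).
#' @param speeds speed factors.
#' @param grid_spacing start-point/plane grid spacing (cm).
#' @param plane_orientations subset of `c("horizontal", "vertical")`.
#' @return an `augmentation_config` list.
#' @export
augmentation_config <- function(scales = c(0.7, 1, 1.3),
                                rotations = c(-pi / 6, -pi / 12, 0, pi / 12, pi / 6),
                                shears = c(-pi / 6, -pi / 12, 0, pi / 12, pi / 6),
                                speeds = c(0.8, 1, 1.2, 1.4),
                                grid_spacing = 3,
                                plane_orientations = c("horizontal", "vertical")) {
  if (!length(scales) || !length(rotations) || !length(shears) || !length(speeds))
    stop_pt("all augmentation level lists must be non-empty", "pt_config_error")
  if (grid_spacing <= 0) stop_pt("grid_spacing must be > 0", "pt_config_error")
  plane_orientations <- match.arg(plane_orientations,
                                  c("horizontal", "vertical"), several.ok = TRUE)
  structure(list(scales = scales, rotations = rotations, shears = shears,
                 speeds = speeds, grid_spacing = grid_spacing,
                 plane_orientations = plane_orientations),
            class = "augmentation_config")
}

#' Apply an affine variant to a trajectory
#'
#' Positions are transformed by the composed matrix shear o rotation o
#' scale about the trajectory centroid (composition order fixed for
#' reproducibility); timestamps are unchanged.
#'
#' @param traj a [pen_trajectory()].
#' @param scale scale factor.
#' @param rotation rotation angle (rad), counterclockwise.
#' @param shear shear angle (rad), applied along the x axis.
#' @return transformed [pen_trajectory()].
#' @export
apply_affine <- function(traj, scale = 1, rotation = 0, shear = 0) {
  stopifnot(inherits(traj, "pen_trajectory"))
  if (scale == 1 && rotation == 0 && shear == 0) return(traj)
  S <- diag(2) * scale
  R <- matrix(c(cos(rotation), sin(rotation),
                -sin(rotation), cos(rotation)), 2, 2)
  H <- matrix(c(1, 0, tan(shear), 1), 2, 2)
  M <- H %*% R %*% S
  ctr <- colMeans(traj$points)
  pts <- sweep(sweep(traj$points, 2, ctr) %*% t(M), 2, ctr, `+`)
  pen_trajectory(traj$label, pts, traj$dt, traj$velocity %*% t(M))
}

#' Warp the speed of a trajectory
#'
#' Divides the duration by `speed` (spatial path unchanged) and resamples
#' onto the original sampling grid.
#'
#' @param traj a [pen_trajectory()].
#' @param speed speed factor (> 0).
#' @return time-warped [pen_trajectory()] with the same dt.
#' @export
time_warp <- function(traj, speed = 1) {
  stopifnot(inherits(traj, "pen_trajectory"))
  if (speed <= 0) stop_pt("speed must be > 0", "pt_config_error")
  if (speed == 1) return(traj)
  dur <- (nrow(traj$points) - 1) * traj$dt / speed
  n_out <- max(round(dur / traj$dt) + 1, 2)
  .resample_n(traj, n_out, traj$dt)
}

#' Enumerate affine/speed variant tuples
#'
#' Cartesian product of the configured levels in a fixed, deterministic
#' order (scale varies fastest, then rotation, shear, speed).
#'
#' @param cfg an [augmentation_config()].
#' @return data.frame with columns scale, rotation, shear, speed.
#' @export
enumerate_variants <- function(cfg = augmentation_config()) {
  stopifnot(inherits(cfg, "augmentation_config"))
  expand.grid(scale = cfg$scales, rotation = cfg$rotations,
              shear = cfg$shears, speed = cfg$speeds,
              KEEP.OUT.ATTRS = FALSE)
}

#' Construct a writing plane
#'
#' @param orientation `"horizontal"` (fixed z) or `"vertical"` (fixed x).
#' @param start_point 3D start position (cm) in the shoulder frame; the
#'   plane passes through it.
#' @return a `writing_plane` list with the plane offset along its normal.
#' @export
writing_plane <- function(orientation = c("horizontal", "vertical"),
                          start_point) {
  orientation <- match.arg(orientation)
  stopifnot(length(start_point) == 3)
  offset <- if (orientation == "horizontal") start_point[3] else start_point[1]
  structure(list(orientation = orientation, offset = offset,
                 start_point = as.numeric(start_point)),
            class = "writing_plane")
}

#' Embed a 2D trajectory in a writing plane
#'
#' The stroke is embedded with its first point at the plane's start point.
#' Axis convention (shoulder frame, cm): x points away from the body, y to
#' the right, z up. On horizontal planes the character's first axis maps to
#' world y (rightward) and its second to world x (away), at fixed z; on
#' vertical planes to world y and z (up), at fixed x.
#'
#' @param traj a [pen_trajectory()] (cm).
#' @param plane a [writing_plane()].
#' @return n x 3 matrix of end-effector positions (cm).
#' @export
place_in_plane <- function(traj, plane) {
  stopifnot(inherits(traj, "pen_trajectory"), inherits(plane, "writing_plane"))
  rel <- sweep(traj$points, 2, traj$points[1, ])
  sp <- plane$start_point
  if (plane$orientation == "horizontal") {
    cbind(sp[1] + rel[, 2], sp[2] + rel[, 1], rep(sp[3], nrow(rel)))
  } else {
    cbind(rep(sp[1], nrow(rel)), sp[2] + rel[, 1], sp[3] + rel[, 2])
  }
}

#' In-plane coordinates of a 3D trace
#'
#' Projects a 3D end-effector trace back onto its writing plane's 2D axes
#' (first axis rightward, second axis away from the body for horizontal
#' planes / upward for vertical planes). Used by the tuning analyses.
#'
#' @param e n x 3 matrix (cm or m, units preserved).
#' @param plane a [writing_plane()] or its orientation string.
#' @return n x 2 matrix of in-plane coordinates.
#' @export
plane_coordinates <- function(e, plane) {
  orientation <- if (inherits(plane, "writing_plane")) plane$orientation else plane
  if (orientation == "horizontal") cbind(e[, 2], e[, 1]) else cbind(e[, 2], e[, 3])
}
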