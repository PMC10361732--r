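# Two-link, four degree-of-freedom arm: forward kinematics, constrained
# inverse kinematics, and workspace / start-point grid computation.
#
# Joint vector q = (theta_ef, theta_sr, theta_se, theta_sep): elbow
# flexion, shoulder rotation, shoulder elevation and elevation plane.
# End-effector position in the shoulder frame {S}:
#   e = RS (RL e0 + l0),  RL = RX(theta_ef),
#   RS = RY(theta_se) RZ(theta_sep) RY(-theta_se) RY(theta_sr),
# with RX, RY, RZ the basic right-handed rotation matrices, e0/l0 the rest
# positions of hand (relative to the elbow) and elbow (relative to the
# shoulder). Internal units are SI (m, rad); cm appears only at the
# dataset I/O boundary. Frame axes: x away from the body, y rightward,
# z up.

.RX <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
.RY <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
.RZ <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
.dRX <- function(t) matrix(c(0, 0, 0, 0, -sin(t), cos(t), 0, -cos(t), -sin(t)), 3, 3)
.dRY <- function(t) matrix(c(-sin(t), 0, -cos(t), 0, 0, 0, cos(t), 0, -sin(t)), 3, 3)
.dRZ <- function(t) matrix(c(-sin(t), cos(t), 0, -cos(t), -sin(t), 0, 0, 0, 0), 3, 3)

#' Arm geometry and joint limits
#'
#' @param upper_arm_length shoulder-to-elbow length (m).
#' @param forearm_length elbow-to-hand length (m), including the hand.
#' @param joint_limits 4 x 2 matrix of (min, max) per joint angle (rad) in
#'   the order (elbow flexion, shoulder rotation, shoulder elevation,
#'   elevation plane). Defaults are physiological ranges.
#' @return an `arm_geometry` list with rest positions `e0` (hand relative
#'   to the elbow) and `l0` (elbow relative to the shoulder); at q = 0 the
#'   arm hangs along -z.
#' @export
arm_geometry <- function(upper_arm_length = 0.33, forearm_length = 0.30,
                         joint_limits = NULL) {
  if (upper_arm_length <= 0 || forearm_length <= 0)
    stop_pt("link lengths must be positive", "pt_config_error")
  if (is.null(joint_limits)) {
    joint_limits <- rbind(c(0.00, 2.27),    # elbow flexion
                          c(-1.50, 1.50),   # shoulder rotation
                          c(0.00, 2.90),    # shoulder elevation
                          c(-1.30, 2.60))   # elevation plane
  }
  joint_limits <- as.matrix(joint_limits)
  if (!all(dim(joint_limits) == c(4, 2)) ||
      any(joint_limits[, 1] >= joint_limits[, 2]))
    stop_pt("joint_limits must be 4 x 2 with min < max", "pt_config_error")
  rownames(joint_limits) <- c("theta_ef", "theta_sr", "theta_se", "theta_sep")
  structure(list(upper_arm_length = upper_arm_length,
                 forearm_length = forearm_length,
                 e0 = c(0, 0, -forearm_length),
                 l0 = c(0, 0, -upper_arm_length),
                 joint_limits = joint_limits),
            class = "arm_geometry")
}

#' Natural (resting) pose: the mid-range of each joint limit
#' @param geom an [arm_geometry()].
#' @return 4-vector of joint angles (rad).
#' @export
natural_pose <- function(geom) {
  unname(rowMeans(geom$joint_limits))
}

.shoulder_rotation <- function(q) {
  .RY(q[3]) %*% .RZ(q[4]) %*% .RY(-q[3]) %*% .RY(q[2])
}

#' Forward kinematics
#'
#' @param q joint angles (4-vector, rad).
#' @param geom an [arm_geometry()].
#' @return end-effector position (3-vector, m) in the shoulder frame.
#' @export
forward_kinematics <- function(q, geom) {
  stopifnot(length(q) == 4, all(is.finite(q)))
  RS <- .shoulder_rotation(q)
  as.numeric(RS %*% (.RX(q[1]) %*% geom$e0 + geom$l0))
}

#' Analytic Jacobian of the forward kinematics
#'
#' @param q joint angles (4-vector, rad).
#' @param geom an [arm_geometry()].
#' @return 3 x 4 matrix de/dq.
#' @export
fk_jacobian <- function(q, geom) {
  A <- .RY(q[3]); B <- .RZ(q[4]); C <- .RY(-q[3]); D <- .RY(q[2])
  RL_e0 <- .RX(q[1]) %*% geom$e0
  p <- RL_e0 + geom$l0
  RS <- A %*% B %*% C %*% D
  J <- matrix(0, 3, 4)
  J[, 1] <- RS %*% (.dRX(q[1]) %*% geom$e0)
  J[, 2] <- A %*% B %*% C %*% .dRY(q[2]) %*% p
  J[, 3] <- (.dRY(q[3]) %*% B %*% C %*% D - A %*% B %*% .dRY(-q[3]) %*% D) %*% p
  J[, 4] <- A %*% .dRZ(q[4]) %*% C %*% D %*% p
  J
}

#' Is a point inside the arm's reach annulus?
#' @param e 3D point (m).
#' @param geom an [arm_geometry()].
#' @param slack tolerance (m) added on both sides.
#' @return logical.
#' @export
reachable <- function(e, geom, slack = 1e-6) {
  r <- sqrt(sum(e^2))
  r_max <- geom$upper_arm_length + geom$forearm_length
  r_min <- abs(geom$upper_arm_length - geom$forearm_length)
  r <= r_max + slack && r >= r_min - slack
}

#' One constrained inverse-kinematics step
#'
#' Finds joint angles close to `q_prev` whose forward kinematics match
#' `e_target` to within `tol_e`, subject to the joint limits. The
#' minimal-change objective is realized by damped least-squares updates
#' from the warm start (minimum-norm steps), with limit clamping at every
#' iteration and an L-BFGS-B polish as fallback.
#'
#' @param e_target 3D target (m).
#' @param q_prev warm-start joint angles (4-vector, rad).
#' @param geom an [arm_geometry()].
#' @param tol_e end-effector tolerance (m), default 1e-4.
#' @param max_iter damped least-squares iteration cap.
#' @return list with `q`, `residual` (m), `iterations`.
#' @export
inverse_kinematics_step <- function(e_target, q_prev, geom,
                                    tol_e = 1e-4, max_iter = 100L) {
  stopifnot(length(e_target) == 3)
  if (!reachable(e_target, geom, slack = tol_e))
    stop_pt(sprintf("target outside reach annulus (|e| = %.3f m)",
                    sqrt(sum(e_target^2))),
            "pt_ik_infeasible", residual = sqrt(sum(e_target^2)))
  lims <- geom$joint_limits
  solve_from <- function(q0) {
    q <- pmin(pmax(q0, lims[, 1]), lims[, 2])
    best <- list(q = q, residual = Inf, iterations = 0L)
    for (it in seq_len(max_iter)) {
      r <- e_target - forward_kinematics(q, geom)
      nr <- sqrt(sum(r^2))
      if (nr < best$residual) best <- list(q = q, residual = nr, iterations = it - 1L)
      if (nr <= tol_e) return(best)
      J <- fk_jacobian(q, geom)
      dq <- crossprod(J, solve(J %*% t(J) + diag(1e-6, 3), r))
      step <- sqrt(sum(dq^2))
      if (step > 0.5) dq <- dq * (0.5 / step)  # trust region
      q <- pmin(pmax(q + as.numeric(dq), lims[, 1]), lims[, 2])
    }
    # polish: bounded quasi-Newton on the squared residual
    obj <- function(qq) sum((forward_kinematics(qq, geom) - e_target)^2)
    grad <- function(qq) as.numeric(2 * crossprod(
      fk_jacobian(qq, geom), forward_kinematics(qq, geom) - e_target))
    fit <- stats::optim(best$q, obj, grad, method = "L-BFGS-B",
                        lower = lims[, 1], upper = lims[, 2],
                        control = list(maxit = 200))
    list(q = fit$par, residual = sqrt(fit$value), iterations = max_iter)
  }
  sol <- solve_from(q_prev)
  if (sol$residual <= tol_e) return(sol)
  # warm start trapped at a limit corner: deterministic restart poses
  best <- sol
  fr <- function(f) lims[, 1] + f * (lims[, 2] - lims[, 1])
  restarts <- list(fr(0.5), fr(0.25), fr(0.75),
                   fr(c(0.25, 0.5, 0.75, 0.25)), fr(c(0.75, 0.5, 0.25, 0.75)),
                   fr(c(0.5, 0.25, 0.75, 0.5)), fr(c(0.5, 0.75, 0.25, 0.5)))
  for (q0 in restarts) {
    sol <- solve_from(q0)
    if (sol$residual < best$residual) best <- sol
    if (best$residual <= tol_e) return(best)
  }
  stop_pt(sprintf("IK infeasible: best residual %.2e m > tol %.1e m",
                  best$residual, tol_e),
          "pt_ik_infeasible", residual = best$residual)
}

#' Solve inverse kinematics along a trajectory
#'
#' Sequential solve with warm start from the previous frame, which yields
#' smooth movements in joint space; the initial reference pose is the
#' natural pose in the center of the workspace.
#'
#' @param e_traj n x 3 matrix of end-effector targets (m).
#' @param geom an [arm_geometry()].
#' @param q_init warm start for the first frame, default [natural_pose()].
#' @param dt sampling interval (s), stored on the result.
#' @param tol_e end-effector tolerance (m).
#' @return a `joint_trajectory`: list with `q` (n x 4 matrix), `dt`.
#' @export
solve_trajectory_ik <- function(e_traj, geom, q_init = natural_pose(geom),
                                dt = 0.015, tol_e = 1e-4) {
  e_traj <- as.matrix(e_traj)
  n <- nrow(e_traj)
  q <- matrix(NA_real_, n, 4)
  q_prev <- q_init
  for (i in seq_len(n)) {
    sol <- tryCatch(
      inverse_kinematics_step(e_traj[i, ], q_prev, geom, tol_e = tol_e),
      pt_ik_infeasible = function(e)
        stop_pt(sprintf("frame %d: %s", i, conditionMessage(e)),
                "pt_ik_infeasible", frame = i))
    q[i, ] <- sol$q
    q_prev <- sol$q
  }
  structure(list(q = q, dt = dt), class = "joint_trajectory")
}

#' Compute the grid of feasible writing-plane start points
#'
#' Candidate planes are horizontal (fixed z) and vertical (fixed x) planes
#' at `spacing`-cm offsets; candidate start points lie on an in-plane grid
#' of the same spacing. A start point is retained only when the corners of
#' the character bounding box (half-width `char_extent / 2`, which should
#' already include the largest augmentation scale) placed around it pass an
#' inverse-kinematics feasibility check.
#'
#' @param geom an [arm_geometry()].
#' @param spacing grid spacing (cm), default 3.
#' @param char_extent character bounding-box side (cm), default 13
#'   (10 cm box times the largest scale 1.3).
#' @param horizontal_offsets candidate z offsets (cm); defaults span the
#'   workspace below and around shoulder height.
#' @param vertical_offsets candidate x offsets (cm).
#' @param orientations which plane orientations to include.
#' @return list of [writing_plane()] objects, one per retained start point.
#' @export
compute_start_grid <- function(geom, spacing = 3, char_extent = 13,
                               horizontal_offsets = seq(-24, 6, by = spacing),
                               vertical_offsets = seq(21, 45, by = spacing),
                               inplane_u = seq(-24, 36, by = spacing),
                               inplane_v = NULL,
                               orientations = c("horizontal", "vertical")) {
  if (spacing <= 0) stop_pt("spacing must be > 0", "pt_config_error")
  h <- ceiling(char_extent / 2 / spacing) * spacing  # snap corners onto the grid
  key_args <- paste(format(c(geom$upper_arm_length, geom$forearm_length,
                             geom$joint_limits, spacing, char_extent,
                             horizontal_offsets, vertical_offsets,
                             inplane_u, inplane_v %||% -999), digits = 10),
                    collapse = "|")
  key_args <- paste(key_args, paste(orientations, collapse = ","))
  hit <- .grid_cache[[key_args]]
  if (!is.null(hit)) return(hit)
  cache <- new.env(parent = emptyenv())
  feasible_pt <- function(p_cm) {
    key <- paste(p_cm, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    ok <- reachable(p_cm / 100, geom, slack = -0.005) &&
      .ik_feasible(p_cm / 100, geom)
    cache[[key]] <- ok
    ok
  }
  corner_offsets <- as.matrix(expand.grid(a = c(-h, h), b = c(-h, h)))
  planes <- list()
  for (orient in orientations) {
    offsets <- if (orient == "horizontal") horizontal_offsets else vertical_offsets
    vgrid <- inplane_v %||%
      (if (orient == "horizontal") seq(12, 54, by = spacing)
       else seq(-24, 6, by = spacing))
    for (off in offsets) {
      for (u in inplane_u) for (v in vgrid) {
        # u: rightward (y); v: away (x) on horizontal planes, up (z) on vertical
        sp <- if (orient == "horizontal") c(v, u, off) else c(off, u, v)
        ok <- TRUE
        for (ci in seq_len(nrow(corner_offsets))) {
          co <- corner_offsets[ci, ]
          corner <- if (orient == "horizontal")
            sp + c(co[["b"]], co[["a"]], 0) else sp + c(0, co[["a"]], co[["b"]])
          if (!feasible_pt(corner)) { ok <- FALSE; break }
        }
        if (ok) planes[[length(planes) + 1]] <- writing_plane(orient, sp)
      }
    }
  }
  .grid_cache[[key_args]] <- planes
  planes
}

# session cache: the start grid depends only on geometry and grid settings
.grid_cache <- new.env(parent = emptyenv())

# Cheap feasibility probe used for workspace gridding: a short damped
# least-squares run from the natural pose plus two fixed restarts. Budgeted
# for speed, not for the minimal-change objective.
.ik_feasible <- function(p, geom, tol = 1e-3) {
  lims <- geom$joint_limits
  dls <- function(q, iters) {
    for (it in seq_len(iters)) {
      r <- p - forward_kinematics(q, geom)
      if (sqrt(sum(r^2)) <= tol) return(list(q = q, ok = TRUE))
      J <- fk_jacobian(q, geom)
      dq <- crossprod(J, solve(J %*% t(J) + diag(1e-6, 3), r))
      step <- sqrt(sum(dq^2))
      if (step > 0.5) dq <- dq * (0.5 / step)
      q <- pmin(pmax(q + as.numeric(dq), lims[, 1]), lims[, 2])
    }
    list(q = q, ok = FALSE, residual = sqrt(sum((forward_kinematics(q, geom) - p)^2)))
  }
  fr <- function(f) lims[, 1] + f * (lims[, 2] - lims[, 1])
  for (q0 in list(fr(0.5), fr(0.25), fr(0.75))) {
    s <- dls(q0, 40L)
    if (s$ok) return(TRUE)
    if (s$residual < 0.03) {  # close: polish with bounded quasi-Newton
      fit <- stats::optim(s$q, function(qq) sum((forward_kinematics(qq, geom) - p)^2),
                          function(qq) as.numeric(2 * crossprod(
                            fk_jacobian(qq, geom),
                            forward_kinematics(qq, geom) - p)),
                          method = "L-BFGS-B",
                          lower = lims[, 1], upper = lims[, 2],
                          control = list(maxit = 60))
      if (sqrt(fit$value) <= tol) return(TRUE)
    }
  }
  FALSE
}
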