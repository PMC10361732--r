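# Muscle geometry stand-in and spindle-style proprioceptive inputs.
#
# The mapping from joint angles to the 25 equilibrium muscle fiber lengths
# is a configurable moment-arm model: m_i(q) = L0_i + sum_j C_ij (q_j -
# q_ref_j) + sum_j Q_ij (q_j - q_ref_j)^2, i.e. constant (or low-order
# polynomial) moment arms about a reference posture. It is a pluggable
# stand-in for a full musculoskeletal engine: any function mapping a joint
# trajectory to a 25 x T length matrix can be substituted via the
# `length_fn` slot, preserving the rest of the pipeline.

#' Default 25-muscle geometry
#'
#' Moment arms (m/rad) couple each muscle to the four degrees of freedom
#' (elbow flexion, shoulder rotation, shoulder elevation, elevation plane);
#' shoulder muscles span the three shoulder angles, elbow muscles the
#' flexion angle, and the long biceps/triceps heads are biarticular.
#' Antagonist pairs carry opposite signs so that passive movements shorten
#' some muscles while stretching others.
#'
#' @param q_ref reference posture (rad) at which muscles take their rest
#'   length; defaults to the mid-range natural pose of [arm_geometry()].
#' @return a `muscle_geometry` list with `names`, `L0` (m), moment-arm
#'   matrix `C` (25 x 4), quadratic terms `Q` (25 x 4), `q_ref`.
#' @export
default_muscle_geometry <- function(q_ref = natural_pose(arm_geometry())) {
  names <- c("DELT1", "DELT2", "DELT3", "SUPSP", "INFSP", "SUBSC", "TMIN",
             "TMAJ", "PECM1", "PECM2", "PECM3", "LAT1", "LAT2", "LAT3",
             "CORB", "TRIlong", "TRIlat", "TRImed", "ANC", "SUP",
             "BIClong", "BICshort", "BRA", "BRD", "ECRL")
  # columns: theta_ef, theta_sr, theta_se, theta_sep
  C <- rbind(
    DELT1    = c(0.000,  0.010, -0.033,  0.016),
    DELT2    = c(0.000,  0.000, -0.042,  0.000),
    DELT3    = c(0.000, -0.012, -0.030, -0.018),
    SUPSP    = c(0.000,  0.006, -0.024,  0.008),
    INFSP    = c(0.000, -0.028,  0.010, -0.012),
    SUBSC    = c(0.000,  0.030,  0.008,  0.010),
    TMIN     = c(0.000, -0.022,  0.014, -0.008),
    TMAJ     = c(0.000,  0.018,  0.030, -0.014),
    PECM1    = c(0.000,  0.016, -0.012,  0.034),
    PECM2    = c(0.000,  0.014,  0.010,  0.038),
    PECM3    = c(0.000,  0.010,  0.022,  0.030),
    LAT1     = c(0.000, -0.014,  0.034, -0.024),
    LAT2     = c(0.000, -0.010,  0.038, -0.018),
    LAT3     = c(0.000, -0.006,  0.032, -0.012),
    CORB     = c(0.000,  0.008, -0.018,  0.022),
    TRIlong  = c(0.022,  0.000,  0.020, -0.010),
    TRIlat   = c(0.024,  0.000,  0.000,  0.000),
    TRImed   = c(0.021,  0.000,  0.000,  0.000),
    ANC      = c(0.018,  0.000,  0.000,  0.000),
    SUP      = c(0.006, -0.014,  0.000,  0.000),
    BIClong  = c(-0.030, 0.000, -0.022,  0.012),
    BICshort = c(-0.032, 0.000, -0.010,  0.018),
    BRA      = c(-0.026, 0.000,  0.000,  0.000),
    BRD      = c(-0.034, 0.008,  0.000,  0.000),
    ECRL     = c(-0.020, 0.012,  0.000,  0.000)
  )
  L0 <- c(0.16, 0.15, 0.16, 0.12, 0.14, 0.15, 0.12, 0.16, 0.18, 0.19, 0.20,
          0.24, 0.23, 0.22, 0.17, 0.26, 0.18, 0.17, 0.10, 0.08,
          0.28, 0.25, 0.16, 0.25, 0.22)
  muscle_geometry(names, L0, C, q_ref = q_ref)
}

#' Construct a muscle geometry
#'
#' @param names muscle identifiers (must be 25 for the standard pipeline).
#' @param L0 rest lengths (m), positive.
#' @param C moment-arm matrix (n_muscles x 4, m/rad).
#' @param Q optional quadratic moment-arm terms (same shape), default 0.
#' @param q_ref reference posture (rad).
#' @param n_required expected muscle count (default 25).
#' @return a `muscle_geometry` object.
#' @export
muscle_geometry <- function(names, L0, C, Q = NULL, q_ref = rep(0, 4),
                            n_required = 25L) {
  C <- as.matrix(C)
  n <- length(names)
  if (!is.null(n_required) && n != n_required)
    stop_pt(sprintf("expected %d muscles, got %d", n_required, n),
            "pt_config_error")
  if (length(L0) != n || nrow(C) != n || ncol(C) != 4)
    stop_pt("inconsistent muscle geometry dimensions", "pt_config_error")
  if (any(L0 <= 0)) stop_pt("rest lengths must be positive", "pt_config_error")
  if (any(rowSums(abs(C)) == 0))
    stop_pt("every muscle must couple to at least one DoF", "pt_config_error")
  if (is.null(Q)) Q <- matrix(0, n, 4)
  structure(list(names = names, L0 = as.numeric(L0), C = unname(C),
                 Q = unname(as.matrix(Q)), q_ref = as.numeric(q_ref)),
            class = "muscle_geometry")
}

#' Equilibrium muscle lengths along a joint trajectory
#'
#' @param q_traj a `joint_trajectory` (from [solve_trajectory_ik()]) or an
#'   n x 4 matrix of joint angles (rad).
#' @param geom a [muscle_geometry()].
#' @return 25 x T matrix of muscle lengths (m).
#' @export
muscle_lengths <- function(q_traj, geom) {
  stopifnot(inherits(geom, "muscle_geometry"))
  q <- if (inherits(q_traj, "joint_trajectory")) q_traj$q else as.matrix(q_traj)
  dq <- sweep(q, 2, geom$q_ref)          # T x 4
  m <- geom$L0 + geom$C %*% t(dq)        # 25 x T
  if (any(geom$Q != 0)) m <- m + geom$Q %*% t(dq^2)
  dimnames(m) <- list(geom$names, NULL)
  m
}

#' Muscle velocities by finite differences
#'
#' Central differences in the interior, one-sided at the ends.
#'
#' @param m 25 x T matrix of muscle lengths (m).
#' @param dt sampling interval (s).
#' @return 25 x T matrix of muscle velocities (m/s).
#' @export
muscle_velocities <- function(m, dt) {
  if (ncol(m) < 2)
    stop_pt("need at least 2 time points", "pt_shape_error")
  t(finite_diff(t(m), dt))
}

#' Spindle afferent rate proxy
#'
#' Affine combination of muscle length, velocity, acceleration and EMG
#' with weights `k = (k1..k5)`. In passive mode (the default) the EMG term
#' is forced to zero regardless of the supplied activity.
#'
#' @param l,l_dot,l_ddot muscle length (m), velocity (m/s), acceleration
#'   (m/s^2); vectors or matrices of a common shape.
#' @param emg muscle activity; ignored when `passive = TRUE`.
#' @param k 5-vector of weights (intercept, length, velocity, acceleration,
#'   EMG).
#' @param passive logical; passive movements carry negligible EMG.
#' @return afferent rate proxy with the shape of the inputs.
#' @export
spindle_response <- function(l, l_dot = 0, l_ddot = 0, emg = 0,
                             k = c(0, 1, 1, 0, 0), passive = TRUE) {
  stopifnot(length(k) == 5, all(is.finite(k)))
  if (passive) emg <- 0
  k[1] + k[2] * l + k[3] * l_dot + k[4] * l_ddot + k[5] * emg
}

#' Stack lengths and velocities into the proprioceptive input tensor
#'
#' @param m 25 x T muscle lengths.
#' @param v 25 x T muscle velocities.
#' @param normalizer optional per-channel normalizer from
#'   [fit_channel_normalizer()].
#' @return 25 x T x 2 array (length channel first).
#' @export
assemble_input <- function(m, v, normalizer = NULL) {
  if (!all(dim(m) == dim(v)))
    stop_pt("length and velocity matrices must agree in shape", "pt_shape_error")
  x <- array(0, c(nrow(m), ncol(m), 2))
  x[, , 1] <- m
  x[, , 2] <- v
  if (!is.null(normalizer)) x <- apply_normalizer(x, normalizer)
  x
}

#' Fit a per-channel standardizer on training inputs
#'
#' One mean/sd pair per (muscle, channel), estimated on the training split
#' only and reused verbatim elsewhere.
#'
#' @param inputs n x 25 x T x 2 array of training inputs.
#' @return a `channel_normalizer` with 25 x 2 `mean` and `sd` matrices.
#' @export
fit_channel_normalizer <- function(inputs) {
  mu <- apply(inputs, c(2, 4), mean)
  sd <- apply(inputs, c(2, 4), stats::sd)
  sd[sd < 1e-12] <- 1
  structure(list(mean = mu, sd = sd), class = "channel_normalizer")
}

#' Apply a per-channel standardizer
#'
#' @param x 25 x T x 2 array (single sample) or n x 25 x T x 2 array.
#' @param normalizer a `channel_normalizer`.
#' @return standardized array of the same shape.
#' @export
apply_normalizer <- function(x, normalizer) {
  d <- dim(x)
  if (length(d) == 3) {
    for (ch in 1:2)
      x[, , ch] <- (x[, , ch] - normalizer$mean[, ch]) / normalizer$sd[, ch]
  } else if (length(d) == 4) {
    for (ch in 1:2)
      x[, , , ch] <- sweep(sweep(x[, , , ch, drop = FALSE], 2,
                                 normalizer$mean[, ch]),
                           2, normalizer$sd[, ch], `/`)
  } else stop_pt("expected a 3- or 4-dimensional input array", "pt_shape_error")
  x
}
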