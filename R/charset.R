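# Single-stroke character trajectories: generation, normalization, I/O.
#
# Twenty lowercase Latin letters can be handwritten in one stroke (all but
# f, i, j, k, t, x). Each retained class is described by a hand-specified
# spline template; sampled trajectories emulate a pen-tip recording: smooth
# path, bell-shaped speed profile, 200 Hz sampling in a ~1 cm box, later
# rescaled to the 10 x 10 cm writing grid at 66.7 Hz.

#' The 20 retained single-stroke character classes
#' @export
character_classes <- function() {
  setdiff(letters, c("f", "i", "j", "k", "t", "x"))
}

# Template registry: control points of each letter's stroke in a roughly
# unit box. 5-9 points per class; visually distinct, single continuous
# stroke. Coordinates are cm at the original (pen-tablet) scale.
.char_templates <- list(
  a = cbind(c(0.70, 0.45, 0.20, 0.30, 0.60, 0.72, 0.75),
            c(0.60, 0.75, 0.55, 0.25, 0.25, 0.50, 0.20)),
  b = cbind(c(0.25, 0.25, 0.25, 0.55, 0.70, 0.50, 0.27),
            c(0.95, 0.50, 0.10, 0.05, 0.30, 0.50, 0.45)),
  c = cbind(c(0.75, 0.45, 0.20, 0.25, 0.50, 0.78),
            c(0.70, 0.85, 0.55, 0.25, 0.10, 0.25)),
  d = cbind(c(0.68, 0.40, 0.20, 0.35, 0.62, 0.70, 0.70),
            c(0.45, 0.62, 0.40, 0.12, 0.20, 0.90, 0.10)),
  e = cbind(c(0.25, 0.70, 0.60, 0.30, 0.15, 0.30, 0.70),
            c(0.45, 0.50, 0.80, 0.75, 0.45, 0.15, 0.12)),
  g = cbind(c(0.70, 0.40, 0.20, 0.35, 0.65, 0.72, 0.70, 0.45, 0.25),
            c(0.65, 0.80, 0.55, 0.30, 0.35, 0.60, 0.05, -0.15, -0.05)),
  h = cbind(c(0.20, 0.20, 0.20, 0.30, 0.55, 0.70, 0.72),
            c(0.95, 0.50, 0.10, 0.45, 0.55, 0.35, 0.10)),
  l = cbind(c(0.45, 0.42, 0.40, 0.55, 0.68),
            c(0.95, 0.55, 0.15, 0.05, 0.12)),
  m = cbind(c(0.10, 0.12, 0.22, 0.32, 0.35, 0.45, 0.55, 0.63, 0.68),
            c(0.12, 0.55, 0.62, 0.45, 0.10, 0.55, 0.62, 0.40, 0.10)),
  n = cbind(c(0.20, 0.22, 0.30, 0.50, 0.62, 0.65),
            c(0.10, 0.55, 0.62, 0.55, 0.35, 0.10)),
  o = cbind(c(0.50, 0.22, 0.20, 0.50, 0.75, 0.72, 0.52),
            c(0.80, 0.60, 0.30, 0.12, 0.30, 0.62, 0.78)),
  p = cbind(c(0.25, 0.25, 0.25, 0.28, 0.50, 0.70, 0.55, 0.30),
            c(0.60, 0.10, -0.30, 0.30, 0.62, 0.45, 0.20, 0.25)),
  q = cbind(c(0.65, 0.35, 0.18, 0.40, 0.65, 0.68, 0.66, 0.80),
            c(0.60, 0.70, 0.40, 0.15, 0.30, 0.60, -0.20, -0.28)),
  r = cbind(c(0.25, 0.25, 0.25, 0.28, 0.45, 0.65),
            c(0.65, 0.35, 0.10, 0.45, 0.65, 0.60)),
  s = cbind(c(0.70, 0.40, 0.25, 0.50, 0.70, 0.50, 0.20),
            c(0.75, 0.85, 0.60, 0.45, 0.30, 0.08, 0.18)),
  u = cbind(c(0.20, 0.22, 0.40, 0.60, 0.68, 0.70),
            c(0.65, 0.25, 0.10, 0.20, 0.65, 0.10)),
  v = cbind(c(0.20, 0.35, 0.45, 0.55, 0.70),
            c(0.70, 0.35, 0.10, 0.35, 0.70)),
  w = cbind(c(0.10, 0.22, 0.35, 0.48, 0.62),
            c(0.70, 0.10, 0.55, 0.10, 0.70)),
  y = cbind(c(0.20, 0.30, 0.45, 0.62, 0.68, 0.60, 0.45, 0.25),
            c(0.70, 0.40, 0.25, 0.45, 0.70, 0.20, -0.15, -0.25)),
  z = cbind(c(0.20, 0.50, 0.70, 0.45, 0.20, 0.50, 0.75),
            c(0.70, 0.72, 0.68, 0.40, 0.12, 0.10, 0.12))
)

#' Construct a pen trajectory
#'
#' A labeled 2D pen-tip path with per-sample velocities.
#'
#' @param label character class, one of [character_classes()].
#' @param points n x 2 matrix of positions (cm).
#' @param dt sampling interval (s).
#' @param velocity n x 2 matrix of velocities (cm/s); computed by finite
#'   differences when omitted.
#' @return an object of class `pen_trajectory`.
#' @export
pen_trajectory <- function(label, points, dt, velocity = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 2)
    stop_pt("a pen trajectory needs at least 2 points", "pt_degenerate_path")
  if (!is.numeric(dt) || dt <= 0)
    stop_pt("dt must be positive", "pt_config_error")
  if (!label %in% character_classes())
    stop_pt(sprintf("unknown character class '%s'", label), "pt_config_error")
  if (is.null(velocity)) velocity <- finite_diff(points, dt)
  if (nrow(velocity) != nrow(points))
    stop_pt("points and velocity must have equal length", "pt_shape_error")
  structure(list(label = label, points = unname(points), dt = dt,
                 velocity = unname(as.matrix(velocity))),
            class = "pen_trajectory")
}

#' @export
print.pen_trajectory <- function(x, ...) {
  cat(sprintf("<pen_trajectory '%s': %d samples, dt = %g s, %.2f s>\n",
              x$label, nrow(x$points), x$dt, (nrow(x$points) - 1) * x$dt))
  invisible(x)
}

# Evaluate a template: spline-smooth the control polygon and sample it with
# a bell-shaped speed profile (fast mid-stroke, slow at the ends).
.sample_template <- function(cp, duration, dt) {
  k <- nrow(cp)
  s_knots <- seq(0, 1, length.out = k)
  fx <- stats::splinefun(s_knots, cp[, 1], method = "natural")
  fy <- stats::splinefun(s_knots, cp[, 2], method = "natural")
  n <- max(round(duration / dt) + 1, 8)
  # arc-position profile: integrate a smooth bell speed profile
  tau <- (seq_len(n) - 0.5) / n
  w <- 0.25 + sin(pi * tau)^2
  s <- c(0, cumsum(w))
  s <- s / s[length(s)]
  s <- s[seq_len(n)] / s[n]
  pts <- cbind(fx(s), fy(s))
  pen_trajectory_raw(pts, dt)
}

# internal: points -> (points, velocity) without label checks
pen_trajectory_raw <- function(pts, dt) list(points = pts, dt = dt)

#' Generate synthetic single-stroke character trajectories
#'
#' Draws `n_per_class` trajectories for each of the 20 retained classes from
#' the fixed spline template registry, with seeded jitter of the control
#' points and the stroke duration. Trajectories are sampled at 200 Hz
#' (dt = 5 ms) in an approximately 1 x 1 cm box, emulating a pen-tablet
#' recording.
#'
#' @param n_per_class number of trajectories per class (>= 1).
#' @param noise_scale standard deviation (cm) of the control-point jitter.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @param classes subset of classes (default all 20).
#' @return list of [pen_trajectory()] objects, `20 * n_per_class` long.
#' @export
generate_synthetic_characters <- function(n_per_class, noise_scale = 0.03,
                                          seed = 1L,
                                          classes = character_classes()) {
  if (n_per_class < 1) stop_pt("n_per_class must be >= 1", "pt_config_error")
  if (noise_scale < 0) stop_pt("noise_scale must be >= 0", "pt_config_error")
  bad <- setdiff(classes, names(.char_templates))
  if (length(bad))
    stop_pt(sprintf("no template for class: %s", paste(bad, collapse = ", ")),
            "pt_config_error")
  set.seed(seed)
  out <- vector("list", length(classes) * n_per_class)
  i <- 0
  for (cl in classes) {
    cp0 <- .char_templates[[cl]]
    # duration scales with the control-polygon length; capped so that the
    # slowest augmented variant still fits the 4.8 s input window
    plen <- sum(sqrt(rowSums(diff(cp0)^2)))
    base_dur <- min(0.45 + 0.28 * plen, 1.1)
    for (r in seq_len(n_per_class)) {
      cp <- cp0 + matrix(stats::rnorm(length(cp0), 0, noise_scale), ncol = 2)
      dur <- base_dur * stats::runif(1, 0.9, 1.1)
      raw <- .sample_template(cp, dur, 0.005)
      i <- i + 1
      out[[i]] <- pen_trajectory(cl, raw$points, raw$dt)
    }
  }
  out
}

# Resample a trajectory onto a new uniform time grid of n_out samples
# spanning the same duration, interpolating positions linearly in time so
# that the (normalized) velocity profile is preserved.
.resample_n <- function(traj, n_out, new_dt) {
  n_in <- nrow(traj$points)
  t_in <- seq(0, 1, length.out = n_in)
  t_out <- seq(0, 1, length.out = n_out)
  pts <- interp_matrix(traj$points, t_in, t_out)
  pen_trajectory(traj$label, pts, new_dt)
}

#' Rescale a trajectory to the writing grid and resample it
#'
#' Rescales positions to fit a `box` x `box` cm square (centered on the
#' trajectory's bounding-box center, aspect ratio preserved) and changes the
#' sampling interval to `out_dt`. Writing a character on the large grid
#' takes proportionally longer, so the per-sample interval is stretched
#' (5 ms -> 15 ms by default) while keeping the sample count: the relative
#' speed profile over normalized time is untouched.
#'
#' @param traj a [pen_trajectory()].
#' @param box side length (cm) of the target square, default 10.
#' @param out_dt output sampling interval (s), default 0.015 (66.7 Hz).
#' @return a [pen_trajectory()] whose points lie within the box.
#' @export
rescale_and_resample <- function(traj, box = 10, out_dt = 0.015) {
  stopifnot(inherits(traj, "pen_trajectory"))
  if (nrow(traj$points) < 2)
    stop_pt("cannot resample a single-point path", "pt_degenerate_path")
  rng <- apply(traj$points, 2, range)
  extent <- max(rng[2, ] - rng[1, ])
  ctr <- colMeans(rng)
  sc <- if (extent > 0) box / extent else 1
  pts <- sweep(traj$points, 2, ctr) * sc
  pen_trajectory(traj$label, pts, out_dt)
}

#' Read pen trajectories from the velocity-format text container
#'
#' The container holds one block per sample: a header line `label n`
#' followed by three whitespace-separated rows of `n` values each
#' (x-velocity, y-velocity, pen pressure) sampled at 200 Hz. The pressure
#' channel is discarded; positions are recovered by integrating the
#' velocities. Only the 20 single-stroke classes are accepted.
#'
#' @param path path to the container file.
#' @return list of [pen_trajectory()] objects with dt = 5 ms.
#' @export
load_uci_trajectories <- function(path) {
  if (!file.exists(path))
    stop_pt(sprintf("trajectory file not found: %s", path), "pt_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(hdr) != 2)
      stop_pt(sprintf("malformed header at line %d", i), "pt_format_error")
    label <- hdr[1]
    n <- suppressWarnings(as.integer(hdr[2]))
    if (is.na(n) || n < 2 || i + 3 > length(lines))
      stop_pt(sprintf("malformed block at line %d", i), "pt_format_error")
    if (!label %in% character_classes())
      stop_pt(sprintf("label '%s' is not a single-stroke class", label),
              "pt_format_error")
    rows <- lapply(lines[i + 1:3], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (any(lengths(rows) != n))
      stop_pt(sprintf("row length mismatch in block at line %d", i),
              "pt_format_error")
    dt <- 0.005
    vel <- cbind(rows[[1]], rows[[2]])
    pts <- apply(vel, 2, function(v) cumsum(v) * dt)
    out[[length(out) + 1]] <- pen_trajectory(label, pts, dt, vel)
    i <- i + 4
  }
  out
}

#' Write pen trajectories to the velocity-format text container
#'
#' Inverse of [load_uci_trajectories()]; pressure is written as zeros.
#'
#' @param trajs list of [pen_trajectory()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in trajs) {
    n <- nrow(tr$points)
    writeLines(sprintf("%s %d", tr$label, n), con)
    writeLines(paste(format(tr$velocity[, 1], digits = 8), collapse = " "), con)
    writeLines(paste(format(tr$velocity[, 2], digits = 8), collapse = " "), con)
    writeLines(paste(rep("0", n), collapse = " "), con)
  }
  invisible(path)
}
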