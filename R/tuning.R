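# Single-unit tuning analysis: kinematic features of the end-effector
# trace, cosine/linear tuning-curve fits, label selectivity, and
# classification of units into tuning types.
#
# Conventions: analyses run in the 2D writing plane. The first in-plane
# axis points rightward, the second away from the body (horizontal
# planes) or upward (vertical planes); movement direction 0 is rightward
# and 90 degrees is away/up, counterclockwise positive; angles lie in
# (-pi, pi].

#' Kinematic features of an end-effector trace
#'
#' Computes, per time point: position relative to the trace start (both
#' Cartesian and polar), velocity (speed and direction), and acceleration
#' magnitude. Derivatives use the same finite-difference scheme as the
#' muscle velocities. Frames with speed below `speed_eps` have no defined
#' direction and are flagged invalid for direction-based fits (this
#' removes the static padding).
#'
#' @param e T x 3 end-effector positions (m, shoulder frame).
#' @param orientation `"horizontal"` or `"vertical"` (or a
#'   [writing_plane()]).
#' @param dt sampling interval (s).
#' @param speed_eps minimum speed (cm/s) for a defined direction.
#' @return data.frame with columns rx, ry (cm, start-relative), rho, phi,
#'   vx, vy (cm/s), speed, theta, accel, valid_dir.
#' @export
kinematic_features <- function(e, orientation, dt = 0.015, speed_eps = 1e-4) {
  p <- plane_coordinates(as.matrix(e) * 100, orientation)  # cm, (right, away/up)
  rel <- sweep(p, 2, p[1, ])
  v <- finite_diff(p, dt)
  a <- finite_diff(v, dt)
  speed <- sqrt(rowSums(v^2))
  theta <- wrap_angle(atan2(v[, 2], v[, 1]))
  data.frame(rx = rel[, 1], ry = rel[, 2],
             rho = sqrt(rowSums(rel^2)),
             phi = wrap_angle(atan2(rel[, 2], rel[, 1])),
             vx = v[, 1], vy = v[, 2], speed = speed, theta = theta,
             accel = sqrt(rowSums(a^2)),
             valid_dir = speed > speed_eps)
}

.tuning_kinds <- c("direction", "speed", "velocity", "position_cart",
                   "position_polar", "acceleration")

# Design matrix (without intercept) and validity mask for a tuning kind.
# All kinds relate activity to kinematics during the continuous movement,
# so the static padding frames (no defined direction, degenerate position)
# are excluded throughout.
.tuning_design <- function(frames, kind) {
  moving <- frames$valid_dir
  switch(kind,
    direction = list(X = cbind(cos(frames$theta), sin(frames$theta)),
                     valid = moving, cosine = TRUE),
    speed = list(X = cbind(frames$speed), valid = moving, cosine = FALSE),
    velocity = list(X = cbind(frames$speed * cos(frames$theta),
                              frames$speed * sin(frames$theta)),
                    valid = moving, cosine = TRUE),
    position_cart = list(X = cbind(frames$rx, frames$ry),
                         valid = moving, cosine = FALSE),
    position_polar = list(X = cbind(frames$rho * cos(frames$phi),
                                    frames$rho * sin(frames$phi)),
                          valid = moving, cosine = TRUE),
    acceleration = list(X = cbind(frames$accel), valid = moving,
                        cosine = FALSE),
    stop_pt(sprintf("unknown tuning kind '%s'", kind), "pt_config_error"))
}

# R^2 with the degenerate-target convention: a perfectly predicted
# constant target scores 1 (a "dead" unit), an unpredicted one 0.
.r2_score <- function(y, pred) {
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot < 1e-24) return(if (ss_res < 1e-24) 1 else 0)
  1 - ss_res / ss_tot
}

#' Fit tuning models for many units at once
#'
#' Ordinary least-squares fit of the linearized design of the given kind
#' (cosine models use the sum/difference expansion, so the preferred
#' direction is recovered as atan2 of the two coefficients). The split is
#' between trajectories: no trajectory contributes to both train and test
#' rows.
#'
#' @param Y frames x units activity matrix.
#' @param frames data.frame from [kinematic_features()] (rows pooled over
#'   trajectories).
#' @param traj per-row trajectory id.
#' @param kind one of direction, speed, velocity, position_cart,
#'   position_polar, acceleration.
#' @param train_frac fraction of trajectories used for fitting.
#' @param seed trajectory-split seed.
#' @return data.frame with one row per unit: coefficients, amplitude
#'   `alpha`, preferred direction `theta_pd` (cosine kinds), intercept
#'   `beta`, `train_r2`, `test_r2`, `flagged` (singular design).
#' @export
fit_tuning_models <- function(Y, frames, traj, kind, train_frac = 0.8,
                              seed = 1L) {
  Y <- as.matrix(Y)
  des <- .tuning_design(frames, kind)
  ids <- unique(traj)
  set.seed(seed)
  tr_ids <- sample(ids, max(1, round(train_frac * length(ids))))
  is_tr <- traj %in% tr_ids
  use_tr <- which(is_tr & des$valid)
  use_te <- which(!is_tr & des$valid)
  if (!length(use_tr) || !length(use_te))
    stop_pt("empty train or test rows for tuning fit", "pt_config_error")
  Xtr <- cbind(1, des$X[use_tr, , drop = FALSE])
  fit <- stats::lm.fit(Xtr, Y[use_tr, , drop = FALSE])
  cf <- as.matrix(fit$coefficients)
  flagged <- apply(cf, 2, anyNA)
  cf[is.na(cf)] <- 0
  pred_tr <- Xtr %*% cf
  Xte <- cbind(1, des$X[use_te, , drop = FALSE])
  pred_te <- Xte %*% cf
  nunit <- ncol(Y)
  out <- data.frame(unit = seq_len(nunit), kind = kind,
                    beta = cf[1, ],
                    alpha1 = if (nrow(cf) >= 2) cf[2, ] else NA_real_,
                    alpha2 = if (nrow(cf) >= 3) cf[3, ] else NA_real_,
                    flagged = flagged)
  if (des$cosine) {
    out$alpha <- sqrt(out$alpha1^2 + out$alpha2^2)
    out$theta_pd <- atan2(out$alpha2, out$alpha1)
  } else {
    out$alpha <- out$alpha1
    out$theta_pd <- NA_real_
  }
  out$train_r2 <- vapply(seq_len(nunit), function(u)
    .r2_score(Y[use_tr, u], pred_tr[, u]), numeric(1))
  out$test_r2 <- vapply(seq_len(nunit), function(u)
    .r2_score(Y[use_te, u], pred_te[, u]), numeric(1))
  out
}

#' Fit a single unit's tuning model
#'
#' @param activity per-frame activity vector of one unit.
#' @inheritParams fit_tuning_models
#' @return single-row data.frame (see [fit_tuning_models()]).
#' @export
fit_tuning_model <- function(activity, frames, traj, kind,
                             train_frac = 0.8, seed = 1L) {
  fit_tuning_models(matrix(activity, ncol = 1), frames, traj, kind,
                    train_frac = train_frac, seed = seed)
}

#' Nonlinear cosine tuning fit (reference implementation)
#'
#' Direct nonlinear least squares of `alpha * cos(theta - theta_pd) +
#' beta`; used to validate that the linearized fit is exactly equivalent.
#'
#' @param activity per-frame unit activity.
#' @param theta per-frame direction (rad).
#' @return list with alpha, theta_pd, beta.
#' @export
fit_cosine_nls <- function(activity, theta) {
  lin <- stats::lm.fit(cbind(1, cos(theta), sin(theta)), activity)$coefficients
  start <- list(alpha = unname(sqrt(lin[2]^2 + lin[3]^2)) + 1e-6,
                theta_pd = unname(atan2(lin[3], lin[2])),
                beta = unname(lin[1]))
  # tolerance is pushed to the machine-precision floor; nls may report
  # hitting the iteration cap there although the fit is at the optimum,
  # so convergence chatter is muffled (the linearized fit bounds the
  # result to ~1e-8 regardless)
  fit <- suppressWarnings(
    stats::nls(a ~ alpha * cos(theta - theta_pd) + beta,
               data = data.frame(a = activity, theta = theta),
               start = start,
               control = stats::nls.control(maxiter = 200, tol = 1e-12,
                                            minFactor = 1e-10,
                                            warnOnly = TRUE)))
  cf <- stats::coef(fit)
  if (cf[["alpha"]] < 0) {  # canonical form: positive amplitude
    cf[["alpha"]] <- -cf[["alpha"]]
    cf[["theta_pd"]] <- wrap_angle(cf[["theta_pd"]] + pi)
  }
  list(alpha = cf[["alpha"]], theta_pd = wrap_angle(cf[["theta_pd"]]),
       beta = cf[["beta"]])
}

#' Label selectivity of single units
#'
#' For each unit, one-vs-rest linear classifiers are trained per class on
#' the unit's own activity (its feature vector over kept time points);
#' each classifier's auROC measures how well that class can be read from
#' the unit alone, and the selectivity index is `2 * (max auROC - 0.5)`.
#'
#' @param features n_traj x p matrix of one unit's per-trajectory
#'   features (or a vector of scalar rates).
#' @param labels per-trajectory class labels.
#' @param classifier `"svm"` (linear SVM decision values) or `"rate"`
#'   (the activity itself as the score; only for p = 1).
#' @return a `selectivity_result`: list with per-class `auroc`,
#'   `max_auroc`, `si`.
#' @export
label_selectivity <- function(features, labels, classifier = c("svm", "rate")) {
  classifier <- match.arg(classifier)
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop_pt("need at least 2 classes for selectivity", "pt_config_error")
  features <- as.matrix(features)
  aurocs <- vapply(levels(droplevels(labels)), function(cl) {
    yy <- factor(ifelse(labels == cl, "pos", "neg"), levels = c("neg", "pos"))
    score <- if (classifier == "svm") {
      fit <- e1071::svm(features, yy, kernel = "linear", scale = FALSE)
      as.numeric(attr(predict(fit, features, decision.values = TRUE),
                      "decision.values"))
    } else features[, 1]
    if (length(unique(score)) < 2) return(0.5)
    as.numeric(suppressMessages(pROC::auc(yy, score,
                                          direction = "<", quiet = TRUE)))
  }, numeric(1))
  aurocs <- pmax(aurocs, 1 - aurocs)  # orientation-free discriminability
  structure(list(auroc = aurocs, max_auroc = max(aurocs),
                 si = 2 * (max(aurocs) - 0.5)),
            class = "selectivity_result")
}

#' Classify a unit into tuning types
#'
#' A unit belongs to every kind whose held-out R^2 exceeds the threshold;
#' scores equal to 1 (dead unit) or below -0.1 (non-converged fit) are
#' excluded before assignment.
#'
#' @param test_r2 named numeric vector of per-kind test R^2 values.
#' @param threshold assignment threshold, default 0.2.
#' @return character vector of assigned kinds (possibly empty).
#' @export
classify_unit <- function(test_r2, threshold = 0.2) {
  ok <- !is.na(test_r2) & test_r2 != 1 & test_r2 >= -0.1
  names(test_r2)[ok & test_r2 > threshold]
}

#' Pooled kinematic frames for a set of dataset samples
#'
#' Builds the frame table used by the layer-level tuning fits: kinematic
#' features of every sample's end-effector trace, restricted to the kept
#' time points of a network layer (or the full grid), pooled over all
#' samples of a common plane orientation.
#'
#' @param ds a `prop_dataset`.
#' @param idx sample indices (should share a plane orientation).
#' @param time_idx kept time indices (default all).
#' @return list with `frames` (data.frame), `traj` (per-row sample id),
#'   `row_sample`, `row_time` bookkeeping vectors.
#' @export
pooled_frames <- function(ds, idx, time_idx = seq_len(dim(ds$targets_e)[2])) {
  orient <- ds$manifest$plane[idx]
  if (length(unique(orient)) > 1)
    stop_pt("samples must share a plane orientation", "pt_config_error")
  fr <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    f <- kinematic_features(ds$targets_e[idx[k], , ], orient[1],
                            dt = ds$config$dt)
    fr[[k]] <- f[time_idx, ]
  }
  frames <- do.call(rbind, fr)
  list(frames = frames,
       traj = rep(idx, each = length(time_idx)),
       row_sample = rep(idx, each = length(time_idx)),
       row_time = rep(time_idx, times = length(idx)))
}

#' Layer-wide tuning fits on network activations
#'
#' Extracts a layer's activations for the given samples and fits the
#' requested tuning kind for every unit, pooled over all samples (planes
#' of a common orientation).
#'
#' @param net a `prop_net`.
#' @param ds a `prop_dataset`.
#' @param layer layer index.
#' @param idx sample indices (one plane orientation).
#' @param kind tuning kind (see [fit_tuning_models()]).
#' @param seed trajectory-split seed.
#' @return per-unit data.frame from [fit_tuning_models()].
#' @export
layer_tuning_fits <- function(net, ds, layer, idx, kind = "direction",
                              seed = 1L) {
  act <- extract_activations(net, ds$inputs[idx, , , , drop = FALSE], layer)
  pf <- pooled_frames(ds, idx, act$time_idx)
  Y <- act$act                   # (n, Tk, U)
  d <- dim(Y)
  Y <- aperm(Y, c(2, 1, 3))      # (Tk, n, U): time fastest within a sample
  dim(Y) <- c(d[1] * d[2], d[3]) # row r = time + (sample-1)*Tk, matching
  fit_tuning_models(Y, pf$frames, pf$traj, kind, seed = seed)  # pooled rows
}

#' Tuning fits for the spindle input channels
#'
#' Treats each of the 50 input channels (25 muscle lengths, 25 muscle
#' velocities) as a unit and fits the requested tuning kind.
#'
#' @param ds a `prop_dataset`.
#' @param idx sample indices (one plane orientation).
#' @param kind tuning kind.
#' @param seed split seed.
#' @return per-unit data.frame with a `channel` column (`length` or
#'   `velocity`) and `muscle` index.
#' @export
spindle_tuning_fits <- function(ds, idx, kind = "direction", seed = 1L) {
  pf <- pooled_frames(ds, idx)
  n <- length(idx); Tn <- dim(ds$inputs)[3]; nm <- dim(ds$inputs)[2]
  x <- ds$inputs[idx, , , , drop = FALSE]      # (n, M, T, 2)
  x <- aperm(x, c(3, 1, 2, 4))                 # (T, n, M, 2): time fastest
  dim(x) <- c(Tn * n, nm * 2)                  # row r = time + (sample-1)*T
  fits <- fit_tuning_models(x, pf$frames, pf$traj, kind, seed = seed)
  fits$channel <- rep(c("length", "velocity"), each = nm)
  fits$muscle <- rep(seq_len(nm), times = 2)
  fits
}
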