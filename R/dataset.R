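# Dataset assembly: candidate generation, smoothness filtering, balancing,
# padding with onset jitter, stratified splitting, and serialization.

#' Pad a movement to a fixed window with onset jitter
#'
#' Pre-padding repeats the start posture and post-padding the end posture
#' (static postures, zero velocity); the movement onset is drawn uniformly
#' over all feasible offsets so the beginning of the writing is ambiguous.
#'
#' @param m 25 x L muscle lengths of the movement.
#' @param v 25 x L muscle velocities.
#' @param e L x 3 end-effector trace (m).
#' @param T_out output window length (samples).
#' @param onset optional fixed onset (0-based); drawn from the current RNG
#'   stream when `NULL`.
#' @return list with padded `m`, `v` (25 x T_out), `e` (T_out x 3), and the
#'   0-based `onset`.
#' @export
pad_and_jitter <- function(m, v, e, T_out, onset = NULL) {
  L <- ncol(m)
  if (L > T_out)
    stop_pt(sprintf("movement length %d exceeds window %d", L, T_out),
            "pt_shape_error")
  max_onset <- T_out - L
  if (is.null(onset)) onset <- if (max_onset > 0) sample.int(max_onset + 1, 1) - 1L else 0L
  if (onset < 0 || onset > max_onset)
    stop_pt("onset outside feasible range", "pt_config_error")
  pre <- onset; post <- T_out - L - onset
  rep_cols <- function(col, k)
    if (k > 0) matrix(col, length(col), k) else matrix(numeric(0), length(col), 0)
  m_out <- cbind(rep_cols(m[, 1], pre), m, rep_cols(m[, L], post))
  v_out <- cbind(matrix(0, nrow(v), pre), v, matrix(0, nrow(v), post))
  e_out <- rbind(matrix(rep(e[1, ], each = pre), pre, 3), e,
                 matrix(rep(e[nrow(e), ], each = post), post, 3))
  list(m = m_out, v = v_out, e = e_out, onset = as.integer(onset))
}

# Integral of the norm of the discrete third derivative, summed over time:
# sum_t ||d^3 x / dt^3||_2 * dt. `x` is T x d.
.jerk_integral <- function(x, dt) {
  x <- as.matrix(x)
  if (nrow(x) < 4)
    stop_pt("need at least 4 frames for a third difference", "pt_shape_error")
  d3 <- diff(x, differences = 3) / dt^3
  sum(sqrt(rowSums(d3^2))) * dt
}

#' Joint-space jerk filter
#'
#' Scores a joint trajectory by the integral of joint-space jerk (the norm
#' of the third time derivative) and passes it when the score is below the
#' threshold, rejecting non-smooth arm movements.
#'
#' @param q_traj a `joint_trajectory` or T x 4 matrix (rad) with `dt`.
#' @param threshold pass threshold, default 1.
#' @param dt sampling interval when `q_traj` is a bare matrix.
#' @return list(pass = logical, score = numeric).
#' @export
joint_jerk_filter <- function(q_traj, threshold = 1, dt = NULL) {
  if (inherits(q_traj, "joint_trajectory")) {
    q <- q_traj$q; dt <- q_traj$dt
  } else q <- as.matrix(q_traj)
  if (is.null(dt)) stop_pt("dt required for a bare matrix", "pt_config_error")
  score <- .jerk_integral(q, dt)
  list(pass = score < threshold, score = score)
}

#' Muscle-space jerk score
#'
#' Defined analogously to the joint-space jerk over the 25-dimensional
#' muscle length trajectory; used to rank candidates for selection.
#'
#' @param m 25 x T muscle lengths (m).
#' @param dt sampling interval (s).
#' @return numeric score.
#' @export
muscle_jerk_score <- function(m, dt) .jerk_integral(t(m), dt)

#' Select a balanced, minimally jerky subset
#'
#' Per class, keeps the `n_total / n_classes` candidates with the smallest
#' muscle-space jerk; ties broken deterministically by sample id.
#'
#' @param candidates data.frame with columns `id`, `label`, `muscle_jerk`.
#' @param n_total total number of samples to retain (divisible by the
#'   number of classes).
#' @return the retained subset of `candidates` (row order: by class, then
#'   ascending jerk).
#' @export
select_balanced <- function(candidates, n_total) {
  classes <- sort(unique(as.character(candidates$label)))
  k <- n_total / length(classes)
  if (k != round(k))
    stop_pt("n_total must be divisible by the class count", "pt_config_error")
  picks <- lapply(classes, function(cl) {
    sub <- candidates[candidates$label == cl, ]
    if (nrow(sub) < k)
      stop_pt(sprintf("class '%s' has %d candidates, need %d",
                      cl, nrow(sub), k), "pt_insufficient_candidates")
    sub[order(sub$muscle_jerk, sub$id), ][seq_len(k), ]
  })
  do.call(rbind, picks)
}

#' Stratified train/validation/test split
#'
#' @param labels per-sample class labels.
#' @param ratios split fractions (train, validation, test), summing to 1.
#' @param seed integer seed; identical seeds give identical assignments.
#' @return factor of `"train"`, `"val"`, `"test"` per sample.
#' @export
split_dataset <- function(labels, ratios = c(0.72, 0.08, 0.20), seed = 1L) {
  if (any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-8)
    stop_pt("ratios must be positive and sum to 1", "pt_config_error")
  labels <- as.character(labels)
  out <- character(length(labels))
  set.seed(seed)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    n_tr <- round(n * ratios[1]); n_va <- round(n * ratios[2])
    if (n_tr + n_va >= n) {  # tiny class: keep at least one test sample
      n_va <- max(0, n - n_tr - 1)
      warning(sprintf("class '%s' too small for exact split ratios", cl))
    }
    out[idx[seq_len(n_tr)]] <- "train"
    if (n_va > 0) out[idx[n_tr + seq_len(n_va)]] <- "val"
    out[idx[(n_tr + n_va + 1):n]] <- "test"
  }
  factor(out, levels = c("train", "val", "test"))
}

#' @rdname generate_dataset
#' @param n_samples total retained samples (divisible by 20).
#' @param T_out input window length (samples), default 320 (4.8 s at
#'   66.7 Hz).
#' @param dt sampling interval (s), default 0.015.
#' @param box writing-grid side (cm), default 10.
#' @param noise_scale template control-point jitter (cm).
#' @param oversample candidate pool size as a multiple of `n_samples`.
#' @param jerk_threshold joint-space jerk pass threshold for candidates.
#' @param normalize standardize channels with training-split statistics.
#' @param arm an [arm_geometry()].
#' @param muscle a [muscle_geometry()].
#' @param augmentation an [augmentation_config()].
#' @param horizontal_offsets,vertical_offsets,inplane_u candidate plane and
#'   start-point grids (cm) passed to [compute_start_grid()].
#' @param ratios split ratios.
#' @export
dataset_config <- function(n_samples = 720, T_out = 320, dt = 0.015,
                           box = 10, noise_scale = 0.03, oversample = 1.7,
                           jerk_threshold = 300, normalize = TRUE,
                           arm = arm_geometry(),
                           muscle = default_muscle_geometry(),
                           augmentation = augmentation_config(),
                           horizontal_offsets = c(-6, -3, 0, 3, 6),
                           vertical_offsets = c(24, 27, 30, 33, 36),
                           inplane_u = seq(-12, 24, by = 3),
                           ratios = c(0.72, 0.08, 0.20)) {
  cfg <- list(n_samples = n_samples, T_out = T_out, dt = dt, box = box,
              noise_scale = noise_scale, oversample = oversample,
              jerk_threshold = jerk_threshold, normalize = normalize,
              arm = arm, muscle = muscle, augmentation = augmentation,
              horizontal_offsets = horizontal_offsets,
              vertical_offsets = vertical_offsets, inplane_u = inplane_u,
              ratios = ratios)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "dataset_config")
}

#' Hash a configuration object
#'
#' Deterministic content hash stamped into every artifact so outputs can
#' be traced back to the exact generator settings.
#'
#' @param cfg any serializable R object.
#' @return character hash.
#' @export
config_hash <- function(cfg) {
  cfg$hash <- NULL
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 10,
                                              vec.len = 1e6)), collapse = "\n")
  x <- utf8ToInt(s)
  h1 <- 0; h2 <- 0
  for (chunk in split(x, ceiling(seq_along(x) / 4096))) {
    h1 <- (h1 * 31 + sum(chunk * seq_along(chunk))) %% 2147483647
    h2 <- (h2 * 37 + sum(chunk * chunk)) %% 2147483629
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

#' Generate a proprioceptive character dataset
#'
#' Runs the full synthesis pipeline: sample base characters, draw
#' augmentation variants (affine, speed, plane, start point), solve the
#' sequential inverse kinematics, map to muscle lengths/velocities, filter
#' by joint-space jerk, keep a class-balanced minimally jerky subset, pad
#' to the input window with onset jitter, and split stratified 72-8-20.
#'
#' @param config a [dataset_config()].
#' @param seed master integer seed; the full generation is reproducible
#'   bit-for-bit under a fixed seed.
#' @param verbose print progress.
#' @return a `prop_dataset`: list with `inputs` (n x 25 x T x 2),
#'   `targets_e` (n x T x 3, m, shoulder frame), `labels` (factor),
#'   `manifest` (data.frame), `split` (factor), `normalizer`, `config`.
#' @export
generate_dataset <- function(config = dataset_config(), seed = 1L,
                             verbose = FALSE) {
  n_classes <- 20L
  n_cand <- ceiling(config$n_samples * config$oversample / n_classes) * n_classes
  per_class <- n_cand / n_classes

  base_seed <- derive_seed(seed, "charset")
  n_base <- max(2L, ceiling(per_class / 4))
  chars <- generate_synthetic_characters(n_base, config$noise_scale, base_seed)
  chars <- lapply(chars, rescale_and_resample, box = config$box, out_dt = config$dt)
  labels_base <- vapply(chars, `[[`, "", "label")

  planes <- compute_start_grid(
    config$arm, spacing = config$augmentation$grid_spacing,
    char_extent = config$box * max(config$augmentation$scales),
    horizontal_offsets = config$horizontal_offsets,
    vertical_offsets = config$vertical_offsets,
    inplane_u = config$inplane_u,
    orientations = config$augmentation$plane_orientations)
  if (!length(planes))
    stop_pt("no feasible start points in the configured workspace",
            "pt_config_error")
  if (verbose) message(length(planes), " feasible start points")

  set.seed(derive_seed(seed, "variants"))
  aug <- config$augmentation
  cand <- vector("list", n_cand)
  meta <- vector("list", n_cand)
  ci <- 0
  for (cl in character_classes()) {
    base_idx <- which(labels_base == cl)
    for (r in seq_len(per_class)) {
      ci <- ci + 1
      tr <- chars[[base_idx[1 + (r - 1) %% length(base_idx)]]]
      pars <- list(scale = sample(aug$scales, 1),
                   rotation = sample(aug$rotations, 1),
                   shear = sample(aug$shears, 1),
                   speed = sample(aug$speeds, 1),
                   plane = planes[[sample.int(length(planes), 1)]])
      v <- apply_affine(tr, pars$scale, pars$rotation, pars$shear)
      v <- time_warp(v, pars$speed)
      cand[[ci]] <- v
      meta[[ci]] <- pars
    }
  }

  # kinematics + muscles per candidate
  qn <- natural_pose(config$arm)
  rows <- vector("list", n_cand)
  kin <- vector("list", n_cand)
  n_ik_fail <- 0
  for (i in seq_len(n_cand)) {
    tr <- cand[[i]]; pars <- meta[[i]]
    e_cm <- place_in_plane(tr, pars$plane)
    res <- tryCatch({
      qt <- solve_trajectory_ik(e_cm / 100, config$arm, q_init = qn,
                                dt = config$dt)
      jj <- joint_jerk_filter(qt, threshold = config$jerk_threshold)
      if (!jj$pass) NULL else {
        m <- muscle_lengths(qt, config$muscle)
        list(q = qt, m = m, e = e_cm / 100, jj = jj$score,
             mj = muscle_jerk_score(m, config$dt))
      }
    }, pt_ik_infeasible = function(e) { n_ik_fail <<- n_ik_fail + 1; NULL })
    if (is.null(res)) next
    kin[[i]] <- res
    rows[[i]] <- data.frame(
      id = i, label = tr$label, scale = pars$scale, rotation = pars$rotation,
      shear = pars$shear, speed = pars$speed,
      plane = pars$plane$orientation, plane_offset = pars$plane$offset,
      start_x = pars$plane$start_point[1], start_y = pars$plane$start_point[2],
      start_z = pars$plane$start_point[3],
      joint_jerk = res$jj, muscle_jerk = res$mj,
      stringsAsFactors = FALSE)
  }
  pool <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (verbose)
    message(nrow(pool), " candidates pass filters (", n_ik_fail, " IK failures)")

  keep <- select_balanced(pool, config$n_samples)

  set.seed(derive_seed(seed, "padding"))
  n <- nrow(keep)
  n_mus <- length(config$muscle$names)
  inputs <- array(NA_real_, c(n, n_mus, config$T_out, 2))
  targets <- array(NA_real_, c(n, config$T_out, 3))
  onsets <- integer(n)
  for (j in seq_len(n)) {
    k <- kin[[keep$id[j]]]
    v <- muscle_velocities(k$m, config$dt)
    if (ncol(k$m) > config$T_out)
      stop_pt("movement longer than the input window; increase T_out",
              "pt_shape_error")
    pj <- pad_and_jitter(k$m, v, k$e, config$T_out)
    inputs[j, , , 1] <- pj$m
    inputs[j, , , 2] <- pj$v
    targets[j, , ] <- pj$e
    onsets[j] <- pj$onset
  }
  keep$onset <- onsets

  labels <- factor(keep$label, levels = character_classes())
  split <- split_dataset(labels, config$ratios, seed = derive_seed(seed, "split"))

  normalizer <- NULL
  if (config$normalize) {
    normalizer <- fit_channel_normalizer(inputs[split == "train", , , , drop = FALSE])
    inputs <- apply_normalizer(inputs, normalizer)
  }

  structure(list(inputs = inputs, targets_e = targets, labels = labels,
                 manifest = keep, split = split, normalizer = normalizer,
                 config = config, seed = seed),
            class = "prop_dataset")
}

#' @export
print.prop_dataset <- function(x, ...) {
  d <- dim(x$inputs)
  cat(sprintf("<prop_dataset: %d samples x %d muscles x %d time points x 2 channels>\n",
              d[1], d[2], d[3]))
  cat("  splits:", paste(sprintf("%s=%d", levels(x$split), table(x$split)),
                         collapse = ", "), "\n")
  cat("  config hash:", x$config$hash, "\n")
  invisible(x)
}

#' Position + velocity decoding targets
#'
#' Concatenated 3D position and 3D velocity per time point (6 channels),
#' each dimension min-max scaled by its range on the training split.
#'
#' @param ds a `prop_dataset`.
#' @return list with `targets` (n x T x 6) and the per-dimension `ranges`
#'   (2 x 6 matrix of min/max from the training split).
#' @export
tdt_pv_targets <- function(ds) {
  n <- dim(ds$targets_e)[1]; Tn <- dim(ds$targets_e)[2]
  vel <- array(0, c(n, Tn, 3))
  for (i in seq_len(n))
    vel[i, , ] <- finite_diff(ds$targets_e[i, , ], ds$config$dt)
  full <- array(c(ds$targets_e, vel), c(n, Tn, 6))
  tr <- which(ds$split == "train")
  ranges <- sapply(1:6, function(d) range(full[tr, , d]))
  for (d in 1:6) {
    span <- ranges[2, d] - ranges[1, d]
    if (span < 1e-12) span <- 1
    full[, , d] <- (full[, , d] - ranges[1, d]) / span
  }
  list(targets = full, ranges = ranges)
}

#' Write a dataset container
#'
#' Serializes the dataset to a single container file with a sidecar JSON
#' manifest carrying per-sample records, the split assignment, seeds, and
#' the generator config hash.
#'
#' @param ds a `prop_dataset`.
#' @param path output path (an `.rds` container; `<path>.manifest.json` is
#'   written alongside).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "prop_dataset"))
  payload <- unclass(ds)
  payload$.format_version <- 1L
  saveRDS(payload, path)
  manifest <- list(format_version = 1L, config_hash = ds$config$hash,
                   seed = ds$seed, n = dim(ds$inputs)[1],
                   split = as.character(ds$split),
                   samples = ds$manifest)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset container
#'
#' @param path path written by [write_dataset()].
#' @return a `prop_dataset`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path))
    stop_pt(sprintf("dataset container not found: %s", path), "pt_io_error")
  payload <- readRDS(path)
  ver <- payload$.format_version
  if (is.null(ver) || ver != 1L)
    stop_pt(sprintf("unsupported container version: %s", ver %||% "none"),
            "pt_format_error")
  payload$.format_version <- NULL
  structure(payload, class = "prop_dataset")
}
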