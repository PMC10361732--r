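# Model families, architecture search space, training schedule, and
# activation extraction.
#
# Three families process the 25 x T x 2 spindle input: spatial-temporal
# (1D convolutions across muscles, then 1D convolutions across time),
# spatiotemporal (2D convolutions across both), and LSTM (spatial
# convolutions followed by a recurrent layer). Every convolutional layer
# is conv -> layer normalization -> ReLU; a single fully connected layer
# reads out 20 logits (action recognition), 3 coordinates per time step
# (trajectory decoding) or 6 (position + velocity control task).

.net_families <- c("spatial-temporal", "spatiotemporal", "lstm")

#' Architecture specification
#'
#' @param family one of `"spatial-temporal"`, `"spatiotemporal"`, `"lstm"`.
#' @param spatial_filters filter counts per spatial (or 2D) layer,
#'   non-decreasing.
#' @param temporal_filters filter counts per temporal layer
#'   (spatial-temporal family only).
#' @param spatial_kernel,temporal_kernel kernel sizes (constant across
#'   layers).
#' @param spatial_stride,temporal_stride strides.
#' @param recurrent_units LSTM state size (lstm family only).
#' @param seed integer identifying the weight instantiation.
#' @return an `architecture_spec`.
#' @export
architecture_spec <- function(family, spatial_filters,
                              temporal_filters = integer(),
                              spatial_kernel = 7, temporal_kernel = 9,
                              spatial_stride = 2, temporal_stride = 3,
                              recurrent_units = 256, seed = 1L) {
  family <- match.arg(family, .net_families)
  filt <- c(spatial_filters, temporal_filters)
  if (any(diff(filt) < 0))
    stop_pt("filter counts must be non-decreasing along the hierarchy",
            "pt_config_error")
  structure(list(family = family,
                 spatial_filters = as.integer(spatial_filters),
                 temporal_filters = as.integer(temporal_filters),
                 spatial_kernel = as.integer(spatial_kernel),
                 temporal_kernel = as.integer(temporal_kernel),
                 spatial_stride = as.integer(spatial_stride),
                 temporal_stride = as.integer(temporal_stride),
                 recurrent_units = as.integer(recurrent_units),
                 seed = as.integer(seed)),
            class = "architecture_spec")
}

#' Sample a random architecture from the search grids
#'
#' Hyper-parameters are drawn independently from the search grids: layer
#' count 1-4 (per type; the spatial-temporal family stacks that many
#' spatial plus as many temporal layers, so 2-8 total), filter counts from
#' \{8, 16, 32, 64\} sorted so they never decrease along the hierarchy,
#' kernel sizes from \{3, 5, 7, 9\} (constant across layers), spatial
#' stride from \{1, 2\}, temporal stride from \{1, 2, 3\}, and 128 or 256
#' recurrent units for the LSTM family.
#'
#' @param family model family.
#' @param seed draw seed (also stored as the instantiation seed).
#' @return an [architecture_spec()].
#' @export
sample_architecture <- function(family = .net_families, seed = 1L) {
  family <- match.arg(family, .net_families)
  set.seed(seed)
  filt_grid <- c(8L, 16L, 32L, 64L)
  ksz <- c(3L, 5L, 7L, 9L)
  n_layers <- sample(1:4, 1)
  if (family == "spatial-temporal") {
    f_all <- sort(sample(filt_grid, 2 * n_layers, replace = TRUE))
    architecture_spec(family,
                      spatial_filters = f_all[seq_len(n_layers)],
                      temporal_filters = f_all[n_layers + seq_len(n_layers)],
                      spatial_kernel = sample(ksz, 1),
                      temporal_kernel = sample(ksz, 1),
                      spatial_stride = sample(1:2, 1),
                      temporal_stride = sample(1:3, 1),
                      seed = seed)
  } else if (family == "spatiotemporal") {
    k <- sample(ksz, 1); s <- sample(1:2, 1)
    architecture_spec(family,
                      spatial_filters = sort(sample(filt_grid, n_layers,
                                                    replace = TRUE)),
                      spatial_kernel = k, temporal_kernel = k,
                      spatial_stride = s, temporal_stride = s,
                      seed = seed)
  } else {
    architecture_spec(family,
                      spatial_filters = sort(sample(filt_grid, n_layers,
                                                    replace = TRUE)),
                      spatial_kernel = sample(ksz, 1), temporal_kernel = 1L,
                      spatial_stride = sample(1:2, 1), temporal_stride = 1L,
                      recurrent_units = sample(c(128L, 256L), 1),
                      seed = seed)
  }
}

#' Best-performing published architectures
#'
#' The architectures used as the basis of all single-unit and population
#' analyses, one per family.
#'
#' @return named list of [architecture_spec()] objects.
#' @export
best_architectures <- function() {
  list(
    "spatial-temporal" = architecture_spec(
      "spatial-temporal", spatial_filters = c(8, 16, 16, 32),
      temporal_filters = c(32, 32, 64, 64), spatial_kernel = 7,
      temporal_kernel = 9, spatial_stride = 2, temporal_stride = 3),
    "spatiotemporal" = architecture_spec(
      "spatiotemporal", spatial_filters = c(8, 8, 32, 64),
      spatial_kernel = 7, temporal_kernel = 7,
      spatial_stride = 2, temporal_stride = 2),
    "lstm" = architecture_spec(
      "lstm", spatial_filters = c(8, 16, 16), spatial_kernel = 3,
      temporal_kernel = 1, spatial_stride = 1, temporal_stride = 1,
      recurrent_units = 256)
  )
}

# Per-layer descriptors (type, kernel, stride, filters) for a spec.
.layer_plan <- function(spec) {
  plan <- list()
  if (spec$family == "spatial-temporal") {
    for (f in spec$spatial_filters)
      plan[[length(plan) + 1]] <- list(kind = "conv", kernel = c(spec$spatial_kernel, 1L),
                                       stride = c(spec$spatial_stride, 1L), filters = f)
    for (f in spec$temporal_filters)
      plan[[length(plan) + 1]] <- list(kind = "conv", kernel = c(1L, spec$temporal_kernel),
                                       stride = c(1L, spec$temporal_stride), filters = f)
  } else if (spec$family == "spatiotemporal") {
    for (f in spec$spatial_filters)
      plan[[length(plan) + 1]] <- list(kind = "conv",
                                       kernel = c(spec$spatial_kernel, spec$spatial_kernel),
                                       stride = c(spec$spatial_stride, spec$spatial_stride),
                                       filters = f)
  } else {
    for (f in spec$spatial_filters)
      plan[[length(plan) + 1]] <- list(kind = "conv", kernel = c(spec$spatial_kernel, 1L),
                                       stride = c(spec$spatial_stride, 1L), filters = f)
    plan[[length(plan) + 1]] <- list(kind = "lstm", units = spec$recurrent_units)
  }
  plan
}

#' Layer output shapes for an architecture
#'
#' @param spec an [architecture_spec()].
#' @param input_shape (muscles, time, channels), default c(25, 320, 2).
#' @return data.frame with layer name and spatial/temporal/filter sizes.
#' @export
layer_shapes <- function(spec, input_shape = c(25, 320, 2)) {
  S <- input_shape[1]; Tn <- input_shape[2]
  plan <- .layer_plan(spec)
  rows <- list(data.frame(layer = "Input", spatial = S, temporal = Tn,
                          filters = input_shape[3]))
  n_sp <- length(spec$spatial_filters)
  for (li in seq_along(plan)) {
    p <- plan[[li]]
    if (p$kind == "conv") {
      S <- conv_geom(S, p$kernel[1], p$stride[1])$out
      Tn <- conv_geom(Tn, p$kernel[2], p$stride[2])$out
      nm <- if (spec$family == "spatiotemporal") sprintf("STC%d", li - 1)
            else if (li <= n_sp) sprintf("SC%d", li - 1)
            else sprintf("TC%d", li - n_sp - 1)
      rows[[length(rows) + 1]] <- data.frame(layer = nm, spatial = S,
                                             temporal = Tn, filters = p$filters)
    } else {
      rows[[length(rows) + 1]] <- data.frame(layer = "R", spatial = 1,
                                             temporal = Tn, filters = p$units)
    }
  }
  do.call(rbind, rows)
}

#' Build a network from an architecture spec
#'
#' @param spec an [architecture_spec()].
#' @param head task head: `"art"` (20 logits), `"tdt"` (3 coordinates per
#'   kept time point) or `"tdt_pv"` (6 channels per kept time point).
#' @param input_shape (muscles, time, channels).
#' @param n_classes number of classes for the `art` head.
#' @param seed weight-initialization seed; defaults to the spec seed so a
#'   saved untrained instantiation can be re-created exactly.
#' @return a `prop_net` with untrained weights.
#' @export
build_network <- function(spec, head = c("art", "tdt", "tdt_pv"),
                          input_shape = c(25, 320, 2), n_classes = 20L,
                          seed = spec$seed) {
  head <- match.arg(head)
  plan <- .layer_plan(spec)
  set.seed(seed)
  S <- input_shape[1]; Tn <- input_shape[2]; C <- input_shape[3]
  time_centers <- seq_len(Tn)
  layers <- list()
  for (p in plan) {
    if (p$kind == "conv") {
      if (p$kernel[1] > 2 * S || p$kernel[2] > 2 * Tn)
        stop_pt("kernel exceeds the remaining extent; spec rejected",
                "pt_spec_rejected")
      fan_in <- p$kernel[1] * p$kernel[2] * C
      W <- matrix(stats::rnorm(fan_in * p$filters, 0, sqrt(2 / fan_in)),
                  fan_in, p$filters)
      gT <- conv_geom(Tn, p$kernel[2], p$stride[2])
      layers[[length(layers) + 1]] <- list(
        type = "conv", kernel = p$kernel, stride = p$stride,
        W = W, b = numeric(p$filters),
        gain = rep(1, p$filters), ln_bias = numeric(p$filters))
      S <- conv_geom(S, p$kernel[1], p$stride[1])$out
      time_centers <- time_centers[gT$centers]
      Tn <- gT$out; C <- p$filters
    } else {
      D <- S * C
      W <- matrix(stats::rnorm((D + p$units) * 4 * p$units, 0,
                               sqrt(1 / (D + p$units))), D + p$units, 4 * p$units)
      b <- numeric(4 * p$units)
      b[p$units + seq_len(p$units)] <- 1  # forget-gate bias
      layers[[length(layers) + 1]] <- list(type = "lstm", units = p$units,
                                           W = W, b = b)
      S <- 1L; C <- p$units
    }
  }
  out_dim <- switch(head, art = n_classes, tdt = 3L, tdt_pv = 6L)
  feat <- if (head == "art") S * Tn * C else S * C
  head_W <- matrix(stats::rnorm(feat * out_dim, 0, sqrt(1 / feat)), feat, out_dim)
  structure(list(spec = spec, head = head, layers = layers,
                 head_W = head_W, head_b = numeric(out_dim),
                 input_shape = input_shape, n_classes = n_classes,
                 out_shape = c(S, Tn, C), time_centers = time_centers,
                 init_seed = seed, trained = FALSE, history = NULL),
            class = "prop_net")
}

#' @export
print.prop_net <- function(x, ...) {
  cat(sprintf("<prop_net %s / %s head, %d layers, %s>\n", x$spec$family,
              x$head, length(x$layers),
              if (x$trained) "trained" else "untrained"))
  print(layer_shapes(x$spec, x$input_shape))
  invisible(x)
}

# Forward pass. Returns output plus per-layer caches (training) or
# post-ReLU activations (when collect = TRUE).
net_forward <- function(net, X, training = FALSE, collect = FALSE) {
  A <- X
  caches <- list(); acts <- list()
  for (li in seq_along(net$layers)) {
    ly <- net$layers[[li]]
    if (ly$type == "conv") {
      fw <- conv_forward(ly, A, training = training)
      A <- fw$out
      if (training) caches[[li]] <- fw$cache
    } else {
      d <- dim(A)  # (n, S, T, C) -> sequence (n, T, S*C)
      seqX <- array(aperm(A, c(1, 3, 2, 4)), c(d[1], d[3], d[2] * d[4]))
      fw <- lstm_forward(ly, seqX, training = training)
      A <- array(fw$out, c(d[1], dim(fw$out)[2], 1, ly$units))
      A <- aperm(A, c(1, 3, 2, 4))  # back to (n, S=1, T, C=units)
      if (training) caches[[li]] <- fw$cache
    }
    if (collect) acts[[li]] <- A
  }
  n <- dim(A)[1]
  if (net$head == "art") {
    feats <- A
    dim(feats) <- c(n, prod(dim(A)[-1]))
    out <- feats %*% net$head_W
    out <- out + matrix(net$head_b, n, ncol(out), byrow = TRUE)
  } else {
    d <- dim(A)  # per-time-step readout: (n*T, S*C)
    feats <- aperm(A, c(1, 3, 2, 4))
    dim(feats) <- c(n * d[3], d[2] * d[4])
    out <- feats %*% net$head_W
    out <- out + matrix(net$head_b, nrow(out), ncol(out), byrow = TRUE)
    dim(out) <- c(n, d[3], ncol(out))
  }
  list(out = out, caches = caches, acts = acts, feats = feats,
       final = A)
}

# Backward pass given the loss gradient at the head output.
net_backward <- function(net, fw, dout) {
  A <- fw$final
  d <- dim(A); n <- d[1]
  if (net$head == "art") {
    dfeats <- tcrossprod(dout, net$head_W)
    dW_head <- crossprod(fw$feats, dout)
    db_head <- colSums(dout)
    dA <- array(dfeats, d)
  } else {
    dout_m <- matrix(dout, n * d[3], dim(dout)[3])
    dW_head <- crossprod(fw$feats, dout_m)
    db_head <- colSums(dout_m)
    dfeats <- tcrossprod(dout_m, net$head_W)
    dA <- aperm(array(dfeats, c(n, d[3], d[2], d[4])), c(1, 3, 2, 4))
  }
  grads <- vector("list", length(net$layers))
  for (li in rev(seq_along(net$layers))) {
    ly <- net$layers[[li]]
    if (ly$type == "conv") {
      bw <- conv_backward(ly, dA, fw$caches[[li]])
    } else {
      dseq <- array(aperm(dA, c(1, 3, 2, 4)), c(n, dim(dA)[3], ly$units))
      bw <- lstm_backward(ly, dseq, fw$caches[[li]])
      dn <- dim(bw$dX)
      # sequence grad back to (n, S, T, C)
      S_prev <- dn[3] / .layer_channels(net, li - 1)
      bw$dX <- aperm(array(bw$dX, c(n, dn[2], S_prev, .layer_channels(net, li - 1))),
                     c(1, 3, 2, 4))
    }
    grads[[li]] <- bw$grads
    dA <- bw$dX
  }
  list(layer_grads = grads, head_W = dW_head, head_b = db_head)
}

.layer_channels <- function(net, li) {
  if (li == 0) return(net$input_shape[3])
  ly <- net$layers[[li]]
  if (ly$type == "conv") ncol(ly$W) else ly$units
}

# flatten / restore parameter lists for the optimizer
.collect_params <- function(net) {
  ps <- list()
  for (li in seq_along(net$layers)) {
    ly <- net$layers[[li]]
    keep <- if (ly$type == "conv") c("W", "b", "gain", "ln_bias") else c("W", "b")
    for (k in keep) ps[[sprintf("L%d.%s", li, k)]] <- ly[[k]]
  }
  ps$head_W <- net$head_W; ps$head_b <- net$head_b
  ps
}

.assign_params <- function(net, ps) {
  for (li in seq_along(net$layers)) {
    ly <- net$layers[[li]]
    keep <- if (ly$type == "conv") c("W", "b", "gain", "ln_bias") else c("W", "b")
    for (k in keep) net$layers[[li]][[k]] <- ps[[sprintf("L%d.%s", li, k)]]
  }
  net$head_W <- ps$head_W; net$head_b <- ps$head_b
  net
}

.grads_to_list <- function(net, bk) {
  gs <- list()
  for (li in seq_along(bk$layer_grads))
    for (k in names(bk$layer_grads[[li]]))
      gs[[sprintf("L%d.%s", li, k)]] <- bk$layer_grads[[li]][[k]]
  gs$head_W <- bk$head_W; gs$head_b <- bk$head_b
  gs
}

# Task targets aligned to the network's kept time points.
.task_targets <- function(net, ds, idx, task, pv = NULL) {
  if (task == "art") return(as.integer(ds$labels[idx]))
  tc <- net$time_centers
  if (task == "tdt") {
    tg <- ds$targets_e[idx, tc, , drop = FALSE]
  } else {
    tg <- pv$targets[idx, tc, , drop = FALSE]
  }
  tg
}

.batch_loss <- function(net, X, target, task) {
  fw <- net_forward(net, X, training = TRUE)
  if (task == "art") {
    ls <- softmax_xent(fw$out, target)
    list(loss = ls$loss, dout = ls$dlogits, fw = fw)
  } else {
    ls <- mse_loss(fw$out, target)
    list(loss = ls$loss, dout = ls$dpred, fw = fw)
  }
}

#' Train a network
#'
#' Adam (decay parameters 0.9 / 0.999) with an initial learning rate of
#' 5e-4 and batch size 256, minimizing softmax cross-entropy (action
#' recognition) or mean squared error (trajectory decoding). Validation
#' loss is monitored every epoch; when it fails to reach a new minimum for
#' five consecutive epochs the learning rate is divided by 4, and training
#' stops the second time the validation error saturates (or at
#' `max_epochs`).
#'
#' @param net a `prop_net` from [build_network()].
#' @param ds a `prop_dataset`.
#' @param task `"art"`, `"tdt"` or `"tdt_pv"` (must match the head).
#' @param lr initial learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs upper bound on epochs.
#' @param patience stall epochs before a saturation event.
#' @param seed shuffling seed.
#' @param verbose print per-epoch progress.
#' @return the trained `prop_net` with a `history` data.frame.
#' @export
train_network <- function(net, ds, task = net$head, lr = 5e-4,
                          batch_size = 256L, max_epochs = 40L,
                          patience = 5L, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(net, "prop_net"), inherits(ds, "prop_dataset"))
  if (task != net$head)
    stop_pt("task must match the network head", "pt_config_error")
  pv <- if (task == "tdt_pv") tdt_pv_targets(ds) else NULL
  tr_idx <- which(ds$split == "train")
  va_idx <- which(ds$split == "val")
  if (task != "art" && all(net$head_b == 0)) {
    # start the regression head at the training-target mean so early
    # updates model structure rather than the workspace offset
    tg <- .task_targets(net, ds, tr_idx, task, pv)
    net$head_b <- apply(tg, 3, mean)
  }
  params <- .collect_params(net)
  state <- adam_init(params)
  set.seed(seed)
  best_val <- Inf; stall <- 0L; saturations <- 0L; t_adam <- 0L
  hist <- list()
  for (epoch in seq_len(max_epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    ep_loss <- 0; nb <- 0
    for (b0 in seq(1, length(ord), by = batch_size)) {
      bidx <- ord[b0:min(b0 + batch_size - 1, length(ord))]
      X <- ds$inputs[bidx, , , , drop = FALSE]
      target <- .task_targets(net, ds, bidx, task, pv)
      net_tmp <- .assign_params(net, params)
      bl <- .batch_loss(net_tmp, X, target, task)
      if (!is.finite(bl$loss))
        stop_pt(sprintf("non-finite loss at epoch %d", epoch),
                "pt_training_diverged")
      bk <- net_backward(net_tmp, bl$fw, bl$dout)
      t_adam <- t_adam + 1L
      upd <- adam_step(params, .grads_to_list(net_tmp, bk), state, lr, t_adam)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + bl$loss; nb <- nb + 1
    }
    net <- .assign_params(net, params)
    # fall back to the train loss when the validation split is empty
    val_loss <- if (length(va_idx)) evaluate_loss(net, ds, va_idx, task, pv)
                else ep_loss / nb
    event <- ""
    if (val_loss < best_val) {
      best_val <- val_loss; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) {
        saturations <- saturations + 1L
        stall <- 0L
        if (saturations == 1L) {
          lr <- lr / 4
          event <- "lr_drop"
        } else event <- "stop"
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                val_loss = val_loss, lr = lr, event = event)
    if (verbose)
      message(sprintf("epoch %d train %.4f val %.4f lr %.2e %s", epoch,
                      ep_loss / nb, val_loss, lr, event))
    if (identical(event, "stop")) break
  }
  net$trained <- TRUE
  net$history <- do.call(rbind, hist)
  net
}

#' Evaluate the task loss on a subset
#'
#' @param net a `prop_net`.
#' @param ds a `prop_dataset`.
#' @param idx sample indices.
#' @param task task name.
#' @param pv precomputed [tdt_pv_targets()] when task is `tdt_pv`.
#' @param batch_size forward-pass chunk size.
#' @return mean loss.
#' @export
evaluate_loss <- function(net, ds, idx, task = net$head, pv = NULL,
                          batch_size = 256L) {
  if (!length(idx)) return(NA_real_)
  if (task == "tdt_pv" && is.null(pv)) pv <- tdt_pv_targets(ds)
  tot <- 0; n <- 0
  for (b0 in seq(1, length(idx), by = batch_size)) {
    bidx <- idx[b0:min(b0 + batch_size - 1, length(idx))]
    X <- ds$inputs[bidx, , , , drop = FALSE]
    fw <- net_forward(net, X)
    target <- .task_targets(net, ds, bidx, task, pv)
    l <- if (task == "art") softmax_xent(fw$out, target)$loss
         else mse_loss(fw$out, target)$loss
    tot <- tot + l * length(bidx); n <- n + length(bidx)
  }
  tot / n
}

#' Predict with a trained network
#'
#' @param object a `prop_net`.
#' @param inputs n x 25 x T x 2 array.
#' @param batch_size forward chunk size.
#' @param ... unused.
#' @return class labels (factor, art head) or an n x T_kept x d array of
#'   decoded outputs.
#' @export
predict.prop_net <- function(object, inputs, batch_size = 256L, ...) {
  n <- dim(inputs)[1]
  outs <- list()
  for (b0 in seq(1, n, by = batch_size)) {
    bidx <- b0:min(b0 + batch_size - 1, n)
    fw <- net_forward(object, inputs[bidx, , , , drop = FALSE])
    outs[[length(outs) + 1]] <- fw$out
  }
  if (object$head == "art") {
    logits <- do.call(rbind, outs)
    factor(character_classes()[max.col(logits, ties.method = "first")],
           levels = character_classes())
  } else {
    out <- array(0, c(n, dim(outs[[1]])[2], dim(outs[[1]])[3]))
    at <- 0
    for (o in outs) {
      out[at + seq_len(dim(o)[1]), , ] <- o
      at <- at + dim(o)[1]
    }
    out
  }
}

#' Classification accuracy on a dataset split
#'
#' @param net an art-head `prop_net`.
#' @param ds a `prop_dataset`.
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @return fraction of correctly classified samples.
#' @export
art_accuracy <- function(net, ds, split = "test") {
  idx <- which(ds$split == split)
  pred <- predict(net, ds$inputs[idx, , , , drop = FALSE])
  mean(as.character(pred) == as.character(ds$labels[idx]))
}

#' Mean Euclidean decoding error (cm) of a trajectory-decoding network
#'
#' @param net a tdt-head `prop_net`.
#' @param ds a `prop_dataset`.
#' @param split evaluation split.
#' @return mean 3D distance between decoded and true end-effector
#'   positions (cm) over samples and kept time points.
#' @export
tdt_error_cm <- function(net, ds, split = "test") {
  idx <- which(ds$split == split)
  pred <- predict(net, ds$inputs[idx, , , , drop = FALSE])
  truth <- ds$targets_e[idx, net$time_centers, , drop = FALSE]
  mean(sqrt(apply((pred - truth)^2, c(1, 2), sum))) * 100
}

#' Extract post-nonlinearity activations for a layer
#'
#' Activations are captured after the ReLU (or the LSTM hidden state) and
#' aligned to the input time grid: only the time points at the centers of
#' the units' receptive fields are kept.
#'
#' @param net a `prop_net`.
#' @param inputs n x 25 x T x 2 array.
#' @param layer layer index (1-based).
#' @param batch_size forward chunk size.
#' @return an `activation_tensor`: list with `act` (n x kept-times x
#'   units), `time_idx` (kept input time indices), `layer`, `n_units`.
#' @export
extract_activations <- function(net, inputs, layer, batch_size = 128L) {
  if (layer < 1 || layer > length(net$layers))
    stop_pt("no such layer", "pt_config_error")
  n <- dim(inputs)[1]
  acts <- NULL
  at <- 0
  for (b0 in seq(1, n, by = batch_size)) {
    bidx <- b0:min(b0 + batch_size - 1, n)
    fw <- net_forward(net, inputs[bidx, , , , drop = FALSE], collect = TRUE)
    A <- fw$acts[[layer]]           # (nb, S, T_l, C)
    d <- dim(A)
    Am <- array(aperm(A, c(1, 3, 2, 4)), c(d[1], d[3], d[2] * d[4]))
    if (is.null(acts)) acts <- array(0, c(n, d[3], d[2] * d[4]))
    acts[at + seq_len(d[1]), , ] <- Am
    at <- at + d[1]
  }
  tc <- .layer_time_centers(net, layer)
  structure(list(act = acts, time_idx = tc, layer = layer,
                 n_units = dim(acts)[3]),
            class = "activation_tensor")
}

# input-grid time indices corresponding to the kept time points of layer li
.layer_time_centers <- function(net, li) {
  tc <- seq_len(net$input_shape[2])
  for (j in seq_len(li)) {
    ly <- net$layers[[j]]
    if (ly$type == "conv") {
      g <- conv_geom(length(tc), ly$kernel[2], ly$stride[2])
      tc <- tc[g$centers]
    }
    # the LSTM keeps the full time resolution (its state at step t is
    # aligned to input time t)
  }
  tc
}
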