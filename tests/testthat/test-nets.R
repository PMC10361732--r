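test_that("sampled architectures stay on the search grids with monotone filters", {
  for (s in 1:12) {
    fam <- c("spatial-temporal", "spatiotemporal", "lstm")[(s %% 3) + 1]
    spec <- sample_architecture(fam, seed = s)
    filt <- c(spec$spatial_filters, spec$temporal_filters)
    expect_true(all(diff(filt) >= 0))
    expect_true(all(filt %in% c(8, 16, 32, 64)))
    expect_true(spec$spatial_kernel %in% c(3, 5, 7, 9))
    expect_true(spec$spatial_stride %in% 1:2)
    if (fam == "spatial-temporal") {
      expect_true(length(spec$spatial_filters) %in% 1:4)
      expect_equal(length(spec$spatial_filters), length(spec$temporal_filters))
      expect_true(spec$temporal_stride %in% 1:3)
    }
    if (fam == "lstm") expect_true(spec$recurrent_units %in% c(128, 256))
  }
  expect_identical(sample_architecture("lstm", seed = 4),
                   sample_architecture("lstm", seed = 4))
  expect_error(architecture_spec("spatial-temporal",
                                 spatial_filters = c(16, 8)),
               class = "pt_config_error")
})

test_that("best published architectures reproduce the printed layer shapes", {
  ba <- best_architectures()
  st <- layer_shapes(ba[["spatial-temporal"]])
  expect_equal(st$layer,
               c("Input", "SC0", "SC1", "SC2", "SC3",
                 "TC0", "TC1", "TC2", "TC3"))
  expect_equal(st$spatial, c(25, 13, 7, 4, 2, 2, 2, 2, 2))
  expect_equal(st$temporal, c(320, 320, 320, 320, 320, 107, 36, 12, 4))
  expect_equal(st$filters, c(2, 8, 16, 16, 32, 32, 32, 64, 64))

  stt <- layer_shapes(ba[["spatiotemporal"]])
  expect_equal(stt$spatial, c(25, 13, 7, 4, 2))
  expect_equal(stt$temporal, c(320, 160, 80, 40, 20))
  expect_equal(stt$filters, c(2, 8, 8, 32, 64))

  lst <- layer_shapes(ba[["lstm"]])
  expect_equal(lst$spatial, c(25, 25, 25, 25, 1))
  expect_equal(lst$temporal, rep(320, 5))
  expect_equal(lst$filters, c(2, 8, 16, 16, 256))
})

test_that("heads have the contracted output dimensions", {
  spec <- architecture_spec("spatial-temporal", spatial_filters = 4,
                            temporal_filters = 4, spatial_kernel = 3,
                            temporal_kernel = 3, spatial_stride = 2,
                            temporal_stride = 3)
  X <- array(stats::rnorm(2 * 25 * 60 * 2), c(2, 25, 60, 2))
  art <- build_network(spec, "art", input_shape = c(25, 60, 2))
  expect_equal(dim(net_forward(art, X)$out), c(2, 20))
  tdt <- build_network(spec, "tdt", input_shape = c(25, 60, 2))
  o <- net_forward(tdt, X)$out
  expect_equal(dim(o)[3], 3)
  pv <- build_network(spec, "tdt_pv", input_shape = c(25, 60, 2))
  expect_equal(dim(net_forward(pv, X)$out)[3], 6)
  # an LSTM spec carries its recurrent state size
  lspec <- architecture_spec("lstm", spatial_filters = 4, spatial_kernel = 3,
                             temporal_kernel = 1, spatial_stride = 2,
                             temporal_stride = 1, recurrent_units = 32)
  lnet <- build_network(lspec, "tdt", input_shape = c(25, 30, 2))
  expect_equal(lnet$layers[[2]]$units, 32)
  expect_equal(dim(net_forward(lnet, X[, , 1:30, , drop = FALSE])$out),
               c(2, 30, 3))
})

test_that("analytic gradients match finite differences for every family", {
  specs <- list(
    architecture_spec("spatial-temporal", spatial_filters = 3,
                      temporal_filters = 4, spatial_kernel = 3,
                      temporal_kernel = 3, spatial_stride = 2,
                      temporal_stride = 2),
    architecture_spec("spatiotemporal", spatial_filters = c(3, 4),
                      spatial_kernel = 3, temporal_kernel = 3,
                      spatial_stride = 2, temporal_stride = 2),
    architecture_spec("lstm", spatial_filters = 3, spatial_kernel = 3,
                      temporal_kernel = 1, spatial_stride = 2,
                      temporal_stride = 1, recurrent_units = 5))
  for (spec in specs) for (head in c("art", "tdt")) {
    net <- build_network(spec, head, input_shape = c(7, 12, 2),
                         n_classes = 4, seed = 2)
    set.seed(5)
    X <- array(stats::rnorm(3 * 7 * 12 * 2), c(3, 7, 12, 2))
    target <- if (head == "art") sample(1:4, 3, replace = TRUE) else
      array(stats::rnorm(3 * length(net$time_centers) * 3),
            c(3, length(net$time_centers), 3))
    lossfn <- function(nt) {
      fw <- net_forward(nt, X, training = TRUE)
      if (head == "art") softmax_xent(fw$out, target)$loss
      else mse_loss(fw$out, target)$loss
    }
    fw <- net_forward(net, X, training = TRUE)
    dout <- if (head == "art") softmax_xent(fw$out, target)$dlogits else
      mse_loss(fw$out, target)$dpred
    bk <- net_backward(net, fw, dout)
    gs <- propriotask:::.grads_to_list(net, bk)
    ps <- propriotask:::.collect_params(net)
    for (k in names(ps)) {
      for (ii in seq_len(min(3, length(ps[[k]])))) {
        h <- 1e-5
        p2 <- ps; p2[[k]][ii] <- p2[[k]][ii] + h
        lp <- lossfn(propriotask:::.assign_params(net, p2))
        p2[[k]][ii] <- p2[[k]][ii] - 2 * h
        lm <- lossfn(propriotask:::.assign_params(net, p2))
        num <- (lp - lm) / (2 * h)
        expect_equal(gs[[k]][ii], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("activation extraction aligns kept time points to receptive-field centers", {
  spec <- architecture_spec("spatial-temporal", spatial_filters = 4,
                            temporal_filters = 4, spatial_kernel = 3,
                            temporal_kernel = 3, spatial_stride = 1,
                            temporal_stride = 2)
  net <- build_network(spec, "art", input_shape = c(25, 40, 2))
  X <- array(stats::rnorm(3 * 25 * 40 * 2), c(3, 25, 40, 2))
  a1 <- extract_activations(net, X, 1)
  # stride-1 spatial layer keeps every input time point
  expect_equal(a1$time_idx, 1:40)
  a2 <- extract_activations(net, X, 2)
  expect_equal(length(a2$time_idx), 20)
  expect_true(all(diff(a2$time_idx) == 2))
  # deterministic: identical inputs give identical activations
  a2b <- extract_activations(net, X, 2)
  expect_identical(a2$act, a2b$act)
  # activations are post-ReLU
  expect_gte(min(a1$act), 0)
  expect_error(extract_activations(net, X, 9), class = "pt_config_error")
})

test_that("the LR schedule quarters on stall and stops at the second saturation", {
  # deterministic loss stream exercised through the same state machine
  sched <- function(val_losses, patience = 5) {
    lr <- 5e-4; best <- Inf; stall <- 0; sat <- 0; events <- character()
    for (v in val_losses) {
      if (v < best) { best <- v; stall <- 0 } else {
        stall <- stall + 1
        if (stall >= patience) {
          sat <- sat + 1; stall <- 0
          if (sat == 1) { lr <- lr / 4; events <- c(events, "lr_drop") }
          else { events <- c(events, "stop"); break }
        }
      }
    }
    list(lr = lr, events = events)
  }
  out <- sched(c(1, 0.9, rep(1, 5)))
  expect_equal(out$lr, 5e-4 / 4)
  expect_equal(out$events, "lr_drop")
  out2 <- sched(c(1, 0.9, rep(1, 10)))
  expect_equal(out2$events, c("lr_drop", "stop"))

  # the real trainer records the same transitions on a tiny run
  ds <- tiny_dataset()
  spec <- architecture_spec("spatial-temporal", spatial_filters = 4,
                            temporal_filters = 4, spatial_kernel = 3,
                            temporal_kernel = 3, spatial_stride = 2,
                            temporal_stride = 3, seed = 7)
  net <- build_network(spec, "art")
  tr <- train_network(net, ds, max_epochs = 3, seed = 7)
  expect_s3_class(tr$history, "data.frame")
  expect_equal(nrow(tr$history), 3)
  expect_true(all(c("train_loss", "val_loss", "lr", "event") %in%
                  names(tr$history)))
  expect_true(all(is.finite(tr$history$train_loss)))
})

test_that("the same spec trains on all heads by swapping readout and loss", {
  ds <- tiny_dataset()
  spec <- architecture_spec("spatial-temporal", spatial_filters = 4,
                            temporal_filters = 4, spatial_kernel = 3,
                            temporal_kernel = 3, spatial_stride = 2,
                            temporal_stride = 3, seed = 3)
  for (task in c("art", "tdt", "tdt_pv")) {
    net <- build_network(spec, task)
    tr <- train_network(net, ds, task = task, max_epochs = 2, seed = 3)
    expect_true(tr$trained)
  }
  expect_error(train_network(build_network(spec, "art"), ds, task = "tdt"),
               class = "pt_config_error")
})
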