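# Minimal neural-network engine used by the model families: 1D/2D
# convolutions (im2col, BLAS-backed), layer normalization, ReLU, an LSTM
# cell, softmax cross-entropy / MSE losses, and Adam. Activations are kept
# as (batch, space, time, channel) arrays throughout.

# --- convolution geometry ("same" zero padding, out = ceiling(in / stride))

conv_geom <- function(in_len, k, s) {
  out <- ceiling(in_len / s)
  pad_total <- max((out - 1) * s + k - in_len, 0)
  pad_beg <- pad_total %/% 2
  centers <- pmin(pmax((seq_len(out) - 1) * s - pad_beg + ceiling((k + 1) / 2),
                       1L), in_len)
  list(out = out, pad_beg = pad_beg, pad_total = pad_total, centers = centers)
}

# X: (n, S, T, C). Returns list(cols, geometry) where cols is
# (n*S_out*T_out) x (kS*kT*C) with column order (i over kS, j over kT, c).
# The data movement is compiled (src/conv_ops.cpp).
im2col <- function(X, kS, kT, sS, sT) {
  d <- dim(X)
  gS <- conv_geom(d[2], kS, sS); gT <- conv_geom(d[3], kT, sT)
  cols <- pt_im2col(X, d[1], d[2], d[3], d[4], kS, kT, sS, sT,
                    gS$out, gT$out, gS$pad_beg, gT$pad_beg)
  list(cols = cols, gS = gS, gT = gT, dims = d)
}

# Scatter-add column gradients back to the input array.
col2im <- function(dcols, kS, kT, sS, sT, geom) {
  d <- geom$dims
  pt_col2im(dcols, d[1], d[2], d[3], d[4], kS, kT, sS, sT,
            geom$gS$out, geom$gT$out, geom$gS$pad_beg, geom$gT$pad_beg)
}

# --- conv layer: conv -> layer norm -> ReLU

# Reshapes between (n*So*To, F) and (n, So*To*F) are zero-copy: the
# underlying column-major order (n fastest, then S_out, then T_out, then
# filter) is the same, so only the dim attribute changes.
# The (n*So*To, F) matmul output buffer and the (n, So*To*F) layer-norm
# view share one column-major layout, so the fused compiled kernel
# (src/conv_ops.cpp) operates on the buffer in place of any reshape.
conv_forward <- function(layer, X, training = TRUE) {
  k <- layer$kernel; s <- layer$stride
  ic <- im2col(X, k[1], k[2], s[1], s[2])
  Z <- ic$cols %*% layer$W
  n <- dim(X)[1]
  So <- ic$gS$out; To <- ic$gT$out; F <- ncol(layer$W)
  blk <- So * To
  if (any(layer$b != 0)) Z <- Z + rep(layer$b, each = nrow(Z))
  ln <- pt_ln_relu_fwd(Z, n, blk, F, layer$gain, layer$ln_bias)
  A <- ln$A
  dim(A) <- c(n, So, To, F)
  cache <- if (training) list(ic = ic, zh = ln$zh, inv_sd = ln$inv_sd,
                              A = ln$A, So = So, To = To, F = F)
           else list(So = So, To = To, F = F)
  list(out = A, cache = cache)
}

conv_backward <- function(layer, dA, cache) {
  n <- dim(dA)[1]; So <- cache$So; To <- cache$To; F <- cache$F
  blk <- So * To
  ln <- pt_ln_relu_bwd(dA, cache$A, cache$zh, cache$inv_sd, n, blk, F,
                       layer$gain)
  dZ <- ln$dZ
  dim(dZ) <- c(n * blk, F)
  dW <- crossprod(cache$ic$cols, dZ)
  db <- colSums(dZ)
  dcols <- tcrossprod(dZ, layer$W)
  dX <- col2im(dcols, layer$kernel[1], layer$kernel[2],
               layer$stride[1], layer$stride[2], cache$ic)
  list(dX = dX,
       grads = list(W = dW, b = db, gain = ln$dgain, ln_bias = ln$dbias))
}

# --- LSTM layer (batch-first sequences: X is (n, T, D))

lstm_forward <- function(layer, X, training = TRUE) {
  d <- dim(X); n <- d[1]; Tn <- d[2]; D <- d[3]
  H <- layer$units
  h <- matrix(0, n, H); c <- matrix(0, n, H)
  Hs <- array(0, c(n, Tn, H))
  cache <- if (training) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], n, D)
    z <- cbind(xt, h) %*% layer$W
    z <- z + matrix(layer$b, n, 4 * H, byrow = TRUE)
    i <- 1 / (1 + exp(-z[, 1:H, drop = FALSE]))
    f <- 1 / (1 + exp(-z[, H + 1:H, drop = FALSE]))
    g <- tanh(z[, 2 * H + 1:H, drop = FALSE])
    o <- 1 / (1 + exp(-z[, 3 * H + 1:H, drop = FALSE]))
    c_new <- f * c + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    if (training)
      cache[[t]] <- list(xt = xt, h_prev = h, c_prev = c, i = i, f = f,
                         g = g, o = o, tc = tc)
    h <- h_new; c <- c_new
    Hs[, t, ] <- h
  }
  list(out = Hs, cache = cache)
}

lstm_backward <- function(layer, dHs, cache) {
  d <- dim(dHs); n <- d[1]; Tn <- d[2]; H <- layer$units
  D <- ncol(cache[[1]]$xt)
  dW <- matrix(0, D + H, 4 * H); db <- numeric(4 * H)
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  dX <- array(0, c(n, Tn, D))
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dh <- matrix(dHs[, t, ], n, H) + dh_next
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    do <- dh * cc$tc
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    inp <- cbind(cc$xt, cc$h_prev)
    dW <- dW + crossprod(inp, dz)
    db <- db + colSums(dz)
    dinp <- tcrossprod(dz, layer$W)
    dX[, t, ] <- dinp[, seq_len(D), drop = FALSE]
    dh_next <- dinp[, D + seq_len(H), drop = FALSE]
    dc_next <- dc * cc$f
  }
  list(dX = dX, grads = list(W = dW, b = db))
}

# --- losses

softmax_xent <- function(logits, y_idx) {
  n <- nrow(logits)
  m <- logits[, 1]
  for (j in seq_len(ncol(logits))[-1]) m <- pmax(m, logits[, j])
  ez <- exp(logits - m)
  p <- ez / rowSums(ez)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), y_idx)] + eps))
  dlogits <- p
  dlogits[cbind(seq_len(n), y_idx)] <- dlogits[cbind(seq_len(n), y_idx)] - 1
  list(loss = loss, dlogits = dlogits / n, p = p)
}

mse_loss <- function(pred, target) {
  r <- pred - target
  list(loss = mean(r * r), dpred = 2 * r / length(r))
}

# --- Adam

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (k in names(params)) {
    g <- grads[[k]]
    state[[k]]$m <- beta1 * state[[k]]$m + (1 - beta1) * g
    state[[k]]$v <- beta2 * state[[k]]$v + (1 - beta2) * g * g
    mhat <- state[[k]]$m / (1 - beta1^t)
    vhat <- state[[k]]$v / (1 - beta2^t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
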