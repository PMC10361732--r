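# Non-neural reference models: pairwise linear SVMs with one-against-one
# voting for character recognition, and a linear map for end-effector
# decoding.

#' Flatten dataset inputs into per-sample feature vectors
#'
#' Concatenates muscles x time x channels, optionally keeping every
#' `subsample`-th time point (the full 25 x 320 x 2 flattening is large;
#' temporal subsampling preserves the slow kinematics).
#'
#' @param ds a `prop_dataset`.
#' @param representation which representation to expose: proprioceptive
#'   inputs (default), muscle lengths only, joint angles are not stored
#'   per sample so `"endeffector"` uses the decoding targets.
#' @param subsample temporal subsampling stride, default 8.
#' @return n x p feature matrix.
#' @export
flatten_inputs <- function(ds, representation = c("proprio", "muscles",
                                                  "endeffector"),
                           subsample = 8L) {
  representation <- match.arg(representation)
  keep_t <- seq(1, dim(ds$inputs)[3], by = subsample)
  x <- switch(representation,
    proprio = ds$inputs[, , keep_t, , drop = FALSE],
    muscles = ds$inputs[, , keep_t, 1, drop = FALSE],
    endeffector = ds$targets_e[, keep_t, , drop = FALSE])
  matrix(x, dim(x)[1], prod(dim(x)[-1]))
}

#' Train all pairwise SVM classifiers
#'
#' One linear max-margin (hinge loss) classifier per unordered class pair,
#' selected by cross-validation over nine regularization constants spaced
#' logarithmically between 1e-4 and 1e4.
#'
#' @param X n x p feature matrix.
#' @param y class labels (factor or character).
#' @param costs regularization grid; default `10^seq(-4, 4)`.
#' @param folds cross-validation folds for the grid search.
#' @param cv skip the grid search and use cost 1 when `FALSE` (fast path).
#' @param seed fold-assignment seed.
#' @return a `pairwise_svms` object: list of classifiers indexed by pair.
#' @export
train_pairwise_svms <- function(X, y, costs = 10^seq(-4, 4), folds = 3L,
                                cv = TRUE, seed = 1L) {
  y <- factor(y)
  classes <- levels(y)[table(y)[levels(y)] > 0]
  if (any(table(y)[classes] < 2))
    stop_pt("every class needs at least 2 samples", "pt_config_error")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  set.seed(seed)
  fits <- lapply(pairs, function(pr) {
    idx <- which(y %in% pr)
    yy <- factor(as.character(y[idx]), levels = pr)
    xx <- X[idx, , drop = FALSE]
    cost <- 1
    if (cv && length(costs) > 1) {
      fold <- sample(rep_len(seq_len(folds), length(idx)))
      acc <- vapply(costs, function(cc) {
        mean(vapply(seq_len(folds), function(fd) {
          tr <- fold != fd
          if (length(unique(yy[tr])) < 2 || !any(!tr)) return(NA_real_)
          fit <- e1071::svm(xx[tr, , drop = FALSE], yy[tr], kernel = "linear",
                            cost = cc, scale = FALSE)
          mean(predict(fit, xx[!tr, , drop = FALSE]) == yy[!tr])
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1))
      cost <- costs[which.max(acc)]
    }
    fit <- e1071::svm(xx, yy, kernel = "linear", cost = cost, scale = FALSE)
    list(pair = pr, fit = fit, cost = cost)
  })
  structure(list(fits = fits, classes = classes), class = "pairwise_svms")
}

#' One-against-one prediction
#'
#' Voting over all pairwise classifiers, informed by their confidences:
#' each pair casts one vote for its predicted side, and the bounded
#' (squashed) decision values break ties between equally voted classes —
#' an unscaled confidence sum would let pairs not involving the true
#' class dominate with large arbitrary margins. Remaining ties go to the
#' first class in class order.
#'
#' @param model a `pairwise_svms`.
#' @param X n x p feature matrix.
#' @return factor of predicted labels.
#' @export
ovo_predict <- function(model, X) {
  classes <- model$classes
  scores <- matrix(0, nrow(X), length(classes),
                   dimnames = list(NULL, classes))
  tie_scale <- 1 / (4 * length(model$fits))  # total tie-break mass < 1 vote
  for (cl in model$fits) {
    dv <- attr(predict(cl$fit, X, decision.values = TRUE), "decision.values")
    d <- as.numeric(dv)
    # the decision-value column name "a/b" states its orientation: positive
    # values favor the class before the slash (libsvm orders classes by
    # appearance in the training data, not by factor levels)
    orient <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
    conf <- tanh(d) * tie_scale
    scores[, orient[1]] <- scores[, orient[1]] + (d > 0) + conf
    scores[, orient[2]] <- scores[, orient[2]] + (d <= 0) - conf
  }
  factor(classes[max.col(scores, ties.method = "first")], levels = classes)
}

#' Pairwise and multi-class SVM accuracy summary
#'
#' @param model a `pairwise_svms`.
#' @param X test features.
#' @param y test labels.
#' @return list with `multiclass_accuracy`, per-pair accuracies
#'   (`pair_accuracy` data.frame), and the number of pairs.
#' @export
svm_accuracy <- function(model, X, y) {
  y <- factor(y, levels = model$classes)
  pred <- ovo_predict(model, X)
  pair_acc <- do.call(rbind, lapply(model$fits, function(cl) {
    idx <- which(y %in% cl$pair)
    acc <- if (length(idx)) {
      yy <- factor(as.character(y[idx]), levels = cl$pair)
      mean(predict(cl$fit, X[idx, , drop = FALSE]) == yy)
    } else NA_real_
    data.frame(a = cl$pair[1], b = cl$pair[2], accuracy = acc)
  }))
  list(multiclass_accuracy = mean(pred == y, na.rm = TRUE),
       pair_accuracy = pair_acc, n_pairs = length(model$fits))
}

#' Standard scaler (fit)
#'
#' @param X n x p matrix.
#' @param eps variance floor guarding degenerate features.
#' @return `standard_scaler` with mean and sd per feature.
#' @export
fit_scaler <- function(X, eps = 1e-8) {
  mu <- colMeans(X)
  sd <- sqrt(pmax(colMeans(X^2) - mu^2, 0))
  sd[sd < eps] <- 1
  structure(list(mean = mu, sd = sd), class = "standard_scaler")
}

#' @rdname fit_scaler
#' @param scaler a `standard_scaler`.
#' @param inverse undo the transform.
#' @export
apply_scaler <- function(X, scaler, inverse = FALSE) {
  if (inverse)
    sweep(sweep(X, 2, scaler$sd, `*`), 2, scaler$mean, `+`)
  else
    sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, `/`)
}

#' Linear end-effector position decoder
#'
#' A single linear map from the per-time-step proprioceptive input (all
#' muscles, both channels) to the 3D end-effector position at that step,
#' fit by ordinary least squares on standard-scaled features and targets
#' (all training samples and time steps pooled). The reported error is
#' the mean Euclidean distance between predicted and true positions, in
#' cm.
#'
#' @param ds a `prop_dataset`.
#' @param train_idx,test_idx sample indices; default the dataset's train
#'   and test splits.
#' @return list with the fitted `coef`, scalers, and `test_error_cm`.
#' @export
linear_position_decoder <- function(ds,
                                    train_idx = which(ds$split == "train"),
                                    test_idx = which(ds$split == "test")) {
  step_features <- function(idx) {
    x <- ds$inputs[idx, , , , drop = FALSE]
    d <- dim(x)  # (n, muscles, T, 2) -> rows (n*T) x (muscles*2)
    xm <- aperm(x, c(1, 3, 2, 4))
    dim(xm) <- c(d[1] * d[3], d[2] * d[4])
    xm
  }
  step_targets <- function(idx) {
    e <- ds$targets_e[idx, , , drop = FALSE]
    d <- dim(e)
    dim(e) <- c(d[1] * d[2], 3)
    e
  }
  Xtr <- step_features(train_idx); Ytr <- step_targets(train_idx)
  sx <- fit_scaler(Xtr); sy <- fit_scaler(Ytr)
  Xs <- apply_scaler(Xtr, sx); Ys <- apply_scaler(Ytr, sy)
  beta <- stats::lm.fit(cbind(1, Xs), Ys)$coefficients
  beta[is.na(beta)] <- 0
  Xte <- apply_scaler(step_features(test_idx), sx)
  pred <- apply_scaler(cbind(1, Xte) %*% beta, sy, inverse = TRUE)
  truth <- step_targets(test_idx)
  err <- mean(sqrt(rowSums((pred - truth)^2))) * 100
  list(coef = beta, scaler_x = sx, scaler_y = sy, test_error_cm = err)
}
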