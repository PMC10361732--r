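test_that("pairwise SVM training builds one classifier per unordered pair", {
  set.seed(2)
  # separable 4-class toy problem
  n <- 15
  X <- rbind(cbind(stats::rnorm(n, 0), stats::rnorm(n, 0)),
             cbind(stats::rnorm(n, 4), stats::rnorm(n, 4)),
             cbind(stats::rnorm(n, 0), stats::rnorm(n, 8)),
             cbind(stats::rnorm(n, 8), stats::rnorm(n, 0)))
  y <- rep(letters[1:4], each = n)
  m <- train_pairwise_svms(X, y, cv = FALSE)
  expect_length(m$fits, choose(4, 2))
  acc <- svm_accuracy(m, X, y)
  expect_equal(acc$n_pairs, 6)
  expect_gt(acc$multiclass_accuracy, 0.95)
  expect_true(all(acc$pair_accuracy$accuracy > 0.9))

  # linearly separable two-class set trains to perfection and reduces
  # one-against-one voting to the single classifier's sign
  X2 <- X[1:(2 * n), ]; y2 <- y[1:(2 * n)]
  m2 <- train_pairwise_svms(X2, y2, cv = FALSE)
  expect_length(m2$fits, 1)
  pred <- ovo_predict(m2, X2)
  expect_equal(mean(pred == y2), 1)
  direct <- predict(m2$fits[[1]]$fit, X2)
  expect_equal(as.character(pred), as.character(direct))

  expect_error(train_pairwise_svms(X[1:16, ], rep(c("a", "b"), c(15, 1))),
               class = "pt_config_error")
})

test_that("the regularization grid is the nine-point log scale", {
  grid <- eval(formals(train_pairwise_svms)$costs)
  expect_length(grid, 9)
  expect_equal(grid[1], 1e-4)
  expect_equal(grid[9], 1e4)
  expect_equal(diff(log10(grid)), rep(1, 8))
})

test_that("cross-validated cost selection runs and is deterministic", {
  set.seed(9)
  X <- rbind(matrix(stats::rnorm(40, 0, 2), 20, 2),
             matrix(stats::rnorm(40, 3, 2), 20, 2))
  y <- rep(c("a", "b"), each = 20)
  m1 <- train_pairwise_svms(X, y, costs = 10^c(-2, 0, 2), seed = 5)
  m2 <- train_pairwise_svms(X, y, costs = 10^c(-2, 0, 2), seed = 5)
  expect_identical(m1$fits[[1]]$cost, m2$fits[[1]]$cost)
  expect_true(m1$fits[[1]]$cost %in% 10^c(-2, 0, 2))
})

test_that("the scaler round-trips and guards degenerate features", {
  set.seed(1)
  X <- cbind(stats::rnorm(50, 3, 2), stats::rnorm(50, -1, 0.5), rep(2, 50))
  sc <- fit_scaler(X)
  Z <- apply_scaler(X, sc)
  expect_equal(apply_scaler(Z, sc, inverse = TRUE), X, tolerance = 1e-12)
  expect_equal(colMeans(Z)[1:2], c(0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant feature: unit sd fallback, no NaN
  expect_false(anyNA(Z))
})

test_that("the linear position decoder recovers linear targets and regresses to the mean otherwise", {
  ds <- tiny_dataset()
  lin <- linear_position_decoder(ds)
  expect_true(is.finite(lin$test_error_cm))
  expect_gt(lin$test_error_cm, 0)

  # targets exactly linear in the inputs: error collapses toward zero
  ds2 <- ds
  n <- dim(ds2$inputs)[1]; Tn <- dim(ds2$inputs)[3]
  W <- matrix(stats::rnorm(50 * 3, 0, 0.05), 50, 3)
  for (i in seq_len(n)) {
    # per-step feature rows (T x 50): muscles x channels at each time step
    f <- matrix(aperm(ds2$inputs[i, , , , drop = FALSE], c(1, 3, 2, 4)),
                Tn, 50)
    ds2$targets_e[i, , ] <- f %*% W
  }
  lin2 <- linear_position_decoder(ds2)
  expect_lt(lin2$test_error_cm, 1e-6 * 100)

  # targets independent of the inputs: error approaches the mean predictor
  ds3 <- ds
  set.seed(4)
  const <- matrix(stats::rnorm(n * 3, 0, 0.05), n, 3)
  for (i in seq_len(n)) ds3$targets_e[i, , ] <-
    matrix(const[i, ], Tn, 3, byrow = TRUE)
  lin3 <- linear_position_decoder(ds3)
  te <- which(ds3$split == "test")
  mu <- colMeans(ds3$targets_e[which(ds3$split == "train"), 1, ])
  base_err <- mean(sqrt(rowSums(sweep(const[te, ], 2, mu)^2))) * 100
  expect_lt(abs(lin3$test_error_cm - base_err) / base_err, 0.5)
})

test_that("input flattening exposes the alternative representations", {
  ds <- tiny_dataset()
  fp <- flatten_inputs(ds, "proprio", subsample = 8)
  expect_equal(ncol(fp), 25 * 40 * 2)
  fm <- flatten_inputs(ds, "muscles", subsample = 8)
  expect_equal(ncol(fm), 25 * 40)
  fe <- flatten_inputs(ds, "endeffector", subsample = 8)
  expect_equal(ncol(fe), 40 * 3)
  expect_equal(nrow(fp), dim(ds$inputs)[1])
})
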