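test_that("linear CKA matches the brute-force HSIC formula and its invariances", {
  set.seed(4)
  X <- matrix(stats::rnorm(20 * 5), 20, 5)
  Y <- matrix(stats::rnorm(20 * 7), 20, 7)
  # brute force via centered Gram matrices
  H <- diag(20) - matrix(1 / 20, 20, 20)
  K <- H %*% tcrossprod(X) %*% H
  L <- H %*% tcrossprod(Y) %*% H
  hsic <- function(A, B) sum(A * B)
  brute <- hsic(K, L) / sqrt(hsic(K, K) * hsic(L, L))
  expect_equal(linear_cka(X, Y), brute, tolerance = 1e-10)

  expect_equal(linear_cka(X, X), 1, tolerance = 1e-12)
  Q <- qr.Q(qr(matrix(stats::rnorm(25), 5, 5)))
  expect_equal(linear_cka(X, X %*% Q), 1, tolerance = 1e-10)
  expect_equal(linear_cka(X, 3 * X), 1, tolerance = 1e-12)

  set.seed(5)
  A <- matrix(stats::rnorm(500 * 20), 500, 20)
  B <- matrix(stats::rnorm(500 * 20), 500, 20)
  expect_lt(linear_cka(A, B), 0.1)
  expect_error(linear_cka(matrix(1, 10, 3), B[1:10, ]),
               class = "pt_config_error")
})

test_that("RDMs are correlation distances with the contracted extremes", {
  v <- stats::rnorm(30)
  feats <- rbind(v, v + 0, -v, stats::rnorm(30))
  rdm <- compute_rdm(feats)
  expect_equal(dim(rdm), c(4, 4))
  expect_true(all(abs(rdm - t(rdm)) < 1e-12))
  expect_true(all(diag(rdm) == 0))
  expect_equal(rdm[1, 2], 0, tolerance = 1e-12)  # duplicated stimulus
  expect_equal(rdm[1, 3], 2, tolerance = 1e-12)  # anti-correlated
  expect_true(all(rdm >= -1e-12 & rdm <= 2 + 1e-12))
  pct <- compute_rdm(feats, percentile = TRUE)
  expect_equal(max(pct), 100)
  expect_error(compute_rdm(rbind(rep(1, 30), v)), class = "pt_config_error")
})

test_that("oracle similarity ranks block structure correctly", {
  labels <- rep(letters[1:4], each = 5)
  oracle <- 1 - outer(labels, labels, `==`)
  diag(oracle) <- 0
  expect_equal(oracle_similarity(oracle, labels), 1)
  # graded class structure (within < between uniformly) is positive
  set.seed(2)
  graded <- oracle * 0.5 + 0.2 + matrix(stats::runif(400, 0, 0.1), 20)
  graded <- (graded + t(graded)) / 2; diag(graded) <- 0
  expect_gt(oracle_similarity(graded, labels), 0.5)
  # label permutation destroys the alignment on average
  set.seed(7)
  sims <- replicate(30, oracle_similarity(graded, sample(labels)))
  expect_lt(abs(mean(sims)), 0.15)
  expect_error(oracle_similarity(oracle, rep("a", 20)),
               class = "pt_config_error")
})

test_that("the t-SNE protocol returns reproducible 2D embeddings", {
  set.seed(11)
  X <- rbind(matrix(stats::rnorm(60 * 5), 60, 5),
             matrix(stats::rnorm(60 * 5, mean = 6), 60, 5))
  em <- embed_tsne(X, perplexity = 12, n_iter = 60, seed = 3)
  expect_equal(dim(em$coords), c(120, 2))
  em2 <- embed_tsne(X, perplexity = 12, n_iter = 60, seed = 3)
  expect_identical(em$coords, em2$coords)
  # well-separated clusters stay separated in the embedding
  d_within <- mean(dist(em$coords[1:60, ]))
  d_across <- mean(as.matrix(dist(em$coords))[1:60, 61:120])
  expect_gt(d_across, d_within)
  # the PCA stage reports its retained variance on wide data
  W <- matrix(stats::rnorm(80 * 120), 80, 120)
  em3 <- embed_tsne(W, perplexity = 10, n_iter = 5, n_pca = 50, seed = 1)
  expect_true(em3$pca_variance > 0 && em3$pca_variance <= 1)
})

test_that("ridge population decoding matches the closed form and scores sanely", {
  set.seed(6)
  X <- matrix(stats::rnorm(10 * 3), 10, 3)
  y <- stats::rnorm(10)
  # closed form (X'X + I)^-1 X'y on the centered training rows
  set.seed(1)
  tr_rows <- sample(1:10, 8)
  Xt <- X[tr_rows, ]; yt <- y[tr_rows]
  Xc <- sweep(Xt, 2, colMeans(Xt)); yc <- yt - mean(yt)
  beta <- solve(crossprod(Xc) + diag(1, 3), crossprod(Xc, yc))
  fit <- population_decode(X, y, seed = 1)
  expect_equal(unname(fit$coef), unname(beta), tolerance = 1e-10)

  # decoding a unit from itself approaches R^2 = 1
  set.seed(8)
  U <- matrix(stats::rnorm(400 * 6), 400, 6)
  tr <- rep(1:40, each = 10)
  out <- population_decode(U, U[, 2], traj = tr, seed = 2)
  expect_gt(out$r2, 0.99)
  # shuffled targets decode at or below chance
  out2 <- population_decode(U, sample(U[, 2]), traj = tr, seed = 2)
  expect_lt(out2$r2, 0.1)
  # joint XY targets report a Euclidean error
  outxy <- population_decode(U, U[, 1:2] + stats::rnorm(800, 0, 0.01),
                             traj = tr, seed = 2)
  expect_true(is.finite(outxy$error_cm))
  expect_error(population_decode(U, U[1:10, 2], traj = tr),
               class = "pt_shape_error")
})

test_that("preferred-direction uniformity metric has its analytic values", {
  # exactly uniform: one unit per bin
  centers <- seq(-pi + pi / 18, pi, by = 2 * pi / 18)
  expect_equal(pd_uniformity(centers), 0)
  expect_equal(pd_uniformity(rep(centers, 3)), 0)
  # all units in one bin: ((n - n/18) + 17 * n/18) / n = 17/9
  expect_equal(pd_uniformity(rep(0.1, 36)), 17 / 9)
  expect_equal(pd_uniformity(rep(0.1, 7)), 17 / 9)
  # invariant to rotation by a whole number of bins
  expect_equal(pd_uniformity(centers + 2 * pi / 18),
               pd_uniformity(centers))
  # moving a unit from an over-full bin to an under-full (empty) bin
  # strictly lowers the metric
  pds <- c(rep(0.1, 4), 1.2, 2.0)
  pds_moved <- c(rep(0.1, 3), -2.5, 1.2, 2.0)
  expect_lt(pd_uniformity(pds_moved), pd_uniformity(pds))
  expect_error(pd_uniformity(numeric()), class = "pt_config_error")
  h <- pd_histogram(centers)
  expect_length(h$counts, 18)
  expect_equal(sum(h$counts), length(centers))
})

test_that("preferred-direction invariance uses circular differences across planes", {
  base <- data.frame(unit = 1:6, theta_pd = seq(-2, 2, length.out = 6),
                     test_r2 = 0.5)
  same <- list(`0` = base, `3` = base, `6` = base)
  expect_equal(pd_invariance(same, "0"), 0)
  rot <- base; rot$theta_pd <- wrap_angle(base$theta_pd + 0.3)
  expect_equal(pd_invariance(list(`0` = base, `3` = rot), "0"), 0.3,
               tolerance = 1e-12)
  # wrap-around: +179 vs -179 degrees differ by 2 degrees
  a <- data.frame(unit = 1:3, theta_pd = c(179, 0, 90) * pi / 180,
                  test_r2 = 0.5)
  b <- data.frame(unit = 1:3, theta_pd = c(-179, 0, 90) * pi / 180,
                  test_r2 = 0.5)
  expect_equal(pd_invariance(list(`0` = a, `3` = b), "0"),
               (2 * pi / 180) / 3, tolerance = 1e-12)
  # planes with fewer than three tuned units are excluded
  weak <- base; weak$test_r2 <- c(0.5, 0.5, rep(0, 4))
  expect_true(is.na(pd_invariance(list(`0` = base, `3` = weak), "0")))
  expect_error(pd_invariance(list(`3` = base), "0"), class = "pt_config_error")
})

test_that("paired tests report df = n - 1 and flag degenerate differences", {
  a <- c(1.2, 1.4, 1.1, 1.6, 1.3)
  b <- c(1.0, 1.1, 0.9, 1.2, 1.05)
  out <- paired_ttest(a, b)
  expect_equal(out$df, 4)
  expect_false(out$degenerate)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(out$t, unname(ref$statistic))
  expect_equal(out$p, ref$p.value)
  expect_true(paired_ttest(a, a)$degenerate)
  expect_equal(paired_ttest(a, a)$t, 0)
  expect_true(paired_ttest(a, a - 1)$degenerate)
  expect_error(paired_ttest(a, b[1:3]), class = "pt_config_error")
})
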