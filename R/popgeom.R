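# Population-level comparisons: centered kernel alignment, representational
# dissimilarity matrices and oracle similarity, a low-dimensional t-SNE
# embedding protocol, population decoding, preferred-direction uniformity
# and cross-plane invariance, and paired significance tests.

#' Linear centered kernel alignment
#'
#' CKA between two activation matrices over the same stimuli; invariant
#' to orthogonal transformations and isotropic scaling of either
#' representation.
#'
#' @param X,Y samples x features matrices (equal row counts).
#' @return similarity in [0, 1].
#' @export
linear_cka <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop_pt("X and Y must have the same number of samples", "pt_shape_error")
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  nx <- sum(crossprod(Xc)^2)
  ny <- sum(crossprod(Yc)^2)
  if (nx < 1e-24 || ny < 1e-24)
    stop_pt("zero-variance input to CKA", "pt_config_error")
  sum(crossprod(Yc, Xc)^2) / sqrt(nx * ny)
}

#' Representational dissimilarity matrix
#'
#' Correlation distance (1 - Pearson correlation) between the feature
#' vectors of every stimulus pair.
#'
#' @param features stimuli x features matrix.
#' @param percentile return percentile-transformed entries (for
#'   visualization) instead of raw distances.
#' @return an `rd_matrix`: symmetric matrix, zero diagonal, entries in
#'   [0, 2].
#' @export
compute_rdm <- function(features, percentile = FALSE) {
  features <- as.matrix(features)
  if (nrow(features) < 2)
    stop_pt("need at least 2 stimuli", "pt_config_error")
  sds <- apply(features, 1, stats::sd)
  if (any(sds < 1e-15))
    stop_pt("constant feature vector: correlation distance undefined",
            "pt_config_error")
  rdm <- 1 - stats::cor(t(features))
  diag(rdm) <- 0
  if (percentile) {
    ut <- upper.tri(rdm)
    ranks <- rank(rdm[ut], ties.method = "max") / sum(ut) * 100
    out <- matrix(0, nrow(rdm), ncol(rdm))
    out[ut] <- ranks
    out <- out + t(out)
    rdm <- out
  }
  structure(rdm, class = c("rd_matrix", "matrix"))
}

#' Similarity of an RDM to the ideal (oracle) observer
#'
#' The oracle RDM has dissimilarity 0 for stimulus pairs of the same
#' class and 1 otherwise; similarity is the Spearman rank correlation of
#' the upper triangles.
#'
#' @param rdm a dissimilarity matrix.
#' @param labels per-stimulus class labels.
#' @return rank correlation in [-1, 1].
#' @export
oracle_similarity <- function(rdm, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop_pt("need at least 2 classes for the oracle RDM", "pt_config_error")
  oracle <- 1 - outer(labels, labels, `==`)
  ut <- upper.tri(rdm)
  stats::cor(rdm[ut], oracle[ut], method = "spearman")
}

#' Two-dimensional t-SNE embedding of population activity
#'
#' The standard protocol: principal components analysis to 50 dimensions
#' (skipped, with a note, when there are too few samples), then t-SNE
#' with perplexity 40 for 300 iterations under a fixed seed.
#'
#' @param features samples x features matrix.
#' @param perplexity t-SNE perplexity.
#' @param n_iter gradient-descent iterations.
#' @param n_pca PCA dimensionality before t-SNE.
#' @param seed embedding seed.
#' @return list with `coords` (samples x 2) and `pca_variance` (fraction
#'   of variance the PCA stage retained, NA when skipped).
#' @export
embed_tsne <- function(features, perplexity = 40, n_iter = 300L,
                       n_pca = 50L, seed = 1L) {
  X <- as.matrix(features)
  n <- nrow(X)
  pca_var <- NA_real_
  if (n > n_pca && ncol(X) > n_pca) {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pca)
    pca_var <- sum(pc$sdev[seq_len(n_pca)]^2) / sum(pc$sdev^2)
    X <- pc$x
  }
  perplexity <- min(perplexity, floor((n - 1) / 3))
  P <- .tsne_affinities(X, perplexity)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  gains <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  eta <- 200; momentum <- 0.5
  P4 <- P * 4  # early exaggeration
  for (it in seq_len(n_iter)) {
    Pu <- if (it <= 100) P4 else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    L <- (Pu - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    if (it == 20) momentum <- 0.8
  }
  list(coords = Y, pca_variance = pca_var)
}

# symmetric high-dimensional affinities with per-point bisection on the
# Gaussian bandwidth to match the target perplexity
.tsne_affinities <- function(X, perplexity) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump < 1e-300) { beta <- beta / 2; next }
      p <- p / sump
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  P
}

#' Ridge regression population decoder
#'
#' Decodes a kinematic variable from all units of a layer at single time
#' points, with ridge regularization (strength 1) and a
#' trajectory-disjoint train/test split.
#'
#' @param X frames x units predictor matrix.
#' @param y per-frame target (vector or matrix for joint XY decoding).
#' @param traj per-frame trajectory id for the disjoint split.
#' @param alpha ridge strength.
#' @param train_frac fraction of trajectories used for fitting.
#' @param seed split seed.
#' @return list with per-variable test `r2`, `coef`, and `error_cm` (mean
#'   Euclidean distance, only for 2-column targets).
#' @export
population_decode <- function(X, y, traj = NULL, alpha = 1,
                              train_frac = 0.8, seed = 1L) {
  X <- as.matrix(X); y <- as.matrix(y)
  if (nrow(X) != nrow(y))
    stop_pt("predictors and targets are misaligned", "pt_shape_error")
  if (is.null(traj)) traj <- seq_len(nrow(X))
  ids <- unique(traj)
  set.seed(seed)
  tr_ids <- sample(ids, max(1, round(train_frac * length(ids))))
  tr <- traj %in% tr_ids
  ridge_fit <- function(Xs, Ys) {
    mu_x <- colMeans(Xs); mu_y <- colMeans(Ys)
    Xc <- sweep(Xs, 2, mu_x); Yc <- sweep(Ys, 2, mu_y)
    B <- solve(crossprod(Xc) + diag(alpha, ncol(Xc)), crossprod(Xc, Yc))
    list(B = B, mu_x = mu_x, mu_y = mu_y)
  }
  fit <- ridge_fit(X[tr, , drop = FALSE], y[tr, , drop = FALSE])
  pred <- sweep(sweep(X[!tr, , drop = FALSE], 2, fit$mu_x) %*% fit$B,
                2, fit$mu_y, `+`)
  truth <- y[!tr, , drop = FALSE]
  r2 <- vapply(seq_len(ncol(y)), function(j)
    .r2_score(truth[, j], pred[, j]), numeric(1))
  err <- if (ncol(y) == 2)
    mean(sqrt(rowSums((pred - truth)^2))) else NA_real_
  list(r2 = r2, coef = fit$B, error_cm = err)
}

#' Histogram of preferred directions
#'
#' @param pds preferred directions (rad) of the tuned units.
#' @param n_bins angular bin count, default 18.
#' @return a `pd_histogram`: list with `counts`, `breaks`, `n`.
#' @export
pd_histogram <- function(pds, n_bins = 18L) {
  if (!length(pds)) stop_pt("no preferred directions", "pt_config_error")
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  x <- wrap_angle(pds)
  x[x == pi] <- pi - 1e-12  # (-pi, pi] binning with right-open cut
  counts <- as.vector(table(cut(x, breaks, include.lowest = TRUE)))
  structure(list(counts = counts, breaks = breaks, n = length(pds)),
            class = "pd_histogram")
}

#' Deviation of the preferred-direction distribution from uniformity
#'
#' Sums the absolute deviation of every angular bin count from the mean
#' bin count and normalizes by the number of tuned units.
#'
#' @param pds preferred directions (rad) of significantly tuned units.
#' @param n_bins angular bin count, default 18.
#' @return normalized absolute deviation (0 for an exactly uniform
#'   histogram).
#' @export
pd_uniformity <- function(pds, n_bins = 18L) {
  h <- pd_histogram(pds, n_bins)
  sum(abs(h$counts - mean(h$counts))) / h$n
}

#' Invariance of preferred directions across writing planes
#'
#' Mean absolute circular deviation of each unit's preferred direction in
#' every non-central plane from its direction in the central plane,
#' averaged over planes and units. Planes with fewer than `min_units`
#' directionally tuned units are excluded.
#'
#' @param fits_by_plane named list of per-plane tuning-fit tables (from
#'   [fit_tuning_models()] or [layer_tuning_fits()]), keyed by plane
#'   offset.
#' @param central_plane the key of the reference plane.
#' @param r2_threshold tuned-unit threshold on test R^2.
#' @param min_units minimum tuned units for a plane to count.
#' @return mean absolute deviation (rad); NA when no plane qualifies.
#' @export
pd_invariance <- function(fits_by_plane, central_plane,
                          r2_threshold = 0.2, min_units = 3L) {
  central_plane <- as.character(central_plane)
  if (!central_plane %in% names(fits_by_plane))
    stop_pt("central plane missing from the fit set", "pt_config_error")
  ref <- fits_by_plane[[central_plane]]
  ref_ok <- ref$test_r2 > r2_threshold & ref$test_r2 != 1 & ref$test_r2 >= -0.1
  devs <- c()
  for (key in setdiff(names(fits_by_plane), central_plane)) {
    f <- fits_by_plane[[key]]
    ok <- f$test_r2 > r2_threshold & f$test_r2 != 1 & f$test_r2 >= -0.1
    both <- which(ok & ref_ok[match(f$unit, ref$unit)])
    if (length(both) < min_units) next
    dd <- wrap_angle(f$theta_pd[both] -
                     ref$theta_pd[match(f$unit[both], ref$unit)])
    devs <- c(devs, mean(abs(dd)))
  }
  if (!length(devs)) return(NA_real_)
  mean(devs)
}

#' Paired t-test over model instantiations
#'
#' @param a,b per-instantiation metric vectors of equal length.
#' @param alpha significance level, default 0.05.
#' @return list with `t`, `df`, `p`, `significant`, `degenerate` (zero
#'   variance of the differences).
#' @export
paired_ttest <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b) || length(a) < 2)
    stop_pt("need two equal-length vectors of length >= 2", "pt_config_error")
  d <- a - b
  if (stats::sd(d) < 1e-15)
    return(list(t = if (all(d == 0)) 0 else NA_real_, df = length(d) - 1L,
                p = NA_real_, significant = FALSE, degenerate = TRUE))
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, significant = tt$p.value < alpha, degenerate = FALSE)
}
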