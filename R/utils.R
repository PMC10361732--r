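#' @keywords internal
#' @useDynLib propriotask, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pt <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "propriotask_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Linear interpolation of an n x d matrix of positions sampled at `t_in`
# onto query times `t_out` (both increasing).
interp_matrix <- function(points, t_in, t_out) {
  vapply(seq_len(ncol(points)), function(j) {
    stats::approx(t_in, points[, j], xout = t_out, rule = 2)$y
  }, numeric(length(t_out)))
}

# Finite-difference velocity: central differences in the interior,
# one-sided at the ends. `x` is n x d; returns n x d.
finite_diff <- function(x, dt) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop_pt("need at least 2 samples to differentiate", "pt_shape_error")
  d <- x
  d[1, ] <- (x[2, ] - x[1, ]) / dt
  d[n, ] <- (x[n, ] - x[n - 1, ]) / dt
  if (n > 2) d[2:(n - 1), ] <- (x[3:n, ] - x[1:(n - 2), ]) / (2 * dt)
  d
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministic integer sub-seed derivation (below 2^31) so that every
#' pipeline stage is independently reproducible from one master seed.
#'
#' @param master integer master seed.
#' @param stage stage name (any string).
#' @return integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 2654435 + h * 97 + 1) %% .Machine$integer.max)
}
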