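# Small numerical helpers shared across the package.

#' Trapezoidal integration
#'
#' Integrates sampled values `y` against abscissae `x` with the composite
#' trapezoidal rule.
#'
#' @param x Numeric vector of strictly increasing abscissae.
#' @param y Numeric vector of samples, same length as `x`.
#' @return The integral as a single number.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Ellipse perimeter (Ramanujan's second approximation)
#'
#' Perimeter of an ellipse with semi-axes `a` and `b`.  Relative error is
#' below 0.05% for aspect ratios up to 4, far below every tolerance used in
#' this package.
#'
#' @param a,b Semi-axes (same length unit; vectorised).
#' @return Perimeter in the same unit.
#' @export
ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Weighted quantile with linear interpolation on the weighted ECDF
#'
#' Quantile estimator for weighted samples: values are sorted, each value i
#' is placed at probability (cumw_i - w_i/2) / sum(w), and the quantile is
#' read off by linear interpolation (constant extrapolation beyond the
#' extreme placements).
#'
#' @param x Numeric values.
#' @param w Non-negative weights, same length as `x`.
#' @param p Probability in \[0, 1\] (vectorised).
#' @return Quantile estimate(s).
#' @export
weighted_quantile <- function(x, w, p) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0,
            all(p >= 0 & p <= 1))
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w)
  pk <- (cw - w / 2) / sum(w)
  stats::approx(pk, x, xout = p, rule = 2, ties = "ordered")$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mm/ml based reporting units <-> SI
MM <- 1e-3      # m per mm
MM2 <- 1e-6    # m^2 per mm^2
MLPS <- 1e-6   # m^3/s per ml/s
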