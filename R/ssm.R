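# Statistical shape model: PCA over the stacked vertex coordinates of a
# corresponded corpus.  The fitted object follows the classic R modelling
# idiom (print/summary/coef/predict/plot/simulate/residuals methods).

check_shared_topology <- function(corpus) {
  ref <- corpus$members[[1]]
  for (i in seq_along(corpus$members)) {
    m <- corpus$members[[i]]
    if (!identical(dim(m$vertices), dim(ref$vertices)) ||
        !identical(m$triangles, ref$triangles) ||
        !identical(m$patch_labels, ref$patch_labels))
      stop("corpus member ", i,
           " does not share the reference triangulation/patch labels")
  }
  invisible(ref)
}

# Rigid (rotation + translation, no scaling) generalised alignment by
# iterated Kabsch registration to the running mean.
rigid_align <- function(X, n_iter = 5) {
  n <- nrow(X)
  V <- ncol(X) / 3
  as_mat <- function(row) matrix(row, ncol = 3)
  centered <- lapply(seq_len(n), function(i) {
    m <- as_mat(X[i, ])
    sweep(m, 2, colMeans(m))
  })
  ref <- centered[[1]]
  for (it in seq_len(n_iter)) {
    aligned <- lapply(centered, function(m) {
      sv <- svd(crossprod(m, ref))
      d <- sign(det(sv$v %*% t(sv$u)))
      rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
      m %*% t(rot)
    })
    ref <- Reduce(`+`, aligned) / n
    centered <- aligned
  }
  t(vapply(centered, as.vector, numeric(3 * V)))
}

#' Fit a statistical shape model to a corresponded corpus
#'
#' Performs principal component analysis on the stacked vertex coordinates
#' of all corpus members (an n x 3V matrix), yielding the average shape,
#' orthonormal displacement modes and per-mode variances.  With all modes
#' retained any member is reconstructed exactly from the mean and its mode
#' weights.
#'
#' @param corpus A `duct_corpus` whose members share one triangulation
#'   (typically [mirror_augment()]ed first).
#' @param align If `TRUE`, apply generalised rigid alignment (rotation and
#'   translation, no scaling) before the PCA.  Off by default: the
#'   synthetic generator emits pre-aligned shapes.
#' @param tol Relative singular-value threshold below which modes are
#'   treated as zero-variance and dropped.
#' @return An object of class `nasal_ssm` with components `mean_vertices`
#'   (V x 3, mm), `modes` (3V x k, orthonormal columns, sign-fixed so each
#'   mode's largest-magnitude component is positive), `variances` (mm²,
#'   non-increasing), `scores` (n x k per-member weights, mm),
#'   `n_samples`, and the reference triangulation.
#' @seealso [mean_shape()], [modes_for_variance()], [predict.nasal_ssm()],
#'   [simulate.nasal_ssm()]
#' @export
nasal_ssm <- function(corpus, align = FALSE, tol = 1e-10) {
  stopifnot(inherits(corpus, "duct_corpus"))
  n <- length(corpus$members)
  if (n < 2) stop("a shape model needs at least two corpus members")
  ref <- check_shared_topology(corpus)

  X <- t(vapply(corpus$members, function(m) as.vector(m$vertices),
                numeric(3 * nrow(ref$vertices))))
  if (align) X <- rigid_align(X)

  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d[1], 0) * tol & sv$d > 0
  d <- sv$d[keep]
  modes <- sv$v[, keep, drop = FALSE]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, nrow = length(d))
  # Reproducible mode orientation: largest-magnitude component positive.
  for (k in seq_len(ncol(modes))) {
    m <- which.max(abs(modes[, k]))
    if (modes[m, k] < 0) {
      modes[, k] <- -modes[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(
    list(mean_vertices = matrix(mu, ncol = 3),
         modes = modes,
         variances = d^2 / (n - 1),
         scores = scores,
         n_samples = n,
         aligned = align,
         topology = ref$topology,
         ring_dirs = ref$ring_dirs,
         provenance = corpus$provenance),
    class = "nasal_ssm")
}

#' @export
print.nasal_ssm <- function(x, ...) {
  cat(sprintf("Statistical shape model: %d samples, %d modes, %d vertices\n",
              x$n_samples, length(x$variances), nrow(x$mean_vertices)))
  if (length(x$variances) > 0) {
    tot <- sum(x$variances)
    cat(sprintf("  total variance %.3f mm2; leading mode explains %.1f%%\n",
                tot, 100 * x$variances[1] / tot))
  } else {
    cat("  zero shape variance (all members identical)\n")
  }
  invisible(x)
}

#' @export
summary.nasal_ssm <- function(object, fractions = c(0.90, 0.95, 0.99), ...) {
  v <- object$variances
  tab <- if (length(v) > 0)
    data.frame(mode = seq_along(v), variance_mm2 = v,
               fraction = v / sum(v), cumulative = cumsum(v) / sum(v))
  else data.frame(mode = integer(), variance_mm2 = numeric(),
                  fraction = numeric(), cumulative = numeric())
  need <- if (length(v) > 0)
    vapply(fractions, function(f) modes_for_variance(object, f), integer(1))
  else rep(NA_integer_, length(fractions))
  structure(list(table = tab, n_samples = object$n_samples,
                 modes_needed = stats::setNames(need, paste0(100 * fractions, "%"))),
            class = "summary.nasal_ssm")
}

#' @export
print.summary.nasal_ssm <- function(x, ...) {
  cat(sprintf("Shape model over %d samples, %d modes\n",
              x$n_samples, nrow(x$table)))
  if (nrow(x$table) > 0) {
    print(utils::head(x$table, 10), row.names = FALSE, digits = 4)
    if (nrow(x$table) > 10) cat("  ...\n")
    cat("Modes needed to explain variance:\n")
    print(x$modes_needed)
  }
  invisible(x)
}

#' Per-member mode weights of a fitted shape model
#'
#' @param object A `nasal_ssm`.
#' @param ... Unused.
#' @return An n x k matrix of mode weights (mm); row i reconstructs member
#'   i as `mean + modes %*% coef[i, ]`.
#' @export
coef.nasal_ssm <- function(object, ...) object$scores

#' Average geometry of a shape model
#'
#' Returns the mean shape as a full `duct_geometry` on the reference
#' triangulation, with profiles recomputed from the mean rings.  For a
#' mirror-augmented corpus this geometry is mirror-symmetric.
#'
#' @param model A `nasal_ssm`.
#' @return A `duct_geometry`.
#' @export
mean_shape <- function(model) {
  stopifnot(inherits(model, "nasal_ssm"))
  new_duct_geometry(model$mean_vertices, model$topology, model$ring_dirs,
                    provenance = list(source = "ssm_mean",
                                      n_samples = model$n_samples))
}

#' Number of modes needed to explain a variance fraction
#'
#' @param model A `nasal_ssm` with positive total variance.
#' @param fraction Target fraction in (0, 1].
#' @return The smallest k with cumulative variance fraction >= `fraction`.
#' @export
modes_for_variance <- function(model, fraction) {
  v <- if (inherits(model, "nasal_ssm")) model$variances else model
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (length(v) == 0 || sum(v) <= 0)
    stop("model has zero total shape variance")
  as.integer(which(cumsum(v) / sum(v) >= fraction - 1e-12)[1])
}

#' Synthesize a geometry from mode weights
#'
#' Evaluates `mean + sum_k w_k mode_k` and rebuilds the station profiles.
#' Zero weights return the mean shape; the weights returned by
#' [coef.nasal_ssm()] reconstruct the corresponding member exactly.
#'
#' @param object A `nasal_ssm`.
#' @param weights Numeric vector of mode weights (mm), length at most the
#'   number of modes; missing trailing weights are taken as zero.
#' @param ... Unused.
#' @return A `duct_geometry`.
#' @export
predict.nasal_ssm <- function(object, weights = numeric(0), ...) {
  k <- length(object$variances)
  if (length(weights) > k)
    stop("weight vector longer than the model's mode list (", k, ")")
  v <- as.vector(object$mean_vertices)
  if (length(weights) > 0)
    v <- v + as.vector(object$modes[, seq_along(weights), drop = FALSE] %*%
                         weights)
  new_duct_geometry(matrix(v, ncol = 3), object$topology, object$ring_dirs,
                    provenance = list(source = "ssm_synthesis",
                                      weights = weights))
}

#' @rdname predict.nasal_ssm
#' @param model A `nasal_ssm` (alias interface).
#' @export
synthesize_shape <- function(model, weights = numeric(0)) {
  predict(model, weights)
}

#' Draw random geometries from a shape model
#'
#' Samples mode weights independently from zero-mean normals with the
#' model's per-mode variances.
#'
#' @param object A `nasal_ssm`.
#' @param nsim Number of geometries to draw.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `duct_geometry` objects (length `nsim`).
#' @export
simulate.nasal_ssm <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    w <- stats::rnorm(length(object$variances), 0, sqrt(object$variances))
    predict(object, w)
  }
  if (!is.null(seed)) with_rng_seed(seed, replicate(nsim, draw(),
                                                   simplify = FALSE))
  else replicate(nsim, draw(), simplify = FALSE)
}

#' Reconstruction residuals of a shape model
#'
#' Root-mean-square vertex residual of each corpus member after
#' reconstruction with the leading `k` modes.
#'
#' @param object A `nasal_ssm`.
#' @param k Number of modes used (default: all, giving residuals at
#'   numerical zero).
#' @param ... Unused.
#' @return Numeric vector of per-member RMS residuals in mm.
#' @export
residuals.nasal_ssm <- function(object, k = length(object$variances), ...) {
  if (length(object$variances) == 0) return(rep(0, object$n_samples))
  keep <- seq_len(k)
  drop <- object$scores[, -keep, drop = FALSE]
  modes <- object$modes[, -keep, drop = FALSE]
  vapply(seq_len(object$n_samples), function(i) {
    r <- modes %*% drop[i, ]
    sqrt(mean(matrix(r, ncol = 3)^2) * 3)
  }, numeric(1))
}

#' Variance-explained curve of a shape model
#'
#' Plots the cumulative fraction of shape variance explained against the
#' number of modes, the standard diagnostic for choosing a truncation.
#'
#' @param x A `nasal_ssm`.
#' @param fraction Reference fraction drawn as a horizontal line.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.nasal_ssm <- function(x, fraction = 0.95, ...) {
  v <- x$variances
  if (length(v) == 0) stop("model has zero shape variance; nothing to plot")
  cum <- cumsum(v) / sum(v)
  graphics::plot(seq_along(v), 100 * cum, type = "s",
                 xlab = "number of shape modes",
                 ylab = "cumulative shape variance explained [%]",
                 ylim = c(0, 100), ...)
  graphics::abline(h = 100 * fraction, lty = 2, col = 2)
  k <- modes_for_variance(x, fraction)
  graphics::points(k, 100 * cum[k], pch = 19, col = 2)
  invisible(x)
}
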