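# Nearest-neighbour mapping of wall-bound scalar fields between
# corresponded-or-not triangulations, and vertex-wise cross-subject
# statistics on the reference triangulation.

#' Wall-bound scalar field
#'
#' @param values One scalar per mesh vertex (Pa).
#' @param field_name `"pressure"` or `"wss"`.
#' @param phase `"inspiration"` or `"expiration"`.
#' @param mesh_ref Optional identifier of the carrying mesh.
#' @return An object of class `wall_field`.
#' @export
wall_field <- function(values, field_name = c("wss", "pressure"),
                       phase = c("inspiration", "expiration"),
                       mesh_ref = NULL) {
  field_name <- match.arg(field_name)
  phase <- match.arg(phase)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("field values must be finite")
  if (field_name == "wss" && any(values < 0))
    stop("wall shear stress values must be non-negative")
  structure(list(values = values, field_name = field_name, phase = phase,
                 mesh_ref = mesh_ref),
            class = "wall_field")
}

field_values <- function(x) {
  if (inherits(x, "wall_field")) x$values else as.numeric(x)
}

#' Map a field between meshes by nearest-neighbour interpolation
#'
#' Each target vertex takes the value of its nearest source vertex
#' (Euclidean distance); exact ties are broken deterministically by the
#' lowest source vertex index.  Nearest-neighbour mapping never creates
#' values outside the source range and preserves constant fields.
#'
#' @param source A `wall_field` (or bare numeric vector) on
#'   `source_geometry`.
#' @param source_geometry,target_geometry `duct_geometry` objects (or
#'   anything [hausdorff_distance()] accepts as a surface).
#' @return A `wall_field` on the target mesh.
#' @export
map_field_nearest <- function(source, source_geometry, target_geometry) {
  vals <- field_values(source)
  sv <- as_surface(source_geometry)$vertices
  tv <- as_surface(target_geometry)$vertices
  if (nrow(sv) == 0) stop("empty source mesh")
  if (length(vals) != nrow(sv))
    stop("field length (", length(vals), ") does not match source vertex ",
         "count (", nrow(sv), ")")
  nearest <- vapply(seq_len(nrow(tv)), function(i) {
    d2 <- colSums((t(sv) - tv[i, ])^2)
    which.min(d2)  # first minimum = lowest index on ties
  }, integer(1))
  mapped <- vals[nearest]
  if (inherits(source, "wall_field"))
    wall_field(mapped, source$field_name, source$phase,
               mesh_ref = "mapped")
  else mapped
}

#' Vertex-wise statistics of fields across subjects
#'
#' Computes, at every vertex of the reference triangulation, the mean,
#' median (even-n convention: midpoint of the central pair), sample
#' standard deviation (n-1 denominator) and coefficient of variation
#' `sd/mean` across subjects.  The CoV is masked (set to `NA`) wherever
#' `|mean| < eps`, since near-zero fields make it a low-signal ratio.
#'
#' @param fields List (>= 2) of `wall_field`s or numeric vectors, all on
#'   the reference triangulation.
#' @param eps Masking threshold in Pa (defaults: 1e-3 for WSS, 1e-2 for
#'   pressure fields, 1e-3 otherwise).
#' @return An object of class `vertex_stats`: vectors `mean`, `median`,
#'   `sd`, `cov`, logical `cov_mask`, `n_subjects`, `masked_fraction`.
#' @export
vertexwise_stats <- function(fields, eps = NULL) {
  if (length(fields) < 2) stop("need at least two fields")
  if (is.null(eps)) {
    nm <- if (inherits(fields[[1]], "wall_field")) fields[[1]]$field_name
          else ""
    eps <- if (identical(nm, "pressure")) 1e-2 else 1e-3
  }
  vals <- lapply(fields, field_values)
  len <- vapply(vals, length, integer(1))
  if (length(unique(len)) != 1)
    stop("fields have mismatched lengths: ", paste(unique(len), collapse = ", "))
  M <- do.call(rbind, vals)           # subjects x vertices
  mu <- colMeans(M)
  med <- apply(M, 2, stats::median)
  sdv <- apply(M, 2, stats::sd)
  mask <- abs(mu) < eps
  cov <- ifelse(mask, NA_real_, sdv / mu)
  structure(list(mean = mu, median = med, sd = sdv, cov = cov,
                 cov_mask = mask, n_subjects = nrow(M), eps = eps,
                 masked_fraction = mean(mask)),
            class = "vertex_stats")
}

#' @export
print.vertex_stats <- function(x, ...) {
  cat(sprintf(
    "Vertex-wise stats over %d subjects, %d vertices (%.1f%% CoV-masked at eps = %g)\n",
    x$n_subjects, length(x$mean), 100 * x$masked_fraction, x$eps))
  invisible(x)
}
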