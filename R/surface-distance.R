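# Surface-distance QC metrics: one-directional Hausdorff and mean surface
# distance, using exact point-to-triangle distances (falling back to
# point-to-point when a mesh carries no triangles).

as_surface <- function(x) {
  if (inherits(x, "duct_geometry"))
    return(list(vertices = x$vertices, triangles = x$triangles))
  if (is.list(x) && !is.null(x$vertices))
    return(list(vertices = as.matrix(x$vertices),
                triangles = if (!is.null(x$triangles) &&
                                length(x$triangles) > 0)
                  as.matrix(x$triangles) else NULL))
  if (is.matrix(x)) return(list(vertices = x, triangles = NULL))
  stop("cannot interpret object as a surface (need vertices/triangles)")
}

# Squared distances from one point to many triangles (A, B, C are n x 3).
# Projection onto the triangle plane clamped through barycentric signs;
# outside points fall back to the minimum over the three edges.
point_triangles_dist2 <- function(p, A, B, C) {
  seg_d2 <- function(P, Q) {
    d <- Q - P
    w <- sweep(-P, 2, p, `+`)            # p - P
    tt <- rowSums(w * d) / pmax(rowSums(d * d), .Machine$double.eps)
    tt <- pmin(pmax(tt, 0), 1)
    cl <- P + d * tt
    diffp <- sweep(cl, 2, p)
    rowSums(diffp^2)
  }
  e0 <- B - A
  e1 <- C - A
  w <- sweep(-A, 2, p, `+`)              # p - A
  a <- rowSums(e0 * e0)
  b <- rowSums(e0 * e1)
  c <- rowSums(e1 * e1)
  d <- rowSums(e0 * w)
  e <- rowSums(e1 * w)
  det <- pmax(a * c - b * b, .Machine$double.eps)
  s <- (c * d - b * e) / det
  t <- (a * e - b * d) / det
  inside <- s >= 0 & t >= 0 & (s + t) <= 1
  cl <- A + e0 * s + e1 * t
  diffp <- sweep(cl, 2, p)
  d2_plane <- rowSums(diffp^2)
  d2_edges <- pmin(seg_d2(A, B), seg_d2(A, C), seg_d2(B, C))
  ifelse(inside, d2_plane, d2_edges)
}

# Minimal distance from each vertex of `a` to the surface of `b`.
min_surface_distances <- function(a, b) {
  a <- as_surface(a)
  b <- as_surface(b)
  if (nrow(a$vertices) == 0 || nrow(b$vertices) == 0)
    stop("empty mesh")
  if (is.null(b$triangles)) {
    # point-set target: vertex-to-vertex
    return(vapply(seq_len(nrow(a$vertices)), function(i) {
      sqrt(min(colSums((t(b$vertices) - a$vertices[i, ])^2)))
    }, numeric(1)))
  }
  A <- b$vertices[b$triangles[, 1], , drop = FALSE]
  B <- b$vertices[b$triangles[, 2], , drop = FALSE]
  C <- b$vertices[b$triangles[, 3], , drop = FALSE]
  vapply(seq_len(nrow(a$vertices)), function(i) {
    sqrt(min(point_triangles_dist2(a$vertices[i, ], A, B, C)))
  }, numeric(1))
}

#' One-directional Hausdorff distance between two surfaces
#'
#' The maximum over vertices of `a` of the minimal (exact point-to-triangle)
#' distance to the surface of `b`.  This is the one-directional convention
#' used for segmentation/smoothing QC; use [hausdorff_distance_symmetric()]
#' for the symmetric variant.
#'
#' @param a,b `duct_geometry` objects, or lists with `vertices` (and
#'   optionally `triangles`), or bare vertex matrices.  A target without
#'   triangles is treated as a point set.
#' @return Distance in the meshes' length unit (mm).
#' @export
hausdorff_distance <- function(a, b) max(min_surface_distances(a, b))

#' @rdname hausdorff_distance
#' @export
hausdorff_distance_symmetric <- function(a, b) {
  max(hausdorff_distance(a, b), hausdorff_distance(b, a))
}

#' Mean surface distance between two surfaces
#'
#' The mean over vertices of `a` of the minimal distance to the surface of
#' `b` (same convention as [hausdorff_distance()], averaging instead of
#' maximising).
#'
#' @inheritParams hausdorff_distance
#' @return Distance in mm.
#' @export
mean_surface_distance <- function(a, b) mean(min_surface_distances(a, b))
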