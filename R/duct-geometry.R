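# DuctGeometry: one subject's bilateral airway surface plus per-side
# centerline station profiles (semi-axes, area, perimeter, arc length).

# Recover per-station ellipse parameters from (possibly deformed) rings by
# harmonic projection onto the known ring parameterisation:
#   x_j = cx + b cos(theta_j),  z_j = cz + a sin(theta_j)
# so  b = (2/R) sum x_j cos(theta_j),  a = (2/R) sum z_j sin(theta_j).
# Exact for elliptical rings and unbiased under zero-mean vertex noise.
ring_params <- function(xyz, dirs) {
  R <- length(dirs$cs)
  b <- 2 / R * sum(xyz[, 1] * dirs$cs)
  a <- 2 / R * sum(xyz[, 3] * dirs$sn)
  c(cx = mean(xyz[, 1]), cy = mean(xyz[, 2]), cz = mean(xyz[, 3]),
    a = a, b = b)
}

recompute_profiles <- function(vertices, topo, dirs,
                               min_semi_axis_mm = 0.15) {
  S <- topo$n_stations
  R <- topo$n_ring
  nv_side <- S * R
  out <- list()
  for (side in c("left", "right")) {
    off <- if (side == "left") 0L else nv_side
    prm <- matrix(0, nrow = S, ncol = 5,
                  dimnames = list(NULL, c("cx", "cy", "cz", "a", "b")))
    for (i in seq_len(S)) {
      rows <- off + (i - 1) * R + seq_len(R)
      prm[i, ] <- ring_params(vertices[rows, , drop = FALSE], dirs)
      if (prm[i, "a"] < min_semi_axis_mm || prm[i, "b"] < min_semi_axis_mm)
        stop(sprintf(
          "degenerate ring at station %d (%s side): semi-axes a = %.3f, b = %.3f mm; reduce mode_sd or noise_sd",
          i, side, prm[i, "a"], prm[i, "b"]))
    }
    centers <- prm[, c("cx", "cy", "cz"), drop = FALSE]
    arc <- c(0, cumsum(sqrt(rowSums(diff(centers)^2))))
    out[[side]] <- data.frame(
      station = seq_len(S), s = topo$s_values,
      a_mm = prm[, "a"], b_mm = prm[, "b"],
      area_mm2 = pi * prm[, "a"] * prm[, "b"],
      perimeter_mm = ramanujan_perimeter(prm[, "a"], prm[, "b"]),
      cx_mm = prm[, "cx"], cy_mm = prm[, "cy"], cz_mm = prm[, "cz"],
      arc_mm = arc)
  }
  out
}

new_duct_geometry <- function(vertices, topo, dirs, profiles = NULL,
                              provenance = list()) {
  profiles <- profiles %||% recompute_profiles(vertices, topo, dirs)
  structure(
    list(vertices = vertices,
         triangles = topo$triangles,
         patch_labels = topo$patch_labels,
         side_of_vertex = topo$side_of_vertex,
         station_of_vertex = topo$station_of_vertex,
         ring_of_vertex = topo$ring_of_vertex,
         s_values = topo$s_values,
         symmetry_map = topo$symmetry_map,
         profiles = profiles,
         topology = topo,
         ring_dirs = dirs,
         provenance = provenance),
    class = "duct_geometry")
}

#' @export
print.duct_geometry <- function(x, ...) {
  cat("Bilateral duct geometry\n")
  cat(sprintf("  %d vertices, %d triangles, %d patches, %d stations per side\n",
              nrow(x$vertices), nrow(x$triangles),
              length(unique(x$patch_labels)), length(x$s_values)))
  for (side in c("left", "right")) {
    p <- x$profiles[[side]]
    cat(sprintf("  %-5s: min CSA %.1f mm2 at s = %.2f, length %.1f mm\n",
                side, min(p$area_mm2), p$s[which.min(p$area_mm2)],
                max(p$arc_mm)))
  }
  invisible(x)
}

#' Plot the cross-sectional area profile of a geometry
#'
#' @param x A `duct_geometry`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.duct_geometry <- function(x, ...) {
  A <- cbind(left = x$profiles$left$area_mm2,
             right = x$profiles$right$area_mm2)
  graphics::matplot(x$s_values, A, type = "l", lty = 1:2, col = c(2, 4),
                    xlab = "normalised distance nostril -> choana",
                    ylab = "cross-sectional area [mm2]", ...)
  graphics::legend("bottomright", legend = c("left", "right"),
                   lty = 1:2, col = c(2, 4), bty = "n")
  invisible(x)
}

#' Airway volume of one side
#'
#' Integrates the cross-sectional area along the centerline arc length.
#'
#' @param g A `duct_geometry`.
#' @param side `"left"` or `"right"`.
#' @return Volume in mm³.
#' @export
side_volume <- function(g, side = c("left", "right")) {
  side <- match.arg(side)
  p <- g$profiles[[side]]
  trapz(p$arc_mm, p$area_mm2)
}
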