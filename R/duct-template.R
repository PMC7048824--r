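# Baseline bilateral duct template: two tubes of elliptical cross-section
# around smooth centerlines, with shared triangulation, 24 patch labels
# (12 per side) and a precomputed left<->right symmetry map used for
# sagittal mirroring.

default_area_profile <- function(nostril_area_mm2 = 100) {
  # Anterior constriction (isthmus) at s ~ 0.15 with ~55% of the nostril
  # area, mid-cavity ~2x the nostril area, mild posterior taper.  Knot
  # values are synthetic, chosen to be of the same order as adult nasal
  # cross-sectional areas.
  s_knots <- c(0, 0.07, 0.15, 0.30, 0.50, 0.70, 0.85, 1.00)
  rel <- c(1.00, 0.72, 0.55, 1.40, 2.00, 1.90, 1.70, 1.50)
  f <- stats::splinefun(s_knots, nostril_area_mm2 * rel, method = "natural")
  function(s) f(s)
}

default_aspect_profile <- function() {
  # Vertical-to-lateral semi-axis ratio; nasal passages are taller than
  # wide.  Kept below 4 so the Ramanujan perimeter stays essentially exact.
  function(s) 2.5 + 0.8 * sin(pi * s)
}

default_centerline <- function(length_mm = 70) {
  # One side's centerline: lateral offset bulging mid-cavity, gentle
  # vertical arch.  `side_sign` is -1 for the left side (x < 0), +1 right.
  function(s, side_sign) {
    cbind(side_sign * (6 + 3 * sin(pi * s)),
          s * length_mm,
          8 * sin(pi * s))
  }
}

# Ring direction cosines, symmetrised so that the mirror map is exact in
# floating point: cs[mirror(j)] == -cs[j] and sn[mirror(j)] == sn[j].
ring_directions <- function(n_ring) {
  ang <- 2 * pi * (0:(n_ring - 1)) / n_ring
  cs <- cos(ang)
  sn <- sin(ang)
  jm <- ring_mirror_index(n_ring)
  cs <- (cs - cs[jm]) / 2
  sn <- (sn + sn[jm]) / 2
  list(cs = cs, sn = sn)
}

# Ring index holding the angle pi - theta_j (reflection across x = 0).
ring_mirror_index <- function(n_ring) {
  j <- seq_len(n_ring)
  ((n_ring / 2 - (j - 1)) %% n_ring) + 1
}

build_topology <- function(n_stations, n_ring) {
  S <- n_stations
  R <- n_ring
  nv_side <- S * R
  idx <- function(side, i, j)
    as.integer((side - 1) * nv_side + (i - 1) * R + j)

  tri <- matrix(0L, nrow = 2 * (S - 1) * R * 2, ncol = 3)
  lab <- integer(nrow(tri))
  row <- 0L
  for (side in 1:2) {
    for (i in seq_len(S - 1)) {
      seg <- as.integer(ceiling(i * 4 / (S - 1)))
      for (j in seq_len(R)) {
        jn <- j %% R + 1L
        sec <- as.integer(ceiling(j * 3 / R))
        patch <- (side - 1L) * 12L + (seg - 1L) * 3L + sec
        v00 <- idx(side, i, j); v01 <- idx(side, i, jn)
        v10 <- idx(side, i + 1, j); v11 <- idx(side, i + 1, jn)
        tri[row + 1L, ] <- c(v00, v01, v11)
        tri[row + 2L, ] <- c(v00, v11, v10)
        lab[row + 1L] <- patch
        lab[row + 2L] <- patch
        row <- row + 2L
      }
    }
  }

  side_of_vertex <- rep(c("left", "right"), each = nv_side)
  station_of_vertex <- rep(rep(seq_len(S), each = R), times = 2)
  ring_of_vertex <- rep(rep(seq_len(R), times = S), times = 2)

  jm <- ring_mirror_index(R)
  symmetry_map <- integer(2 * nv_side)
  for (i in seq_len(S)) {
    for (j in seq_len(R)) {
      symmetry_map[idx(1, i, j)] <- idx(2, i, jm[j])
      symmetry_map[idx(2, i, j)] <- idx(1, i, jm[j])
    }
  }

  list(n_stations = S, n_ring = R,
       triangles = tri, patch_labels = lab,
       side_of_vertex = side_of_vertex,
       station_of_vertex = station_of_vertex,
       ring_of_vertex = ring_of_vertex,
       symmetry_map = symmetry_map,
       s_values = seq(0, 1, length.out = S))
}

#' Bilateral nasal duct template
#'
#' Defines the baseline geometry from which synthetic subjects are
#' generated: two tubes of elliptical cross-section (one per nasal cavity)
#' around smooth centerlines, discretised as `n_stations` rings of `n_ring`
#' vertices each per side, with a fixed triangulation, 24 patch labels
#' (12 per side) and an anterior constriction (the isthmus) in the
#' cross-sectional-area profile.
#'
#' @param n_stations Number of centerline stations per side (>= 11).  The
#'   default 21 matches a 5\% sampling of the normalised nostril-to-choana
#'   axis.
#' @param n_ring Number of vertices per cross-sectional ring (even, >= 8).
#' @param length_mm Centerline cord length in mm.
#' @param nostril_area_mm2 Cross-sectional area at the nostril (s = 0), mm².
#' @param area_profile Optional function `A(s)` (mm²) overriding the default
#'   profile; must be strictly positive with a unique interior minimum.
#' @param aspect_profile Optional function giving the vertical/lateral
#'   semi-axis ratio per `s`.
#' @param centerline Optional function `(s, side_sign)` returning an
#'   `length(s) x 3` matrix of centerline points in mm.
#' @param isthmus_position Normalised position of the area minimum
#'   (validated against `area_profile`).
#' @param validate_isthmus Require a unique interior area minimum?  Keep
#'   `TRUE` for nasal-like anatomy; set `FALSE` for idealised phantom
#'   ducts (uniform or monotone profiles) used as analytic references.
#' @return An object of class `duct_template`.
#' @examples
#' tpl <- duct_template(n_stations = 11, n_ring = 8)
#' tpl
#' @export
duct_template <- function(n_stations = 21, n_ring = 24, length_mm = 70,
                          nostril_area_mm2 = 100,
                          area_profile = NULL, aspect_profile = NULL,
                          centerline = NULL, isthmus_position = 0.15,
                          validate_isthmus = TRUE) {
  if (n_stations < 11) stop("n_stations must be >= 11")
  if (n_ring < 8 || n_ring %% 2 != 0) stop("n_ring must be even and >= 8")

  area_profile <- area_profile %||% default_area_profile(nostril_area_mm2)
  aspect_profile <- aspect_profile %||% default_aspect_profile()
  centerline <- centerline %||% default_centerline(length_mm)

  # Validate the area profile: strictly positive, unique interior minimum
  # near the declared isthmus position.
  s_fine <- seq(0, 1, length.out = 2001)
  A_fine <- area_profile(s_fine)
  if (any(!is.finite(A_fine)) || any(A_fine <= 0))
    stop("area_profile must be strictly positive on [0, 1]")
  if (validate_isthmus) {
    interior <- 2:(length(s_fine) - 1)
    is_min <- A_fine[interior] < A_fine[interior - 1] &
      A_fine[interior] <= A_fine[interior + 1]
    mins <- s_fine[interior][is_min]
    if (length(mins) != 1)
      stop("area_profile must have a unique interior minimum (the isthmus); ",
           "found ", length(mins))
    if (abs(mins - isthmus_position) > 0.05)
      stop(sprintf(
        "area_profile minimum at s = %.3f, not at the declared isthmus_position %.3f",
        mins, isthmus_position))
  }

  topo <- build_topology(n_stations, n_ring)
  dirs <- ring_directions(n_ring)

  s <- topo$s_values
  A <- area_profile(s)
  asp <- aspect_profile(s)
  a <- sqrt(A * asp / pi)   # vertical semi-axis (z)
  b <- sqrt(A / (pi * asp)) # lateral semi-axis (x)

  nv_side <- n_stations * n_ring
  vertices <- matrix(0, nrow = 2 * nv_side, ncol = 3)
  for (side in 1:2) {
    sgn <- if (side == 1) -1 else 1
    centers <- centerline(s, sgn)
    for (i in seq_len(n_stations)) {
      rows <- (side - 1) * nv_side + (i - 1) * n_ring + seq_len(n_ring)
      vertices[rows, 1] <- centers[i, 1] + b[i] * dirs$cs
      vertices[rows, 2] <- centers[i, 2]
      vertices[rows, 3] <- centers[i, 3] + a[i] * dirs$sn
    }
  }
  if (max(vertices[topo$side_of_vertex == "left", 1]) >= 0 ||
      min(vertices[topo$side_of_vertex == "right", 1]) <= 0)
    stop("template sides cross the mid-sagittal plane x = 0; ",
         "reduce section widths or move the centerlines apart")

  tpl <- structure(
    list(n_stations = n_stations, n_ring = n_ring, length_mm = length_mm,
         area_profile = area_profile, ellipse_aspect_profile = aspect_profile,
         centerline_curve = centerline, isthmus_position = isthmus_position,
         topology = topo, ring_dirs = dirs, vertices = vertices),
    class = "duct_template")
  tpl
}

#' @export
print.duct_template <- function(x, ...) {
  cat("Bilateral duct template\n")
  cat(sprintf("  stations per side: %d, ring vertices: %d, length: %g mm\n",
              x$n_stations, x$n_ring, x$length_mm))
  cat(sprintf("  vertices: %d, triangles: %d, patches: %d\n",
              nrow(x$vertices), nrow(x$topology$triangles),
              length(unique(x$topology$patch_labels))))
  cat(sprintf("  isthmus at s = %.2f (area %.1f mm2, nostril %.1f mm2)\n",
              x$isthmus_position, x$area_profile(x$isthmus_position),
              x$area_profile(0)))
  invisible(x)
}
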