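# Shared fixtures, all built in code.

# Small nasal-like template: coarse but fast.
small_template <- function() duct_template(n_stations = 11, n_ring = 8)

# Idealised straight circular tube (both sides radius r_mm), used as the
# analytic Poiseuille reference.
circular_template <- function(r_mm = 3, length_mm = 80,
                              n_stations = 11, n_ring = 8) {
  duct_template(
    n_stations = n_stations, n_ring = n_ring, length_mm = length_mm,
    area_profile = function(s) rep(pi * r_mm^2, length(s)),
    aspect_profile = function(s) rep(1, length(s)),
    centerline = function(s, side_sign)
      cbind(side_sign * (r_mm + 10) + 0 * s, s * length_mm, 0 * s),
    validate_isthmus = FALSE)
}

no_variation <- function(seed = 1) {
  shape_variation(n_modes = 0, mode_sd = numeric(0), noise_sd = 0,
                  seed = seed)
}

template_geometry <- function(template) {
  generate_subject(template, no_variation(), 0)
}

# Geometry with per-side radius scaling of a circular tube: vertices of
# each side are scaled about the side's centerline, giving radii
# r * scale_left / r * scale_right.
scaled_circular_geometry <- function(r_mm = 3, scale_left = 1,
                                     scale_right = 1, ...) {
  g <- template_geometry(circular_template(r_mm, ...))
  v <- g$vertices
  for (side in c("left", "right")) {
    sel <- g$side_of_vertex == side
    sc <- if (side == "left") scale_left else scale_right
    st <- g$station_of_vertex[sel]
    prof <- g$profiles[[side]]
    ctr <- cbind(prof$cx_mm[st], prof$cy_mm[st], prof$cz_mm[st])
    v[sel, ] <- ctr + sc * (v[sel, ] - ctr)
  }
  noseflow:::new_duct_geometry(v, g$topology, g$ring_dirs)
}

poiseuille_dp <- function(r_m, L_m, Q_m3s, mu = 1.86e-5) {
  8 * mu * L_m * Q_m3s / (pi * r_m^4)
}
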