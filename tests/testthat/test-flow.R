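# Quasi-1D flow proxy: Poiseuille oracle, partition solver, wall fields,
# direction symmetry.

MU <- 1.86e-5

test_that("circular ducts match the Poiseuille closed form to 1e-10 relative", {
  g <- template_geometry(circular_template(r_mm = 3, length_mm = 80))
  dp <- lateral_pressure_drop(g, "left", 100)
  oracle <- poiseuille_dp(0.003, 0.08, 1e-4)
  expect_equal(dp$delta_p_pa, oracle, tolerance = 1e-10)
  expect_equal(dp$delta_p_pa, 4.678, tolerance = 1e-4)
  expect_equal(lateral_resistance(g, "left", 100), 0.04678,
               tolerance = 1e-4)
})

test_that("halving the radius multiplies resistance by 16 and R is flow-independent", {
  g1 <- template_geometry(circular_template(r_mm = 4))
  g2 <- template_geometry(circular_template(r_mm = 2))
  R1 <- lateral_resistance(g1, "left", 100)
  R2 <- lateral_resistance(g2, "left", 100)
  expect_equal(R2 / R1, 16, tolerance = 1e-10)
  # linear Stokes regime: R independent of Q with losses off
  expect_equal(lateral_resistance(g1, "left", 50),
               lateral_resistance(g1, "left", 400), tolerance = 1e-12)
  # and delta p scales linearly in Q
  expect_equal(lateral_pressure_drop(g1, "left", 300)$delta_p_pa,
               3 * lateral_pressure_drop(g1, "left", 100)$delta_p_pa,
               tolerance = 1e-12)
})

test_that("uniform ducts are loss-free and zero flow gives zero drop", {
  g <- template_geometry(circular_template())
  expect_equal(lateral_pressure_drop(g, "left", 100, losses = TRUE)$delta_p_pa,
               lateral_pressure_drop(g, "left", 100, losses = FALSE)$delta_p_pa,
               tolerance = 1e-15)
  expect_equal(lateral_pressure_drop(g, "left", 0)$delta_p_pa, 0)
})

test_that("the elliptical law reduces to the circular law when a = b", {
  # same area, aspect 1 vs explicit circle: identical by construction;
  # instead compare an aspect-3 ellipse against its own closed form
  r <- 3
  tpl <- duct_template(
    n_stations = 11, n_ring = 12, length_mm = 80,
    area_profile = function(s) rep(pi * r^2, length(s)),
    aspect_profile = function(s) rep(3, length(s)),
    centerline = function(s, sgn) cbind(sgn * 15 + 0 * s, s * 80, 0 * s),
    validate_isthmus = FALSE)
  g <- template_geometry(tpl)
  a <- g$profiles$left$a_mm[1] * 1e-3
  b <- g$profiles$left$b_mm[1] * 1e-3
  dp <- lateral_pressure_drop(g, "left", 100)
  oracle <- 4 * MU * 1e-4 * (a^2 + b^2) / (pi * a^3 * b^3) * 0.08
  expect_equal(dp$delta_p_pa, oracle, tolerance = 1e-12)
  expect_gt(dp$delta_p_pa, poiseuille_dp(0.003, 0.08, 1e-4))  # ellipse resists more
})

test_that("the bilateral partition matches the two-resistor divider", {
  # right radius r/2^(1/4) -> R_right = 2 R_left -> AP = 66.7%
  g <- scaled_circular_geometry(r_mm = 3, scale_left = 1,
                                scale_right = 2^(-1 / 4))
  R_l <- lateral_resistance(g, "left", 100)
  R_r <- lateral_resistance(g, "right", 100)
  expect_equal(R_r / R_l, 2, tolerance = 1e-9)
  sol <- solve_bilateral_partition(g, breathing_phase("inspiration", 200))
  closed <- 200 * R_r / (R_l + R_r)
  expect_equal(sol$Q_left_mls, closed, tolerance = 1e-6)
  expect_equal(sol$AP_pct, 100 * 2 / 3, tolerance = 1e-4)
  expect_equal(sol$Q_left_mls + sol$Q_right_mls, 200, tolerance = 1e-9)
  expect_lte(abs(sol$pressure_mismatch_pa), 1e-9)
  expect_equal(sol$R_total, total_resistance(R_l, R_r), tolerance = 1e-6)
})

test_that("mirror-symmetric geometries split the flow exactly 50/50", {
  g <- mean_shape(nasal_ssm(mirror_augment(generate_corpus(
    small_template(), shape_variation(n_modes = 3, seed = 21), 4))))
  for (losses in c(FALSE, TRUE)) {
    sol <- solve_bilateral_partition(g, breathing_phase("inspiration", 200),
                                     losses = losses)
    expect_equal(sol$AP_pct, 50)
  }
})

test_that("wall fields obey the axial force balance and the nostril reference", {
  g <- template_geometry(circular_template(r_mm = 5, length_mm = 80))
  sol <- solve_bilateral_partition(g, breathing_phase("inspiration", 200))
  wf <- wall_fields(g, sol)
  # circular closed form tau = 4 mu Q / (pi r^3) at Q = 100 ml/s
  expect_equal(unique(round(wf$wss_pa, 12)),
               4 * MU * 1e-4 / (pi * 0.005^3), tolerance = 1e-10)
  expect_equal(max(wf$wss_pa), 0.0189, tolerance = 1e-2)
  # defining identity tau P = |dp/ds| A at every station
  for (side in c("left", "right")) {
    p <- g$profiles[[side]]
    lhs <- sol$tau_stations_pa[[side]] * p$perimeter_mm * 1e-3
    rhs <- lateral_pressure_drop(g, side, sol$Q_left_mls)$visc_grad_pa_per_m *
      p$area_mm2 * 1e-6
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  # nostril vertices sit at the 0 Pa reference in both phases
  nostril <- g$station_of_vertex == 1
  expect_true(all(wf$wall_pressure_pa[nostril] == 0))
  sol_e <- solve_bilateral_partition(g, breathing_phase("expiration", 200))
  wf_e <- wall_fields(g, sol_e)
  expect_true(all(wf_e$wall_pressure_pa[nostril] == 0))
})

test_that("station pressure decreases along the flow direction", {
  g <- template_geometry(small_template())
  for (dir in c("inspiration", "expiration")) {
    for (losses in c(FALSE, TRUE)) {
      dp <- lateral_pressure_drop(g, "left", 120, direction = dir,
                                  losses = losses)
      p <- dp$p_stations_pa
      along_flow <- if (dir == "inspiration") p else rev(p)
      expect_true(all(diff(along_flow) < 0))
    }
  }
})

test_that("losses off gives reversible phases; losses on breaks the symmetry", {
  g <- template_geometry(small_template())
  off <- simulate_phases(g, losses = FALSE)
  expect_equal(off$inspiration$R_total, off$expiration$R_total,
               tolerance = 1e-12)
  on <- simulate_phases(g, losses = TRUE)
  expect_gt(abs(on$inspiration$R_total / on$expiration$R_total - 1), 1e-4)
  expect_lt(on$inspiration$mach_max, 0.01)
})

test_that("circumferential modulation preserves the station-mean shear", {
  tpl <- duct_template(n_stations = 11, n_ring = 16, length_mm = 80,
                       area_profile = function(s) rep(40, length(s)),
                       aspect_profile = function(s) rep(2, length(s)),
                       centerline = function(s, sgn)
                         cbind(sgn * 12 + 0 * s, s * 80, 0 * s),
                       validate_isthmus = FALSE)
  g <- template_geometry(tpl)
  sol <- solve_bilateral_partition(g, breathing_phase("inspiration", 200))
  plain <- wall_fields(g, sol, circumferential = FALSE)
  mod <- wall_fields(g, sol, circumferential = TRUE)
  expect_gt(stats::sd(mod$wss_pa), stats::sd(plain$wss_pa))
  # arc-weighted ring means agree with the unmodulated station value
  sel <- g$side_of_vertex == "left" & g$station_of_vertex == 5
  a <- g$profiles$left$a_mm[5]
  b <- g$profiles$left$b_mm[5]
  cs <- g$ring_dirs$cs[g$ring_of_vertex[sel]]
  sn <- g$ring_dirs$sn[g$ring_of_vertex[sel]]
  w <- sqrt(b^2 * sn^2 + a^2 * cs^2)
  expect_equal(sum(mod$wss_pa[sel] * w) / sum(w),
               unique(plain$wss_pa[sel]), tolerance = 1e-12)
})

test_that("averaged circular geometries resist less than the member average (convexity)", {
  # r^-4 is convex: for two-member corpora of circular ducts the mean-shape
  # resistance is below the mean of the member resistances, strictly so
  # whenever the radii differ.
  set.seed(42)
  for (rep in 1:100) {
    r1 <- stats::runif(1, 2, 4)
    r2 <- stats::runif(1, 2, 4)
    g1 <- scaled_circular_geometry(3, scale_left = r1 / 3,
                                   scale_right = r1 / 3)
    g2 <- scaled_circular_geometry(3, scale_left = r2 / 3,
                                   scale_right = r2 / 3)
    co <- structure(list(members = list(g1, g2),
                         mirrored = c(FALSE, FALSE), provenance = list()),
                    class = "duct_corpus")
    gm <- mean_shape(nasal_ssm(co))
    R_mean_shape <- lateral_resistance(gm, "left", 100)
    R_members <- (lateral_resistance(g1, "left", 100) +
                    lateral_resistance(g2, "left", 100)) / 2
    expect_lte(R_mean_shape, R_members)
    if (abs(r1 - r2) > 1e-3) expect_lt(R_mean_shape, R_members)
  }
})

test_that("fluid and phase constructors validate inputs", {
  expect_error(fluid_properties(density = 0), "positive")
  expect_error(breathing_phase("inspiration", 0), "positive")
  f <- fluid_properties()
  expect_equal(f$density, 1.18)
  expect_equal(f$viscosity_pas, 1.86e-5)
  expect_equal(breathing_phase()$flow_mls, 200)
})
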