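# Quasi-1D laminar flow proxy: exact fully developed elliptical-duct
# viscous pressure gradient, optional Borda-Carnot expansion losses, a
# bisection solver for the bilateral flow partition under a shared pharynx
# pressure, and the wall fields (static pressure, wall shear stress)
# derived from the axial force balance.

#' Fluid properties
#'
#' @param density Density in kg/m³ (default: air at body-ish conditions).
#' @param viscosity_pas Dynamic viscosity in Pa·s.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1.18, viscosity_pas = 1.86e-5) {
  if (density <= 0 || viscosity_pas <= 0)
    stop("density and viscosity must be strictly positive")
  structure(list(density = density, viscosity_pas = viscosity_pas),
            class = "fluid_properties")
}

#' Breathing phase
#'
#' @param label `"inspiration"` or `"expiration"`.
#' @param flow_mls Total (bilateral) volumetric flow rate in ml/s; the
#'   default 200 ml/s corresponds to restful breathing at a respiratory
#'   minute volume of 6 litres with equal phase durations.
#' @return An object of class `breathing_phase`.
#' @export
breathing_phase <- function(label = c("inspiration", "expiration"),
                            flow_mls = 200) {
  label <- match.arg(label)
  if (flow_mls <= 0) stop("flow rate must be positive")
  structure(list(label = label, flow_mls = flow_mls),
            class = "breathing_phase")
}

#' Quasi-steady phase flow rate from the respiratory minute volume
#'
#' Under the quasi-steady assumption, a minute volume of `minute_volume_l`
#' litres moved in a fraction `phase_fraction` of the breathing cycle
#' (0.5 for equal-duration inspiration and expiration) corresponds to a
#' steady phase flow of `minute_volume_l * 1000 / 60 / phase_fraction`
#' ml/s: 6 l/min gives 200 ml/s.
#'
#' @param minute_volume_l Respiratory minute volume in litres.
#' @param phase_fraction Fraction of the cycle spent in the phase.
#' @return Flow rate in ml/s.
#' @export
phase_flow_rate <- function(minute_volume_l = 6, phase_fraction = 0.5) {
  stopifnot(minute_volume_l > 0, phase_fraction > 0, phase_fraction <= 1)
  minute_volume_l * 1000 / 60 / phase_fraction
}

# Per-station viscous pressure gradient (Pa/m) and wall shear stress (Pa)
# for one side at flow Q (ml/s).  Fully developed elliptical duct law:
# dp/dx = 4 mu Q (a^2 + b^2) / (pi a^3 b^3); tau = (dp/dx) A / P.
side_viscous_terms <- function(g, side, Q_mls, fluid) {
  p <- g$profiles[[side]]
  a <- p$a_mm * MM
  b <- p$b_mm * MM
  Q <- Q_mls * MLPS
  grad <- 4 * fluid$viscosity_pas * Q * (a^2 + b^2) / (pi * a^3 * b^3)
  A <- p$area_mm2 * MM2
  P <- p$perimeter_mm * MM
  list(grad_pa_per_m = grad, tau_pa = grad * A / P,
       arc_m = p$arc_mm * MM, area_m2 = A)
}

# Borda-Carnot losses (Pa) at each inter-station transition, traversed in
# the flow direction; `loss[i]` is the loss on the segment between
# stations i and i+1 (nostril-to-choana indexing, whatever the direction).
borda_carnot_losses <- function(area_m2, Q_mls, fluid, direction) {
  Q <- Q_mls * MLPS
  S <- length(area_m2)
  loss <- numeric(S - 1)
  if (direction == "inspiration") {
    up <- area_m2[-S]; dn <- area_m2[-1]
  } else {
    up <- area_m2[-1]; dn <- area_m2[-S]
  }
  expand <- dn > up
  K <- ifelse(expand, (1 - up / dn)^2, 0)
  u_small <- Q / up
  loss <- K * fluid$density * u_small^2 / 2
  loss
}

#' Lateral pressure drop of one nasal cavity
#'
#' Integrates the fully developed elliptical-duct viscous gradient over the
#' station grid (trapezoidal rule on arc length) and, when `losses = TRUE`,
#' adds a Borda-Carnot loss at every inter-station transition whose area
#' increases in the flow direction.  Station pressures are referenced to
#' 0 Pa at the nostril and decrease monotonically along the flow direction.
#'
#' @param g A `duct_geometry`.
#' @param side `"left"` or `"right"`.
#' @param Q_mls Unilateral flow rate in ml/s (0 gives a zero drop).
#' @param fluid A [fluid_properties()].
#' @param direction `"inspiration"` (nostril to pharynx) or
#'   `"expiration"`.
#' @param losses Include Borda-Carnot expansion losses?
#' @return A list: `delta_p_pa` (total drop), `p_stations_pa` (pressure at
#'   each station, nostril-to-choana order, 0 Pa at the nostril),
#'   `tau_stations_pa` (viscous wall shear stress per station; minor-loss
#'   contributions are excluded from the wall shear by design),
#'   `visc_grad_pa_per_m`.
#' @export
lateral_pressure_drop <- function(g, side = c("left", "right"), Q_mls,
                                  fluid = fluid_properties(),
                                  direction = c("inspiration", "expiration"),
                                  losses = FALSE) {
  side <- match.arg(side)
  direction <- match.arg(direction)
  if (Q_mls < 0) stop("flow rate must be non-negative")
  vt <- side_viscous_terms(g, side, Q_mls, fluid)
  S <- length(vt$arc_m)
  # cumulative viscous drop from the nostril to each station
  seg_visc <- (vt$grad_pa_per_m[-1] + vt$grad_pa_per_m[-S]) / 2 *
    diff(vt$arc_m)
  seg_loss <- if (losses)
    borda_carnot_losses(vt$area_m2, Q_mls, fluid, direction)
  else numeric(S - 1)
  seg <- seg_visc + seg_loss
  cum <- c(0, cumsum(seg))          # drop between nostril and station i
  delta_p <- cum[S]
  p <- if (direction == "inspiration") -cum else cum
  list(delta_p_pa = delta_p, p_stations_pa = p,
       tau_stations_pa = vt$tau_pa,
       visc_grad_pa_per_m = vt$grad_pa_per_m,
       direction = direction, side = side, Q_mls = Q_mls, losses = losses)
}

#' Lateral nasal resistance
#'
#' `R = delta_p / Q` in Pa·s/ml.  With losses off the model is linear in Q
#' (Stokes regime) and R is flow-independent.
#'
#' @inheritParams lateral_pressure_drop
#' @return Resistance in Pa·s/ml.
#' @export
lateral_resistance <- function(g, side, Q_mls, fluid = fluid_properties(),
                               direction = "inspiration", losses = FALSE) {
  if (Q_mls <= 0) stop("resistance requires a positive flow rate")
  lateral_pressure_drop(g, side, Q_mls, fluid, direction,
                        losses)$delta_p_pa / Q_mls
}

#' Total nasal resistance (parallel combination)
#'
#' @param R_left,R_right Lateral resistances in Pa·s/ml (both positive).
#' @return `R_left * R_right / (R_left + R_right)`, unrounded.
#' @export
total_resistance <- function(R_left, R_right) {
  if (any(c(R_left, R_right) <= 0))
    stop("lateral resistances must be strictly positive")
  R_left * R_right / (R_left + R_right)
}

#' Solve the bilateral flow partition
#'
#' Both cavities share the nostril pressure (0 Pa) and a common pharynx
#' pressure, so their pressure drops must match.  The left flow is found by
#' bisection on `delta_p_left(Q) = delta_p_right(V - Q)` to a mismatch of
#' at most `tol_pa`; the drop is strictly monotone in Q, so the root is
#' unique.  With losses off the solution equals the two-resistor current
#' divider `Q_left = V R_right / (R_left + R_right)`.
#'
#' @param g A `duct_geometry`.
#' @param phase A [breathing_phase()].
#' @param fluid A [fluid_properties()].
#' @param losses Include Borda-Carnot losses?
#' @param tol_pa Pressure-mismatch tolerance (Pa).
#' @param max_iter Maximum bisection iterations.
#' @return An object of class `flow_solution`: per-side flows (ml/s),
#'   pressure drop, station pressures and wall shear stresses, per-station
#'   mean velocities (m/s), airflow partitioning `AP` (left share, %),
#'   lateral and total resistances (Pa·s/ml), and the peak Mach number.
#' @export
solve_bilateral_partition <- function(g, phase = breathing_phase(),
                                      fluid = fluid_properties(),
                                      losses = FALSE,
                                      tol_pa = 1e-9, max_iter = 200) {
  stopifnot(inherits(g, "duct_geometry"))
  V <- phase$flow_mls
  direction <- phase$label
  dp_l <- function(q) lateral_pressure_drop(g, "left", q, fluid, direction,
                                            losses)$delta_p_pa
  dp_r <- function(q) lateral_pressure_drop(g, "right", q, fluid, direction,
                                            losses)$delta_p_pa
  mismatch <- function(q) dp_l(q) - dp_r(V - q)
  lo <- 0
  hi <- V
  q <- V / 2
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    q <- (lo + hi) / 2
    m <- mismatch(q)
    if (abs(m) <= tol_pa) {
      converged <- TRUE
      break
    }
    if (m > 0) hi <- q else lo <- q
  }
  if (!converged)
    stop("bilateral partition did not converge to ", tol_pa,
         " Pa in ", max_iter, " iterations")

  left <- lateral_pressure_drop(g, "left", q, fluid, direction, losses)
  right <- lateral_pressure_drop(g, "right", V - q, fluid, direction, losses)
  u <- list(
    left = q * MLPS / (g$profiles$left$area_mm2 * MM2),
    right = (V - q) * MLPS / (g$profiles$right$area_mm2 * MM2))
  R_left <- left$delta_p_pa / q
  R_right <- right$delta_p_pa / (V - q)
  sol <- structure(
    list(phase = phase, direction = direction, losses = losses,
         fluid = fluid,
         Q_left_mls = q, Q_right_mls = V - q,
         delta_p_pa = (left$delta_p_pa + right$delta_p_pa) / 2,
         pressure_mismatch_pa = left$delta_p_pa - right$delta_p_pa,
         p_stations_pa = list(left = left$p_stations_pa,
                              right = right$p_stations_pa),
         tau_stations_pa = list(left = left$tau_stations_pa,
                                right = right$tau_stations_pa),
         u_stations_ms = u,
         AP_pct = 100 * q / V,
         R_left = R_left, R_right = R_right,
         R_total = total_resistance(R_left, R_right),
         mach_max = max(unlist(u)) / 340,
         iterations = it),
    class = "flow_solution")
  sol
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("Flow solution (%s, %.0f ml/s, losses %s)\n",
              x$direction, x$phase$flow_mls, if (x$losses) "on" else "off"))
  cat(sprintf("  Q left/right: %.2f / %.2f ml/s (AP %.1f%%)\n",
              x$Q_left_mls, x$Q_right_mls, x$AP_pct))
  cat(sprintf("  delta p: %.3f Pa; R left/right/total: %.3f / %.3f / %.3f Pa.s/ml\n",
              x$delta_p_pa, x$R_left, x$R_right, x$R_total))
  cat(sprintf("  peak Mach %.4f\n", x$mach_max))
  invisible(x)
}

#' Per-vertex wall pressure and wall shear stress
#'
#' Every wall vertex inherits the station pressure and the viscous wall
#' shear stress of its ring, `tau = |dp/ds|_visc A / P` (the exact axial
#' force balance of fully developed flow; Borda-Carnot losses model
#' separated flow and are excluded from the wall shear).  With
#' `circumferential = TRUE` the shear is modulated around the ring
#' following the fully developed elliptical-duct boundary-gradient shape,
#' normalised to preserve the station mean.
#'
#' @param g A `duct_geometry`.
#' @param solution A `flow_solution` for `g`.
#' @param circumferential Apply circumferential modulation of the shear?
#' @return A list of two numeric vectors over vertices:
#'   `wall_pressure_pa` and `wss_pa`.
#' @export
wall_fields <- function(g, solution, circumferential = FALSE) {
  stopifnot(inherits(solution, "flow_solution"))
  nv <- nrow(g$vertices)
  pres <- numeric(nv)
  wss <- numeric(nv)
  for (side in c("left", "right")) {
    sel <- g$side_of_vertex == side
    st <- g$station_of_vertex[sel]
    pres[sel] <- solution$p_stations_pa[[side]][st]
    tau <- solution$tau_stations_pa[[side]][st]
    if (circumferential) {
      prof <- g$profiles[[side]]
      a <- prof$a_mm[st]
      b <- prof$b_mm[st]
      cs <- g$ring_dirs$cs[g$ring_of_vertex[sel]]
      sn <- g$ring_dirs$sn[g$ring_of_vertex[sel]]
      f <- sqrt(cs^2 / b^2 + sn^2 / a^2)    # boundary velocity gradient shape
      wgt <- sqrt(b^2 * sn^2 + a^2 * cs^2)  # local arc-length weight
      # normalise per station so the arc-weighted ring mean is preserved
      idx <- paste(side, st)
      mean_f <- tapply(f * wgt, idx, sum) / tapply(wgt, idx, sum)
      tau <- tau * f / as.numeric(mean_f[idx])
    }
    wss[sel] <- tau
  }
  list(wall_pressure_pa = pres, wss_pa = wss)
}

#' Simulate inspiration and expiration for one geometry
#'
#' Solves the bilateral partition for both breathing directions at the same
#' total flow rate and attaches the per-vertex wall fields.  With losses
#' off the two phases give identical resistances (Stokes reversibility);
#' with losses on they may differ, since expansions depend on direction.
#'
#' @param g A `duct_geometry`.
#' @param fluid A [fluid_properties()].
#' @param flow_mls Total flow rate in ml/s.
#' @param losses Include Borda-Carnot losses?
#' @param circumferential Passed to [wall_fields()].
#' @return A list with elements `inspiration` and `expiration`, each a
#'   `flow_solution` with `$wall` holding the vertex fields.
#' @export
simulate_phases <- function(g, fluid = fluid_properties(), flow_mls = 200,
                            losses = FALSE, circumferential = FALSE) {
  out <- lapply(c("inspiration", "expiration"), function(lbl) {
    sol <- solve_bilateral_partition(g, breathing_phase(lbl, flow_mls),
                                     fluid, losses)
    sol$wall <- wall_fields(g, sol, circumferential)
    sol
  })
  names(out) <- c("inspiration", "expiration")
  out
}
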