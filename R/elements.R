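#' Blood properties
#'
#' Blood is treated as an incompressible Newtonian fluid; the defaults are a
#' density of 1000 kg/m^3 and a dynamic viscosity of 3e-3 Pa.s.
#'
#' @param density kg/m^3, > 0.
#' @param dynamic_viscosity Pa.s, > 0.
#' @return A `blood_properties` object.
#' @export
blood_properties <- function(density = 1000, dynamic_viscosity = 3e-3) {
  if (!is.numeric(density) || density <= 0) {
    stop("blood density must be positive")
  }
  if (!is.numeric(dynamic_viscosity) || dynamic_viscosity <= 0) {
    stop("blood dynamic viscosity must be positive")
  }
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "blood_properties")
}

#' Vessel geometry
#'
#' A named vessel of the computational domain with its length, diameter
#' profile (measured stations or a scaled literature diameter), wall-thickness
#' ratio and Young's modulus.
#'
#' @param vessel_id One of [vessel_ids()].
#' @param length Vessel length in cm, > 0.
#' @param diameter_profile data.frame with columns `position` (cm, measured
#'   from the proximal/central end, within `[0, length]`) and `diameter` (mm,
#'   > 0).  A single row means a uniform calibre.
#' @param wall_thickness_ratio Wall thickness over inner radius, in (0, 0.5).
#' @param youngs_modulus Young's modulus in kPa, > 0.
#' @param is_vein Logical.
#' @return A `vessel_geometry` object.
#' @export
vessel_geometry <- function(vessel_id, length, diameter_profile,
                            wall_thickness_ratio, youngs_modulus,
                            is_vein = FALSE) {
  if (!is.numeric(length) || length <= 0) {
    stop(sprintf("vessel '%s': length must be positive", vessel_id))
  }
  dp <- as.data.frame(diameter_profile)
  if (!all(c("position", "diameter") %in% names(dp)) || nrow(dp) < 1) {
    stop(sprintf("missing vessel measurement: %s", vessel_id))
  }
  if (any(dp$diameter <= 0)) {
    stop(sprintf("vessel '%s': all diameters must be positive", vessel_id))
  }
  if (any(dp$position < -1e-9 | dp$position > length + 1e-9)) {
    stop(sprintf("vessel '%s': diameter stations outside [0, length]", vessel_id))
  }
  if (wall_thickness_ratio <= 0 || wall_thickness_ratio >= 0.5) {
    stop(sprintf("vessel '%s': wall thickness ratio must be in (0, 0.5)", vessel_id))
  }
  if (youngs_modulus <= 0) {
    stop(sprintf("vessel '%s': Young's modulus must be positive", vessel_id))
  }
  structure(list(
    vessel_id = vessel_id,
    length = length,
    diameter_profile = dp[order(dp$position), , drop = FALSE],
    wall_thickness_ratio = wall_thickness_ratio,
    youngs_modulus = youngs_modulus,
    is_vein = isTRUE(is_vein)
  ), class = "vessel_geometry")
}

#' Lumped transmission-line elements of one vessel segment
#'
#' Computes the electrical-analog element values of a single lumped segment
#' from its geometry and material properties: Poiseuille viscous resistance
#' `R = 8 mu l / (pi r^4)`, blood inertance `L = rho l / (pi r^2)` and
#' thin-wall compliance `C = 3 pi r^3 l / (2 E h)`, converted to clinical
#' units (mmHg.s/ml, mmHg.s^2/ml, ml/mmHg).
#'
#' @param seg_length Segment length in cm, >= 0 (all elements vanish at 0).
#' @param diameter Inner diameter in mm, > 0.
#' @param h_over_r Wall-thickness-to-radius ratio, in (0, 0.5).
#' @param E Young's modulus in kPa, > 0.
#' @param blood A [blood_properties()] object.
#' @param r_l_multiplier Optional side-branch leakage parameter: the leakage
#'   resistance `R_L` is this multiple of the segment's own `R` (NA = no
#'   leakage path).
#' @return List with elements `R`, `R_L`, `L`, `C`, `seg_length`, `diameter`.
#' @export
#' @examples
#' segment_elements(5, 4, 0.15, 900, blood_properties())
segment_elements <- function(seg_length, diameter, h_over_r, E,
                             blood = blood_properties(),
                             r_l_multiplier = NA_real_) {
  if (seg_length < 0) stop("segment length must be non-negative")
  if (diameter <= 0) stop("segment diameter must be positive")
  if (h_over_r <= 0 || h_over_r >= 0.5) stop("h/r must be in (0, 0.5)")
  if (E <= 0) stop("Young's modulus must be positive")
  stopifnot(inherits(blood, "blood_properties"))

  l <- cm_to_m(seg_length)
  r <- mm_to_m(diameter) / 2
  mu <- blood$dynamic_viscosity
  rho <- blood$density
  E_pa <- E * 1000
  h <- h_over_r * r

  R <- si_to_clin_resistance(8 * mu * l / (pi * r^4))
  L <- si_to_clin_inertance(rho * l / (pi * r^2))
  C <- si_to_clin_compliance(3 * pi * r^3 * l / (2 * E_pa * h))
  R_L <- if (is.na(r_l_multiplier)) NA_real_ else r_l_multiplier * R

  list(R = R, R_L = R_L, L = L, C = C,
       seg_length = seg_length, diameter = diameter)
}

#' Discretize a vessel into lumped segments
#'
#' Splits a vessel into `ceiling(length / max_seg_len)` equal-length segments
#' and evaluates each segment's elements at the diameter interpolated at the
#' segment midpoint (piecewise-linear between measured stations, linear
#' extrapolation beyond them).
#'
#' @param g A [vessel_geometry()].
#' @param max_seg_len Maximum segment length in cm (default 5).
#' @param blood A [blood_properties()] object.
#' @param r_l_multiplier Side-branch leakage multiple of each segment's R
#'   (NA = none); by default applied to venous segments in the network build.
#' @return data.frame with one row per segment: `seg`, `seg_length`,
#'   `midpoint`, `diameter`, `R`, `R_L`, `L`, `C`.
#' @export
#' @examples
#' g <- vessel_geometry("radial", 12,
#'                      data.frame(position = c(0, 12), diameter = c(4, 3)),
#'                      0.2, 900)
#' discretize_vessel(g)  # 3 segments of 4 cm; midpoint diameters 3.83/3.5/3.17
discretize_vessel <- function(g, max_seg_len = 5, blood = blood_properties(),
                              r_l_multiplier = NA_real_) {
  stopifnot(inherits(g, "vessel_geometry"))
  if (max_seg_len <= 0) stop("max_seg_len must be positive")
  n <- ceiling(g$length / max_seg_len)
  ds <- g$length / n
  mid <- (seq_len(n) - 0.5) * ds
  dia_fun <- interpolate_diameters(g$diameter_profile, g$length,
                                   vessel_id = g$vessel_id)
  dia <- dia_fun(mid)
  el <- lapply(dia, function(d) {
    segment_elements(ds, d, g$wall_thickness_ratio, g$youngs_modulus,
                     blood, r_l_multiplier)
  })
  data.frame(
    seg = seq_len(n),
    seg_length = ds,
    midpoint = mid,
    diameter = dia,
    R = vapply(el, `[[`, 0, "R"),
    R_L = vapply(el, `[[`, 0, "R_L"),
    L = vapply(el, `[[`, 0, "L"),
    C = vapply(el, `[[`, 0, "C")
  )
}

# Loss coefficient at a given anastomosis angle: linear between the 30 and 60
# degree endpoints, floored at zero.
anastomosis_K <- function(angle, K30 = 0.6, K60 = 1.2) {
  max(0, K30 + (K60 - K30) * (angle - 30) / 30)
}

#' Anastomosis element
#'
#' The artery-to-vein junction is represented by two nonlinear resistors: one
#' on the venous limb and one on the distal arterial limb.  Each produces a
#' Borda-Carnot-type quadratic pressure loss `dp = K(theta) rho q |q| / (2 A^2)`
#' that depends on the anastomosis angle through the loss coefficient
#' `K(theta)`, interpolated linearly between its 30 and 60 degree values.
#'
#' @param angle Anastomosis angle in degrees, in `[0, 90]` (default 45).
#' @param venous_limb_area Venous limb cross-section in mm^2, > 0.
#' @param distal_limb_area Distal arterial limb cross-section in mm^2, > 0.
#' @param K30,K60 Loss-coefficient endpoints at 30 and 60 degrees.
#' @return An `anastomosis_element` with per-limb `loss_coefficients`.
#' @export
anastomosis_element <- function(angle = 45, venous_limb_area, distal_limb_area,
                                K30 = 0.6, K60 = 1.2) {
  if (angle < 0 || angle > 90) stop("anastomosis angle must be in [0, 90] degrees")
  if (venous_limb_area <= 0 || distal_limb_area <= 0) {
    stop("anastomosis limb areas must be positive")
  }
  K <- anastomosis_K(angle, K30, K60)
  structure(list(
    angle = angle,
    venous_limb_area = venous_limb_area,
    distal_limb_area = distal_limb_area,
    loss_coefficients = list(venous = K, distal = K),
    K30 = K30, K60 = K60
  ), class = "anastomosis_element")
}

#' Pressure drop over an anastomosis limb
#'
#' Quadratic junction loss `dp = K rho q |q| / (2 A^2)` for the requested
#' limb: an odd, sign-preserving function of flow, linear in the loss
#' coefficient.  (A small series viscous resistance of the limb is added
#' separately during network assembly.)
#'
#' @param elem An [anastomosis_element()].
#' @param q Flow in ml/s (signed).
#' @param limb `"venous"` or `"distal"`.
#' @param blood A [blood_properties()].
#' @return Pressure drop in mmHg, same sign as `q`.
#' @export
#' @examples
#' el <- anastomosis_element(45, venous_limb_area = 5, distal_limb_area = 4)
#' anastomosis_pressure_drop(el, 10, "venous")
anastomosis_pressure_drop <- function(elem, q, limb = c("venous", "distal"),
                                      blood = blood_properties()) {
  stopifnot(inherits(elem, "anastomosis_element"))
  limb <- match.arg(limb)
  K <- elem$loss_coefficients[[limb]]
  A <- mm2_to_m2(if (limb == "venous") elem$venous_limb_area else elem$distal_limb_area)
  q_si <- q * 1e-6
  pa_to_mmhg(K * blood$density * q_si * abs(q_si) / (2 * A^2))
}

# Series viscous resistance of an anastomosis limb, modelled as a 1 cm tube
# with the limb's cross-sectional area (keeps the junction conductance finite
# at zero flow).
anastomosis_series_resistance <- function(area_mm2, blood) {
  r <- sqrt(mm2_to_m2(area_mm2) / pi)
  si_to_clin_resistance(8 * blood$dynamic_viscosity * 0.01 / (pi * r^4))
}

# Quadratic loss coefficient in clinical units: dp[mmHg] = alpha * q|q| with
# q in ml/s.
anastomosis_alpha <- function(K, area_mm2, blood) {
  A <- mm2_to_m2(area_mm2)
  K * blood$density * 1e-12 / (2 * A^2) / PA_PER_MMHG
}
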