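#' Piecewise-linear diameter profile from measured stations
#'
#' Builds a callable diameter profile from discrete duplex-ultrasound
#' stations: piecewise-linear between stations, linear extrapolation beyond
#' the outermost pair (constant when only one station exists), with a
#' positive floor that guards against nonphysical extrapolated diameters.
#'
#' @param stations data.frame with columns `position` (cm) and `diameter`
#'   (mm); at least one row.
#' @param vessel_length Vessel length in cm (used only for validation of the
#'   query range; queries are clamped to the profile's domain of validity).
#' @param floor_mm Minimum returned diameter in mm (default 0.5).
#' @param vessel_id Vessel name used in the error message when no stations
#'   are available.
#' @return A function mapping axial positions (cm) to diameters (mm).
#' @export
#' @examples
#' f <- interpolate_diameters(data.frame(position = c(0, 10),
#'                                       diameter = c(3, 4)), 10)
#' f(5)  # 3.5
interpolate_diameters <- function(stations, vessel_length, floor_mm = 0.5,
                                  vessel_id = "vessel") {
  st <- as.data.frame(stations)
  if (nrow(st) == 0) {
    stop(sprintf("missing vessel measurement: %s", vessel_id))
  }
  st <- st[order(st$position), , drop = FALSE]
  pos <- st$position
  dia <- st$diameter
  if (length(pos) == 1) {
    d0 <- max(dia, floor_mm)
    return(function(x) rep(d0, length(x)))
  }
  function(x) {
    y <- stats::approx(pos, dia, xout = x, rule = 2)$y
    n <- length(pos)
    lo <- x < pos[1]
    hi <- x > pos[n]
    if (any(lo)) {
      s <- (dia[2] - dia[1]) / (pos[2] - pos[1])
      y[lo] <- dia[1] + s * (x[lo] - pos[1])
    }
    if (any(hi)) {
      s <- (dia[n] - dia[n - 1]) / (pos[n] - pos[n - 1])
      y[hi] <- dia[n] + s * (x[hi] - pos[n])
    }
    pmax(y, floor_mm)
  }
}

#' Wall thickness from vessel identity and radius
#'
#' Applies the fixed wall-thickness-to-radius ratios: 15% for the subclavian,
#' axillary and brachial artery, 20% for the radial, ulnar and interosseus
#' artery, 10% for all veins, and literature ratios for the remaining
#' (central) arteries.
#'
#' @param vessel_id One of [vessel_ids()].
#' @param radius Inner radius in mm, > 0.
#' @return Wall thickness in mm.
#' @export
#' @examples
#' wall_thickness("axillary_brachial", 2.0)  # 0.30
wall_thickness <- function(vessel_id, radius) {
  if (any(radius <= 0)) stop("radius must be positive")
  wall_thickness_ratio(vessel_id) * radius
}

#' @rdname wall_thickness
#' @export
wall_thickness_ratio <- function(vessel_id) {
  lit <- literature_geometry()
  if (!vessel_id %in% lit$vessel_id) {
    stop(sprintf("unknown vessel: %s", vessel_id))
  }
  row <- lit[lit$vessel_id == vessel_id, ]
  if (row$is_vein == 1) return(0.10)
  if (vessel_id %in% c("left_subclavian", "right_subclavian", "axillary_brachial")) {
    return(0.15)
  }
  if (vessel_id %in% c("radial", "proximal_ulnar", "distal_ulnar", "interosseus")) {
    return(0.20)
  }
  row$h_over_r
}

#' Young's modulus from arterial distensibility
#'
#' Estimates the brachial artery Young's modulus from a wall-tracking
#' distension waveform and a simultaneous non-invasive pressure waveform.
#' Distensibility is computed from the systolic-diastolic excursions,
#' `D = (A_sys - A_dia) / (A_dia * (p_sys - p_dia))`, and mapped to a
#' thin-wall incompressible modulus `E = 3 / (2 D (h/r))`.  The brachial
#' modulus is applied to all arterial arm segments.
#'
#' @param distension_waveform data.frame `time` (s), `diameter` (mm) over at
#'   least one cardiac cycle.
#' @param pressure_waveform data.frame `time` (s), `pressure` (mmHg) over the
#'   same cycle.
#' @param diastolic_diameter Diastolic diameter in mm; defaults to the
#'   waveform minimum.
#' @param wall_thickness Wall thickness in mm at the diastolic radius.
#' @return Young's modulus in kPa.
#' @export
youngs_modulus_from_distensibility <- function(distension_waveform,
                                               pressure_waveform,
                                               diastolic_diameter = NULL,
                                               wall_thickness) {
  d <- distension_waveform$diameter
  p <- pressure_waveform$pressure
  if (is.null(diastolic_diameter)) diastolic_diameter <- min(d)
  pulse_pressure <- max(p) - min(p)
  if (pulse_pressure <= 0) stop("pulse pressure must be positive")
  a_dia <- pi * diastolic_diameter^2 / 4
  a_sys <- pi * max(d)^2 / 4
  if (a_sys - a_dia <= 0) {
    stop("rigid vessel: no measurable distension over the cardiac cycle")
  }
  D <- (a_sys - a_dia) / (a_dia * pulse_pressure) # 1/mmHg
  h_over_r <- wall_thickness / (diastolic_diameter / 2)
  mmhg_to_kpa(3 / (2 * D * h_over_r))
}

#' Screen vessel calibres for fistula suitability
#'
#' A vessel is considered of adequate calibre for fistula creation when all
#' of its measured diameters exceed 2 mm (strict inequality on the minimum
#' over stations).
#'
#' @param record A [patient_record()].
#' @param threshold_mm Calibre threshold in mm (default 2).
#' @return Named character vector, `"adequate"`/`"inadequate"` per measured
#'   vessel.
#' @export
caliber_screen <- function(record, threshold_mm = 2) {
  stopifnot(inherits(record, "patient_record"))
  dus <- record$dus_diameters
  mins <- tapply(dus$diameter, dus$vessel_id, min)
  out <- ifelse(mins > threshold_mm, "adequate", "inadequate")
  out[order(names(out))]
}

#' Scale the literature aortic geometry to the measured arm calibre
#'
#' Diameters of the aorta and its primary branches are literature values
#' multiplied by the ratio of the measured to the literature subclavian
#' diameter (falling back to the most proximal measured brachial station when
#' no subclavian measurement exists).  Lengths are unchanged.
#'
#' @param lit Output of [literature_geometry()].
#' @param dus_diameters data.frame `vessel_id`, `position`, `diameter` of the
#'   measured stations.
#' @param side `"left"` or `"right"` (selects which subclavian is measured).
#' @return Named list of scaled diameters (mm) for the non-measured vessels,
#'   plus the scaling factor as attribute `"factor"`.
#' @export
scale_aortic_geometry <- function(lit, dus_diameters, side = "left") {
  subcl <- paste0(side, "_subclavian")
  ref <- dus_diameters[dus_diameters$vessel_id == subcl, ]
  if (nrow(ref) > 0) {
    factor <- ref$diameter[which.min(ref$position)] /
      lit$diameter_mm[lit$vessel_id == subcl]
  } else {
    br <- dus_diameters[dus_diameters$vessel_id == "axillary_brachial", ]
    if (nrow(br) == 0) stop("missing vessel measurement: subclavian or brachial artery")
    factor <- br$diameter[which.min(br$position)] /
      lit$diameter_mm[lit$vessel_id == "axillary_brachial"]
  }
  scaled_ids <- setdiff(lit$vessel_id, dus_vessels())
  scaled_ids <- scaled_ids[lit$is_vein[match(scaled_ids, lit$vessel_id)] == 0]
  out <- lit$diameter_mm[match(scaled_ids, lit$vessel_id)] * factor
  names(out) <- scaled_ids
  attr(out, "factor") <- factor
  out
}

#' Anastomosis placement for a fistula configuration
#'
#' The anastomosis sits 5 cm proximal to the wrist on the radial artery for a
#' radiocephalic fistula, and 5 cm proximal to the elbow bifurcation on the
#' brachial artery for the elbow fistulas.  With axial position measured from
#' the proximal end of the host artery, that is 5 cm short of its distal end.
#' The default angle is 45 degrees with a plausible 30-60 degree range.
#'
#' @param configuration `"RC-AVF"`, `"BC-AVF"` or `"BB-AVF"`.
#' @param geometries Named list of [vessel_geometry()] objects.
#' @param offset_cm Distance from the distal end of the host artery (default 5).
#' @return List with `artery`, `position` (cm from the proximal end),
#'   `angle` (degrees) and `angle_range`.
#' @export
place_anastomosis <- function(configuration, geometries, offset_cm = 5) {
  artery <- switch(configuration,
    "RC-AVF" = "radial",
    "BC-AVF" = "axillary_brachial",
    "BB-AVF" = "axillary_brachial",
    stop(sprintf("no anastomosis for configuration '%s'", configuration))
  )
  g <- geometries[[artery]]
  if (is.null(g)) stop(sprintf("incomplete domain: %s", vessel_display_name(artery)))
  if (g$length <= offset_cm) {
    stop(sprintf("vessel '%s' (%.1f cm) shorter than anastomosis offset %.1f cm",
                 artery, g$length, offset_cm))
  }
  list(artery = artery, position = g$length - offset_cm,
       angle = 45, angle_range = c(30, 60))
}

vessel_display_name <- function(vessel_id) {
  lit <- literature_geometry()
  i <- match(vessel_id, lit$vessel_id)
  ifelse(is.na(i), vessel_id, tolower(lit$vessel_name[i]))
}

#' Build the personalized vessel geometry set for one patient
#'
#' Converts a patient measurement record into the full set of vessel
#' geometries: measured upper-extremity vessels get their duplex stations as
#' diameter profiles; the aorta and primary branches get literature diameters
#' scaled to the measured arm calibre; arm arterial Young's modulus comes
#' from brachial distensibility; veins and central vessels use literature
#' moduli.  Veins with no measured stations are omitted (configurations that
#' need them will report an incomplete domain).
#'
#' @param record A [patient_record()].
#' @param overrides Optional perturbations, as produced by the uncertainty
#'   layer: named list with any of `diameter_scale` (named per-vessel factors),
#'   `length_scale` (named per-vessel factors), `E_scale` (named factors for
#'   `arm`, `veins`, `aorta`), `angle`, `venous_pressure`, `wk_R_scale`,
#'   `wk_C_scale`, `leak_multiplier`.
#' @return A `personalization` list: `geometries`, `arm_E` (kPa), `angle`,
#'   `venous_pressure` (mmHg), `leak_multiplier`, `wk_R_scale`, `wk_C_scale`,
#'   `blood`, `side`.
#' @export
personalize_patient <- function(record, overrides = list()) {
  stopifnot(inherits(record, "patient_record"))
  lit <- literature_geometry()
  side <- record$side
  dus <- record$dus_diameters

  dscale <- overrides$diameter_scale %||% numeric(0)
  lscale <- overrides$length_scale %||% numeric(0)
  escale <- overrides$E_scale %||% numeric(0)
  scl <- function(tab, id) if (id %in% names(tab)) tab[[id]] else 1

  h_mm <- wall_thickness("axillary_brachial",
                         radius = brachial_diastolic_diameter(record) / 2)
  arm_E <- youngs_modulus_from_distensibility(
    record$distension_waveform, record$pressure_waveform,
    wall_thickness = h_mm
  ) * scl(escale, "arm")

  scaled <- scale_aortic_geometry(lit, dus, side)

  contralateral <- if (side == "left") "right_subclavian" else "left_subclavian"
  geoms <- list()
  for (i in seq_len(nrow(lit))) {
    vid <- lit$vessel_id[i]
    is_vein <- lit$is_vein[i] == 1
    length_i <- lit$length_cm[i] * scl(lscale, vid)
    measured <- dus[dus$vessel_id == vid, c("position", "diameter")]
    if (nrow(measured) > 0) {
      profile <- measured
      # a perturbed length stretches the vessel; stations sit at fixed
      # anatomic fractions of it
      profile$position <- profile$position * scl(lscale, vid)
    } else if (is_vein) {
      next # no literature fallback for veins: patient-specific by necessity
    } else if (vid %in% names(scaled)) {
      profile <- data.frame(position = 0, diameter = scaled[[vid]])
    } else if (vid == "interosseus") {
      profile <- data.frame(position = 0,
                            diameter = lit$diameter_mm[i] * attr(scaled, "factor"))
    } else if (vid == contralateral) {
      profile <- data.frame(position = 0,
                            diameter = lit$diameter_mm[i] * attr(scaled, "factor"))
    } else {
      stop(sprintf("missing vessel measurement: %s", vessel_display_name(vid)))
    }
    profile$diameter <- profile$diameter * scl(dscale, vid)
    E_i <- if (is_vein) {
      lit$E_kPa[i] * scl(escale, "veins")
    } else if (vid %in% arm_arteries()) {
      arm_E
    } else {
      lit$E_kPa[i] * scl(escale, "aorta")
    }
    geoms[[vid]] <- vessel_geometry(vid, length_i, profile,
                                    wall_thickness_ratio(vid), E_i,
                                    is_vein = is_vein)
  }

  list(
    geometries = geoms,
    arm_E = arm_E,
    angle = overrides$angle %||% 45,
    venous_pressure = overrides$venous_pressure %||% record$venous_pressure,
    leak_multiplier = overrides$leak_multiplier %||% 100,
    wk_R_scale = overrides$wk_R_scale %||% 1,
    wk_C_scale = overrides$wk_C_scale %||% 1,
    blood = blood_properties(),
    side = side
  )
}

brachial_diastolic_diameter <- function(record) {
  min(record$distension_waveform$diameter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
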