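# Synthetic patients.  No measured cohort ships with the package, so a
# generator emulates the statistical structure the pipeline assumes:
# physiologic diameter ranges with distal taper, consistent flow splits, a
# two-phase pulsatile aortic waveform whose mean matches the stated cardiac
# output, and distension/pressure waveforms constructed from a prescribed
# distensibility.

#' Specification of a synthetic patient cohort
#'
#' Ranges (uniform unless noted) from which per-patient values are drawn.
#' The defaults emulate a typical adult pre-dialysis population: brachial
#' artery 3.5-6 mm tapering to the elbow, radial/ulnar arteries 1.5-3.5 mm,
#' cephalic/basilic veins 1.5-4.5 mm (spanning both sides of the 2 mm
#' calibre screen), mean arterial pressure 70-120 mmHg, cardiac period
#' 0.7-1.2 s, cardiac output 3.5-7 l/min with 4-9% to the arm.
#'
#' @param n_patients Cohort size (default 25).
#' @param seed Integer seed.
#' @param brachial_mm,radial_mm,ulnar_mm,cephalic_mm,basilic_mm,
#'   subclavian_vein_mm Diameter ranges (mm) at the proximal station.
#' @param taper Per-vessel distal/proximal diameter ratio range.
#' @param map_mmhg Mean arterial pressure range (mmHg).
#' @param pulse_pressure_mmhg Pulse pressure range (mmHg).
#' @param cardiac_period_s Cardiac period range (s).
#' @param cardiac_output_lmin Cardiac output range (l/min).
#' @param arm_fraction Fraction of cardiac output to the arm.
#' @param radial_fraction Radial share of the brachial flow.
#' @param systolic_fraction Systolic fraction of the cycle (waveform shape).
#' @param distensibility_per_mmhg Brachial distensibility range (1/mmHg).
#' @return A `cohort_spec` list.
#' @export
default_cohort_spec <- function(n_patients = 25, seed = 20120404,
                                brachial_mm = c(3.5, 6.0),
                                radial_mm = c(1.6, 3.4),
                                ulnar_mm = c(1.6, 3.2),
                                cephalic_mm = c(1.5, 4.5),
                                basilic_mm = c(2.0, 4.5),
                                subclavian_vein_mm = c(6, 10),
                                taper = c(0.75, 0.95),
                                map_mmhg = c(70, 120),
                                pulse_pressure_mmhg = c(35, 60),
                                cardiac_period_s = c(0.7, 1.2),
                                cardiac_output_lmin = c(3.5, 7.0),
                                arm_fraction = c(0.04, 0.09),
                                radial_fraction = c(0.35, 0.50),
                                systolic_fraction = c(0.30, 0.38),
                                distensibility_per_mmhg = c(0.7e-3, 2e-3)) {
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate one synthetic patient
#'
#' Deterministic under `(spec$seed, index)`.  Diameters taper distally;
#' radial + ulnar mean flows sum exactly to the brachial flow; the aortic
#' flow waveform is a systolic half-sine with zero diastolic flow whose mean
#' equals the cardiac output.
#'
#' @param spec A [default_cohort_spec()].
#' @param index Patient index (1-based).
#' @return A [patient_record()].
#' @export
generate_patient <- function(spec, index) {
  stopifnot(inherits(spec, "cohort_spec"), index >= 1)
  seed_i <- (as.integer(spec$seed) %% 1000003L) * 2011L + as.integer(index) * 7L
  set.seed(seed_i %% 2147483587L)
  U <- function(r) stats::runif(1, r[1], r[2])
  tap <- function() U(spec$taper)

  side <- sample(c("left", "right"), 1)
  d_brach <- U(spec$brachial_mm)
  d_rad <- min(U(spec$radial_mm), 0.85 * d_brach)
  d_uln <- min(U(spec$ulnar_mm), 0.85 * d_brach)
  d_ceph <- U(spec$cephalic_mm)
  d_bas <- U(spec$basilic_mm)

  subcl <- paste0(side, "_subclavian")
  stations <- rbind(
    data.frame(vessel_id = subcl, position = 1.7,
               diameter = d_brach * stats::runif(1, 1.3, 1.6)),
    data.frame(vessel_id = "axillary_brachial",
               position = c(5, 20, 35),
               diameter = d_brach * cumprod(c(1, stats::runif(1, 0.9, 0.98),
                                              tap()))),
    data.frame(vessel_id = "radial", position = c(1, 12, 22),
               diameter = d_rad * cumprod(c(1, stats::runif(1, 0.85, 0.97),
                                            tap()))),
    data.frame(vessel_id = "proximal_ulnar", position = 3, diameter = d_uln),
    data.frame(vessel_id = "distal_ulnar", position = c(2, 15),
               diameter = d_uln * c(0.95, 0.95 * tap())),
    data.frame(vessel_id = "distal_cephalic", position = c(5, 13, 22),
               diameter = d_ceph * cumprod(c(1, stats::runif(1, 0.85, 0.97),
                                             tap()))),
    data.frame(vessel_id = "median_cubital", position = 2,
               diameter = d_ceph * stats::runif(1, 1.0, 1.3)),
    data.frame(vessel_id = "proximal_cephalic", position = c(4, 20),
               diameter = d_ceph * stats::runif(1, 1.05, 1.35) * c(1, tap())),
    data.frame(vessel_id = "basilic", position = c(4, 20),
               diameter = d_bas * c(1, tap())),
    data.frame(vessel_id = "axillary_subclavian_vein", position = 8,
               diameter = U(spec$subclavian_vein_mm))
  )

  map <- U(spec$map_mmhg)
  pp <- U(spec$pulse_pressure_mmhg)
  period <- U(spec$cardiac_period_s)
  co <- U(spec$cardiac_output_lmin) * 1000 # ml/min

  # Flow splits consistent with the sampled anatomy, as they are in a real
  # patient: the radial/ulnar split follows the Poiseuille calibre weights
  # (clamped into the configured range), and the arm flow is capped so the
  # serial viscous pressure drop along each arterial path stays below 60% of
  # the perfusion pressure - leaving headroom for the peripheral beds and
  # for the uncertainty layer's diameter perturbations.
  arm_frac <- U(spec$arm_fraction)
  q_brach <- arm_frac * co
  d_r4 <- mean(stations$diameter[stations$vessel_id == "radial"])^4
  d_u4 <- mean(stations$diameter[stations$vessel_id == "proximal_ulnar"])^4
  rad_frac <- min(max(d_r4 / (d_r4 + d_u4), spec$radial_fraction[1]),
                  spec$radial_fraction[2])

  path_resistance <- function(vid, length_cm) {
    st <- stations[stations$vessel_id == vid, c("position", "diameter")]
    g <- vessel_geometry(vid, length_cm, st, 0.2, 900)
    sum(discretize_vessel(g)$R)
  }
  lit <- literature_geometry()
  len <- function(vid) lit$length_cm[lit$vessel_id == vid]
  scale_f <- stations$diameter[stations$vessel_id == subcl] / 8.5
  r_sub <- path_resistance(subcl, len(ifelse(side == "left",
                                             "left_subclavian",
                                             "right_subclavian")))
  r_brach <- path_resistance("axillary_brachial", len("axillary_brachial"))
  r_rad <- path_resistance("radial", len("radial"))
  r_uln <- path_resistance("proximal_ulnar", len("proximal_ulnar"))
  r_uld <- path_resistance("distal_ulnar", len("distal_ulnar"))
  g_io <- vessel_geometry("interosseus", len("interosseus"),
                          data.frame(position = 0, diameter = 1.8 * scale_f),
                          0.2, 900)
  r_io <- sum(discretize_vessel(g_io)$R)

  qb <- mlmin_to_mls(q_brach)
  qr <- rad_frac * qb; qu <- (1 - rad_frac) * qb
  common <- (r_sub + r_brach) * qb
  drops <- c(common + r_rad * qr,
             common + r_uln * qu + r_uld * 0.8 * qu,
             common + r_uln * qu + r_io * 0.2 * qu)
  headroom <- 0.6 * (map - 10)
  feas <- min(1, headroom / max(drops))
  q_brach <- q_brach * feas

  mean_flows <- c(aorta = co, brachial = q_brach,
                  radial = rad_frac * q_brach,
                  ulnar = (1 - rad_frac) * q_brach)

  fs <- U(spec$systolic_fraction)
  q_mean <- mlmin_to_mls(co)
  q_peak <- q_mean * pi / (2 * fs)
  tt <- seq(0, period, length.out = 257)
  qq <- ifelse(tt < fs * period, q_peak * sin(pi * tt / (fs * period)), 0)
  aortic_wf <- data.frame(time = tt, flow = qq)

  dia_p <- map - pp / 3
  p_t <- dia_p + pp * ifelse(tt < fs * period,
                             sin(pi * tt / (fs * period)),
                             pmax(0, 1 - (tt - fs * period) / (0.35 * period))^2 * 0.15)
  pressure_wf <- data.frame(time = tt, pressure = p_t)

  D <- U(spec$distensibility_per_mmhg)
  d_dia <- d_brach
  dist_wf <- data.frame(time = tt,
                        diameter = d_dia * sqrt(1 + D * (p_t - min(p_t))))

  patient_record(
    patient_id = sprintf("synthetic-%d", index),
    side = side,
    dus_diameters = stations,
    distension_waveform = dist_wf,
    pressure_waveform = pressure_wf,
    map_pressure = map,
    mean_flows = mean_flows,
    aortic_flow_waveform = aortic_wf,
    cardiac_period = period
  )
}

#' Generate a synthetic cohort
#'
#' @param spec A [default_cohort_spec()].
#' @return List of [patient_record()]s of length `spec$n_patients`.
#' @export
generate_cohort <- function(spec = default_cohort_spec()) {
  lapply(seq_len(spec$n_patients), function(i) generate_patient(spec, i))
}

#' Degrade a patient record into a documented failure mode
#'
#' Produces records reproducing the clinically observed failure scenarios so
#' the error paths are testable: a thrombosed (non-visualizable) cephalic
#' vein makes the cephalic configurations unsimulable; a small radial artery
#' fails the calibre screen and yields low radiocephalic flow; a missing
#' station exercises the constant-extrapolation fallback of the diameter
#' interpolation.
#'
#' @param record A [patient_record()].
#' @param scenario One of `"thrombosed_cephalic"`, `"small_radial"`,
#'   `"missing_station"`.
#' @return The degraded `patient_record`.
#' @export
degrade_patient <- function(record,
                            scenario = c("thrombosed_cephalic", "small_radial",
                                         "missing_station")) {
  scenario <- match.arg(scenario)
  dus <- record$dus_diameters
  if (scenario == "thrombosed_cephalic") {
    drop <- c("distal_cephalic", "proximal_cephalic", "median_cubital")
    record$dus_diameters <- dus[!dus$vessel_id %in% drop, , drop = FALSE]
  } else if (scenario == "small_radial") {
    i <- dus$vessel_id == "radial"
    dus$diameter[i] <- pmin(dus$diameter[i], 1.6)
    record$dus_diameters <- dus
  } else {
    i <- which(dus$vessel_id == "distal_ulnar")
    if (length(i) > 1) record$dus_diameters <- dus[-i[-1], , drop = FALSE]
  }
  record
}
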