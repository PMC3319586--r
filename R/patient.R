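#' Patient measurement record
#'
#' The per-patient inputs of the pipeline: duplex-ultrasound diameter
#' stations, the brachial distension and finger-pressure waveforms (for
#' Young's modulus), mean arterial pressure, magnetic-resonance mean flows
#' at four sites, the preoperative aortic flow waveform, and the cardiac
#' period.
#'
#' @param patient_id Identifier.
#' @param side `"left"` or `"right"`.
#' @param dus_diameters data.frame `vessel_id`, `position` (cm from the
#'   proximal end), `diameter` (mm, > 0).
#' @param distension_waveform data.frame `time` (s), `diameter` (mm) over at
#'   least one cardiac cycle.
#' @param pressure_waveform data.frame `time` (s), `pressure` (mmHg).
#' @param map_pressure Mean arterial pressure in mmHg.
#' @param mean_flows Named numeric (ml/min): `aorta`, `brachial`, `radial`,
#'   `ulnar`.
#' @param aortic_flow_waveform data.frame `time` (s), `flow` (ml/s) over one
#'   cardiac cycle.
#' @param cardiac_period Cardiac period in s, in (0.3, 2).
#' @param venous_pressure Central venous pressure in mmHg (default 10).
#' @return A validated `patient_record`.
#' @export
patient_record <- function(patient_id, side, dus_diameters,
                           distension_waveform, pressure_waveform,
                           map_pressure, mean_flows, aortic_flow_waveform,
                           cardiac_period, venous_pressure = 10) {
  rec <- structure(list(
    patient_id = patient_id,
    side = match.arg(side, c("left", "right")),
    dus_diameters = as.data.frame(dus_diameters),
    distension_waveform = as.data.frame(distension_waveform),
    pressure_waveform = as.data.frame(pressure_waveform),
    map_pressure = map_pressure,
    mean_flows = unlist(mean_flows),
    aortic_flow_waveform = as.data.frame(aortic_flow_waveform),
    cardiac_period = cardiac_period,
    venous_pressure = venous_pressure
  ), class = "patient_record")
  validate_patient_record(rec)
  rec
}

#' @rdname patient_record
#' @param record A `patient_record` to validate.
#' @export
validate_patient_record <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  if (any(record$dus_diameters$diameter <= 0)) {
    stop("all measured diameters must be positive")
  }
  if (record$cardiac_period <= 0.3 || record$cardiac_period >= 2.0) {
    stop("cardiac period must lie in (0.3, 2.0) s")
  }
  mf <- record$mean_flows
  req <- c("aorta", "brachial", "radial", "ulnar")
  if (!all(req %in% names(mf))) {
    stop("mean_flows must contain aorta, brachial, radial and ulnar")
  }
  if (any(mf[req] <= 0)) stop("mean flows must be positive")
  if (mf[["aorta"]] < mf[["brachial"]]) {
    stop("mean aortic flow must be at least the arm (brachial) flow")
  }
  if (mf[["radial"]] + mf[["ulnar"]] > 1.05 * mf[["brachial"]]) {
    stop("radial + ulnar mean flow exceeds the brachial flow")
  }
  wf <- record$aortic_flow_waveform
  wf_mean <- waveform_mean(wf$time, wf$flow)
  if (abs(mls_to_mlmin(wf_mean) - mf[["aorta"]]) > 0.05 * mf[["aorta"]]) {
    stop("aortic waveform mean inconsistent with the measured mean aortic flow")
  }
  if (record$map_pressure <= record$venous_pressure) {
    stop("mean arterial pressure must exceed the venous pressure")
  }
  invisible(record)
}

waveform_mean <- function(t, v) {
  sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2) /
    (t[length(t)] - t[1])
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s (%s arm): MAP %.0f mmHg, CO %.0f ml/min, T %.2f s\n",
              x$patient_id, x$side, x$map_pressure, x$mean_flows[["aorta"]],
              x$cardiac_period))
  cat(sprintf("  DUS stations: %d on %d vessels\n", nrow(x$dus_diameters),
              length(unique(x$dus_diameters$vessel_id))))
  invisible(x)
}
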