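# Clinical decision rule: a configuration is an option for fistula creation
# when the predicted postoperative flow lies in the 400-1500 ml/min window;
# among eligible options the preference order is radiocephalic >
# brachiocephalic > brachiobasilic (most distal first, preserving proximal
# vessels for future access).

#' Assess one configuration against the flow window
#'
#' The decision statistic is the Monte-Carlo median flow.  A configuration
#' is eligible when the median lies inside the (inclusive) window; medians
#' below the floor raise a low-flow (non-maturation) flag, medians above the
#' ceiling a high-flow (steal / cardiac-failure risk) flag.
#'
#' @param flow A `flow_distribution`.
#' @param thresholds Flow window in ml/min (default `c(400, 1500)`).
#' @param cardiac_output Optional cardiac output in ml/min; when given, the
#'   30%-of-cardiac-output steal flag is evaluated too.
#' @return A `configuration_assessment`: `configuration`, `flow`, `eligible`,
#'   `reasons`, `risk_flags` (`low_flow`, `high_flow`, `cardiac_steal`).
#' @export
assess_configuration <- function(flow, thresholds = c(400, 1500),
                                 cardiac_output = NULL) {
  stopifnot(inherits(flow, "flow_distribution"))
  if (!flow$simulable || flow$n_converged < 1) {
    return(structure(list(
      configuration = flow$configuration, flow = flow, eligible = FALSE,
      reasons = "not assessable: no converged simulation",
      risk_flags = c(low_flow = FALSE, high_flow = FALSE, cardiac_steal = FALSE)
    ), class = "configuration_assessment"))
  }
  m <- flow$median
  low <- m < thresholds[1]
  high <- m > thresholds[2]
  eligible <- !low && !high
  steal <- if (!is.null(cardiac_output)) {
    cardiac_steal_flag(m, cardiac_output)
  } else FALSE
  reasons <- character(0)
  if (low) reasons <- c(reasons, sprintf(
    "median flow %.0f ml/min below the %.0f ml/min floor (non-maturation risk)",
    m, thresholds[1]))
  if (high) reasons <- c(reasons, sprintf(
    "median flow %.0f ml/min above the %.0f ml/min ceiling (steal/cardiac risk)",
    m, thresholds[2]))
  if (steal) reasons <- c(reasons, "predicted flow exceeds 30% of cardiac output")
  structure(list(
    configuration = flow$configuration, flow = flow, eligible = eligible,
    reasons = reasons,
    risk_flags = c(low_flow = low, high_flow = high, cardiac_steal = steal)
  ), class = "configuration_assessment")
}

#' @export
print.configuration_assessment <- function(x, ...) {
  cat(sprintf("<assessment> %s: %s%s\n", x$configuration,
              if (x$eligible) "eligible" else "not eligible",
              if (length(x$reasons)) paste0(" (", paste(x$reasons, collapse = "; "), ")")
              else ""))
  invisible(x)
}

#' Recommend a fistula configuration
#'
#' Applies the preference order radiocephalic > brachiocephalic >
#' brachiobasilic to the per-configuration assessments: the first eligible
#' configuration is selected; unsimulable or missing configurations are
#' skipped with an annotation; when none is eligible the recommendation is
#' none.
#'
#' @param assessments Named list of `configuration_assessment` objects (any
#'   subset of `RC-AVF`, `BC-AVF`, `BB-AVF`).
#' @param surgeon_choice Optional configuration chosen by the surgeon, for
#'   the agreement field.
#' @return A `recommendation`: `candidates` (ordered data.frame), `selected`
#'   (configuration or NA), `notes`, `agreement` (NA when no surgeon choice
#'   given).
#' @export
recommend_configuration <- function(assessments, surgeon_choice = NULL) {
  order_pref <- c("RC-AVF", "BC-AVF", "BB-AVF")
  if (length(assessments) == 0) stop("at least one assessment is required")
  notes <- character(0)
  rows <- list()
  selected <- NA_character_
  for (cfg in order_pref) {
    a <- assessments[[cfg]]
    if (is.null(a)) {
      notes <- c(notes, sprintf("%s: not assessed", cfg))
      rows[[cfg]] <- data.frame(configuration = cfg, median = NA_real_,
                                p25 = NA_real_, p75 = NA_real_,
                                eligible = NA, stringsAsFactors = FALSE)
      next
    }
    stopifnot(inherits(a, "configuration_assessment"))
    if (!a$flow$simulable) {
      notes <- c(notes, sprintf("%s: not simulable", cfg))
    }
    rows[[cfg]] <- data.frame(
      configuration = cfg, median = a$flow$median, p25 = a$flow$p25,
      p75 = a$flow$p75, eligible = a$eligible, stringsAsFactors = FALSE)
    if (is.na(selected) && isTRUE(a$eligible)) selected <- cfg
  }
  agreement <- if (!is.null(surgeon_choice)) {
    identical(surgeon_choice, selected)
  } else NA
  structure(list(
    candidates = do.call(rbind, rows),
    selected = selected,
    notes = notes,
    surgeon_choice = if (is.null(surgeon_choice)) NA_character_ else surgeon_choice,
    agreement = agreement
  ), class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat("<recommendation>\n")
  print(x$candidates, row.names = FALSE)
  cat(sprintf("selected: %s\n",
              if (is.na(x$selected)) "none (no configuration eligible)" else x$selected))
  if (length(x$notes)) cat(paste0("  ", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' Cardiac steal / high-output risk flag
#'
#' Postoperative access flows above 30% of the cardiac output carry an
#' increased risk of cardiac failure and hand ischemia.
#'
#' @param flow Predicted flow in ml/min.
#' @param cardiac_output Cardiac output in ml/min, > 0.
#' @param fraction Risk threshold as a fraction of cardiac output
#'   (default 0.30).
#' @return TRUE when `flow > fraction * cardiac_output` (strict).
#' @export
cardiac_steal_flag <- function(flow, cardiac_output, fraction = 0.30) {
  if (cardiac_output <= 0) stop("cardiac output must be positive")
  flow > fraction * cardiac_output
}

#' Project the matured flow from the immediate postoperative flow
#'
#' Immediately after surgery, lower-arm fistulas carry roughly 60-70% of
#' their flow after successful maturation, elbow fistulas 90-100%.  The
#' projection divides the immediate flow by those fractions; it is reported
#' as context only and plays no role in eligibility.
#'
#' @param flow Immediate postoperative flow in ml/min, >= 0.
#' @param configuration Configuration (`RC-AVF` = lower arm; `BC-AVF`,
#'   `BB-AVF` = elbow).
#' @return Numeric length-2 projected matured-flow interval in ml/min.
#' @export
maturation_projection <- function(flow, configuration) {
  if (flow < 0) stop("flow must be non-negative")
  fr <- if (configuration == "RC-AVF") c(0.7, 0.6) else c(1.0, 0.9)
  c(flow / fr[1], flow / fr[2])
}

#' Doppler-ultrasound measured flow interval
#'
#' Converts the time-averaged outer envelope of the Doppler velocity
#' spectrum times the B-mode cross-sectional area into a volume flow, and
#' brackets the unknown velocity profile between parabolic (0.5x) and flat
#' (1.0x).
#'
#' @param velocity_envelope data.frame `time` (s), `velocity` (cm/s) over at
#'   least one cycle.
#' @param vessel_area Cross-sectional area in mm^2, > 0.
#' @return List: `raw` (ml/min) and `interval` (`c(0.5, 1) * raw`, ml/min).
#' @export
#' @examples
#' env <- data.frame(time = seq(0, 1, 0.01), velocity = 50)
#' dus_measured_flow_interval(env, 20)  # raw 600, interval 300-600 ml/min
dus_measured_flow_interval <- function(velocity_envelope, vessel_area) {
  if (vessel_area <= 0) stop("vessel area must be positive")
  t <- velocity_envelope$time
  v <- velocity_envelope$velocity
  if (length(t) < 2) stop("velocity envelope must span at least one cycle")
  vbar <- sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2) /
    (t[length(t)] - t[1])
  # cm/s * mm^2 = 1e-8 m^3/s = 0.6 ml/min
  raw <- vbar * vessel_area * 0.6
  list(raw = raw, interval = c(0.5 * raw, 1.0 * raw))
}

#' Overlap between predicted and measured flow
#'
#' @param predicted A `flow_distribution` (its 25th-75th percentile interval
#'   is used).
#' @param measured_interval Numeric length-2 measured flow interval in
#'   ml/min.
#' @return `"overlap"` or `"no_overlap"` (closed-interval intersection).
#' @export
prediction_overlap <- function(predicted, measured_interval) {
  stopifnot(inherits(predicted, "flow_distribution"),
            length(measured_interval) == 2)
  if (!predicted$simulable) stop("predicted distribution is empty")
  lo <- min(measured_interval); hi <- max(measured_interval)
  if (predicted$p25 <= hi && lo <= predicted$p75) "overlap" else "no_overlap"
}
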