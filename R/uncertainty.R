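# Uncertainty propagation: every uncertain input is given a uniform range
# (nominal +/- half-width, absolute or relative), the joint input space is
# sampled by Latin Hypercube sampling, and the predicted postoperative flow
# distribution is summarized by its median and 25th-75th percentile interval.

#' Uncertainty specification for the model inputs
#'
#' One row per uncertain parameter: a `path` naming what is perturbed, the
#' `nominal` value, a `half_width`, and whether the half-width is `relative`
#' (fractional) or absolute.  Sampling is uniform on
#' `nominal +/- half_width` (times `nominal` when relative).
#'
#' Recognized paths: `diameter/<vessel_id>` and `length/<vessel_id>`
#' (relative scale factors), `E/arm`, `E/veins`, `E/aorta` (relative),
#' `wk/R` and `wk/C` (relative scale of all terminal resistances /
#' compliances), `anastomosis/angle` (degrees, absolute), `venous_pressure`
#' (mmHg, absolute), `leak/multiplier` (relative).
#'
#' @param path,nominal,half_width,relative Vectors of equal length.
#' @return An `uncertainty_spec` data.frame.
#' @export
uncertainty_spec <- function(path, nominal, half_width, relative) {
  stopifnot(length(path) == length(nominal),
            length(path) == length(half_width),
            length(path) == length(relative))
  if (any(half_width < 0)) stop("half-widths must be non-negative")
  structure(
    data.frame(path = path, nominal = nominal, half_width = half_width,
               relative = relative, stringsAsFactors = FALSE),
    class = c("uncertainty_spec", "data.frame")
  )
}

#' Default uncertainty specification for a patient
#'
#' Measurement-precision-scale default half-widths: arterial diameters
#' +/-10%, venous diameters +/-20%, vessel lengths +/-10%, Young's moduli
#' +/-20%, windkessel resistances +/-20%, anastomosis angle 45 +/- 15 degrees
#' (i.e. the plausible 30-60 degree range), venous pressure +/- 5 mmHg, and
#' the venous side-branch leakage multiplier +/-50%.  All are overridable by
#' editing the returned table.
#'
#' @param record A [patient_record()].
#' @return An `uncertainty_spec`.
#' @export
default_uncertainty_spec <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  lit <- literature_geometry()
  measured <- sort(unique(record$dus_diameters$vessel_id))
  is_vein <- lit$is_vein[match(measured, lit$vessel_id)] == 1

  path <- c(
    paste0("diameter/", measured),
    paste0("length/", c(arm_arteries(), vein_vessels())),
    "E/arm", "E/veins", "E/aorta",
    "wk/R",
    "anastomosis/angle",
    "venous_pressure",
    "leak/multiplier"
  )
  nominal <- c(
    rep(1, length(measured)),
    rep(1, length(arm_arteries()) + length(vein_vessels())),
    1, 1, 1,
    1,
    45,
    record$venous_pressure,
    1
  )
  half_width <- c(
    ifelse(is_vein, 0.20, 0.10),
    rep(0.10, length(arm_arteries()) + length(vein_vessels())),
    0.20, 0.20, 0.20,
    0.20,
    15,
    5,
    0.50
  )
  relative <- c(
    rep(TRUE, length(measured)),
    rep(TRUE, length(arm_arteries()) + length(vein_vessels())),
    TRUE, TRUE, TRUE,
    TRUE,
    FALSE,
    FALSE,
    TRUE
  )
  uncertainty_spec(path, nominal, half_width, relative)
}

#' Latin Hypercube sample of an uncertainty specification
#'
#' Draws `n_runs` joint parameter sets such that, for every parameter, the
#' samples occupy each of the `n_runs` equal-probability strata of its
#' uniform range exactly once.
#'
#' @param spec An [uncertainty_spec()].
#' @param n_runs Number of runs, >= 2.
#' @param seed Integer seed; the sample is reproducible under it.
#' @return A data.frame (`n_runs` rows, one column per parameter path) of
#'   parameter values, with the underlying unit-cube sample in attribute
#'   `"unit"`.
#' @export
lhs_sample <- function(spec, n_runs, seed) {
  stopifnot(inherits(spec, "uncertainty_spec"), n_runs >= 2)
  k <- nrow(spec)
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(n_runs, k)
  vals <- matrix(NA_real_, n_runs, k)
  for (j in seq_len(k)) {
    hw <- if (spec$relative[j]) spec$half_width[j] * abs(spec$nominal[j])
          else spec$half_width[j]
    vals[, j] <- spec$nominal[j] + (2 * u[, j] - 1) * hw
  }
  out <- as.data.frame(vals)
  names(out) <- spec$path
  attr(out, "unit") <- u
  out
}

# Translate one sampled parameter row into personalization overrides.
parameter_set_to_overrides <- function(row) {
  ov <- list(diameter_scale = list(), length_scale = list(), E_scale = list())
  for (p in names(row)) {
    v <- row[[p]]
    if (startsWith(p, "diameter/")) {
      ov$diameter_scale[[sub("diameter/", "", p)]] <- v
    } else if (startsWith(p, "length/")) {
      ov$length_scale[[sub("length/", "", p)]] <- v
    } else if (startsWith(p, "E/")) {
      ov$E_scale[[sub("E/", "", p)]] <- v
    } else if (p == "wk/R") {
      ov$wk_R_scale <- v
    } else if (p == "wk/C") {
      ov$wk_C_scale <- v
    } else if (p == "anastomosis/angle") {
      ov$angle <- min(90, max(0, v))
    } else if (p == "venous_pressure") {
      ov$venous_pressure <- v
    } else if (p == "leak/multiplier") {
      ov$leak_multiplier <- 100 * v
    } else {
      stop(sprintf("unknown uncertainty path '%s'", p))
    }
  }
  ov
}

#' Monte-Carlo flow prediction under input uncertainty
#'
#' Runs one postoperative flow prediction per Latin-Hypercube parameter set
#' and summarizes the predicted mean brachial flows.  Runs whose simulation
#' or baroreflex iteration fails to converge are counted and excluded from
#' the percentiles (computed by linear interpolation between order
#' statistics).
#'
#' @param record A [patient_record()].
#' @param configuration Fistula configuration.
#' @param spec An [uncertainty_spec()]; default from
#'   [default_uncertainty_spec()].
#' @param n_runs Number of Monte-Carlo runs (default 256).
#' @param seed Integer seed.
#' @param controls A [simulation_controls()].
#' @return A `flow_distribution`: per-run `flows` (ml/min, NA when not
#'   converged), `n_requested`, `n_converged`, `median`, `p25`, `p75`,
#'   `seed`, `configuration`, `simulable`.
#' @export
run_monte_carlo <- function(record, configuration,
                            spec = default_uncertainty_spec(record),
                            n_runs = 256, seed = 1,
                            controls = simulation_controls()) {
  samples <- lhs_sample(spec, n_runs, seed)
  flows <- rep(NA_real_, n_runs)
  for (i in seq_len(n_runs)) {
    ov <- parameter_set_to_overrides(samples[i, , drop = FALSE])
    pred <- tryCatch(
      predict_postop_flow(record, configuration, overrides = ov,
                          controls = controls),
      error = function(e) NULL
    )
    if (!is.null(pred) && isTRUE(pred$converged)) flows[i] <- pred$flow
  }
  flow_distribution(flows, n_requested = n_runs, seed = seed,
                    configuration = configuration)
}

#' Flow distribution summary
#'
#' @param flows Per-run predicted flows in ml/min (NA = run not converged).
#' @param n_requested Number of runs requested.
#' @param seed Seed used for the sample.
#' @param configuration Configuration label.
#' @return A `flow_distribution` object.
#' @export
flow_distribution <- function(flows, n_requested = length(flows), seed = NA,
                              configuration = NA_character_) {
  ok <- flows[!is.na(flows)]
  qs <- if (length(ok) > 0) {
    stats::quantile(ok, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  } else c(NA_real_, NA_real_, NA_real_)
  structure(list(
    flows = flows,
    n_requested = n_requested,
    n_converged = length(ok),
    median = qs[2], p25 = qs[1], p75 = qs[3],
    seed = seed,
    configuration = configuration,
    simulable = length(ok) > 0
  ), class = "flow_distribution")
}

#' @export
print.flow_distribution <- function(x, ...) {
  if (x$simulable) {
    cat(sprintf(
      "<flow_distribution> %s: median %.0f ml/min [25th-75th: %.0f-%.0f], %d/%d runs converged\n",
      x$configuration, x$median, x$p25, x$p75, x$n_converged, x$n_requested))
  } else {
    cat(sprintf("<flow_distribution> %s: configuration not simulable (%d runs failed)\n",
                x$configuration, x$n_requested))
  }
  invisible(x)
}
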