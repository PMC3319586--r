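#' Literature reference geometry for the computational domain
#'
#' Returns the packaged table of generic adult vessel geometry used wherever a
#' patient-specific measurement is unavailable: vessel lengths, representative
#' diameters, wall-thickness-to-radius ratios, Young's moduli, and the
#' literature flow weights used to distribute the unmeasured share of cardiac
#' output over central windkessel terminals.  The 20 vessels are the named
#' vessels of the computational domain (aorta and primary branches, the
#' upper-extremity arteries, and the cephalic/basilic venous outflow
#' trajectories).
#'
#' Values are literature-informed defaults for a generic adult; upper-extremity
#' diameters are always replaced by duplex ultrasound measurements during
#' personalization, and aortic-branch diameters are rescaled to the measured
#' arm calibre (see [scale_aortic_geometry()]).
#'
#' @return A data.frame with columns `vessel_id`, `vessel_name`, `length_cm`,
#'   `diameter_mm`, `h_over_r`, `E_kPa`, `is_vein` (0/1) and `terminal_weight`.
#' @export
#' @examples
#' lit <- literature_geometry()
#' lit[lit$vessel_id == "radial", ]
literature_geometry <- function() {
  path <- system.file("extdata", "literature_geometry.csv", package = "avfplan")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Names of all vessels in the computational domain
#'
#' @return Character vector of the 20 vessel identifiers.
#' @export
vessel_ids <- function() literature_geometry()$vessel_id

# Vessels whose diameters come from the preoperative duplex examination.
# Remaining vessels are scaled literature geometry.
dus_vessels <- function() {
  c(
    "left_subclavian", "right_subclavian", "axillary_brachial", "radial",
    "proximal_ulnar", "distal_ulnar",
    "distal_cephalic", "median_cubital", "proximal_cephalic", "basilic",
    "axillary_subclavian_vein"
  )
}

arm_arteries <- function() {
  c("axillary_brachial", "radial", "proximal_ulnar", "distal_ulnar", "interosseus")
}

vein_vessels <- function() {
  c("distal_cephalic", "median_cubital", "proximal_cephalic", "basilic",
    "axillary_subclavian_vein")
}

# Literature share of the ulnar trunk flow taken by the interosseus artery.
INTEROSSEUS_FRACTION <- 0.2
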