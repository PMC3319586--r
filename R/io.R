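# Structured-text serialization (YAML, versioned schema) for patient
# records, uncertainty specifications and network domain specifications,
# plus two-column CSV helpers for waveforms.

SCHEMA_VERSION <- 1L

df_to_list <- function(df) lapply(as.list(df), function(col) unname(col))
list_to_df <- function(lst) as.data.frame(lapply(lst, unlist))

#' Read and write patient records
#'
#' Patient records are stored as a single versioned YAML document, waveforms
#' included as parallel time/value arrays.
#'
#' @param record A [patient_record()].
#' @param path File path (conventionally `.yaml`).
#' @return `write_patient_record` invisibly returns `path`;
#'   `read_patient_record` returns the validated `patient_record`.
#' @export
write_patient_record <- function(record, path) {
  stopifnot(inherits(record, "patient_record"))
  doc <- list(
    schema = "avfplan/patient_record",
    schema_version = SCHEMA_VERSION,
    patient_id = record$patient_id,
    side = record$side,
    map_pressure = record$map_pressure,
    cardiac_period = record$cardiac_period,
    venous_pressure = record$venous_pressure,
    mean_flows = as.list(record$mean_flows),
    dus_diameters = df_to_list(record$dus_diameters),
    distension_waveform = df_to_list(record$distension_waveform),
    pressure_waveform = df_to_list(record$pressure_waveform),
    aortic_flow_waveform = df_to_list(record$aortic_flow_waveform)
  )
  writeLines(yaml::as.yaml(doc, precision = 12L), path)
  invisible(path)
}

#' @rdname write_patient_record
#' @export
read_patient_record <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "avfplan/patient_record")) {
    stop(sprintf("'%s' is not a patient record document", path))
  }
  patient_record(
    patient_id = doc$patient_id,
    side = doc$side,
    dus_diameters = list_to_df(doc$dus_diameters),
    distension_waveform = list_to_df(doc$distension_waveform),
    pressure_waveform = list_to_df(doc$pressure_waveform),
    map_pressure = doc$map_pressure,
    mean_flows = unlist(doc$mean_flows),
    aortic_flow_waveform = list_to_df(doc$aortic_flow_waveform),
    cardiac_period = doc$cardiac_period,
    venous_pressure = doc$venous_pressure
  )
}

#' Read and write uncertainty specifications
#'
#' @param spec An [uncertainty_spec()].
#' @param path File path.
#' @export
write_uncertainty_spec <- function(spec, path) {
  stopifnot(inherits(spec, "uncertainty_spec"))
  doc <- list(schema = "avfplan/uncertainty_spec",
              schema_version = SCHEMA_VERSION,
              parameters = df_to_list(as.data.frame(spec)))
  writeLines(yaml::as.yaml(doc, precision = 12L), path)
  invisible(path)
}

#' @rdname write_uncertainty_spec
#' @export
read_uncertainty_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "avfplan/uncertainty_spec")) {
    stop(sprintf("'%s' is not an uncertainty specification", path))
  }
  p <- list_to_df(doc$parameters)
  uncertainty_spec(p$path, p$nominal, p$half_width, p$relative)
}

#' Serialize a network domain specification
#'
#' Writes the geometry-level description of a network - one section per
#' vessel (id, length, diameter stations, wall ratio, Young's modulus), the
#' terminal parameters, and the anastomosis - as a versioned YAML document
#' from which the network can be rebuilt.
#'
#' @param network A `vascular_network`.
#' @param path File path.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "vascular_network"))
  vessels <- lapply(network$geometries, function(g) {
    list(vessel_id = g$vessel_id, length = g$length,
         diameter_stations = df_to_list(g$diameter_profile),
         wall_thickness_ratio = g$wall_thickness_ratio,
         youngs_modulus = g$youngs_modulus, is_vein = g$is_vein)
  })
  an <- network$anastomosis
  doc <- list(
    schema = "avfplan/network",
    schema_version = SCHEMA_VERSION,
    configuration = network$configuration,
    side = network$side,
    blood = list(density = network$blood$density,
                 dynamic_viscosity = network$blood$dynamic_viscosity),
    vessels = vessels,
    terminals = df_to_list(network$terminals),
    anastomosis = if (is.null(an)) NULL else list(
      host = an$host, angle = an$elem$angle,
      venous_limb_area = an$elem$venous_limb_area,
      distal_limb_area = an$elem$distal_limb_area)
  )
  writeLines(yaml::as.yaml(doc, precision = 12L), path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "avfplan/network")) {
    stop(sprintf("'%s' is not a network document", path))
  }
  geoms <- lapply(doc$vessels, function(v) {
    vessel_geometry(v$vessel_id, v$length, list_to_df(v$diameter_stations),
                    v$wall_thickness_ratio, v$youngs_modulus, v$is_vein)
  })
  names(geoms) <- vapply(doc$vessels, `[[`, "", "vessel_id")
  blood <- blood_properties(doc$blood$density, doc$blood$dynamic_viscosity)
  angle <- if (is.null(doc$anastomosis)) 45 else doc$anastomosis$angle
  net <- build_domain(doc$configuration, doc$side, geoms, blood = blood,
                      angle = angle)
  term <- list_to_df(doc$terminals)
  if (!anyNA(term$R_wk)) net <- attach_terminals(net, term)
  net
}

#' Two-column waveform CSV helpers
#'
#' @param waveform data.frame with a `time` column and one value column.
#' @param path File path.
#' @export
write_waveform_csv <- function(waveform, path) {
  utils::write.csv(waveform, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
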