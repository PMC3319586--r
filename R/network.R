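# Network assembly: the computational domain is a directed tree (plus, after
# virtual surgery, one arteriovenous shunt path) of lumped segments.  Nodes
# carry compliance (half of each adjacent segment's C) and optional leakage
# to the venous reference pressure; branches carry R and L.  Node 0 denotes
# the external prescribed-pressure reference (the central venous outflow).

EXTERNAL_NODE <- 0L

config_choices <- function() c("RC-AVF", "BC-AVF", "BB-AVF", "preoperative")

required_veins <- function(configuration) {
  switch(configuration,
    "RC-AVF" = c("distal_cephalic", "median_cubital", "proximal_cephalic",
                 "axillary_subclavian_vein"),
    "BC-AVF" = c("proximal_cephalic", "axillary_subclavian_vein"),
    "BB-AVF" = c("basilic", "axillary_subclavian_vein"),
    "preoperative" = character(0)
  )
}

# Discretize the portion [from_pos, to_pos] of a vessel (positions in cm from
# the proximal end); midpoints are evaluated in the vessel's own coordinates.
discretize_portion <- function(g, from_pos, to_pos, max_seg_len = 5,
                               blood = blood_properties(),
                               r_l_multiplier = NA_real_) {
  len <- to_pos - from_pos
  stopifnot(len > 0)
  n <- ceiling(len / max_seg_len)
  ds <- len / n
  mid <- from_pos + (seq_len(n) - 0.5) * ds
  dia_fun <- interpolate_diameters(g$diameter_profile, g$length,
                                   vessel_id = g$vessel_id)
  dia <- dia_fun(mid)
  el <- lapply(dia, function(d) {
    segment_elements(ds, d, g$wall_thickness_ratio, g$youngs_modulus,
                     blood, r_l_multiplier)
  })
  data.frame(
    seg = seq_len(n), seg_length = ds, midpoint = mid, diameter = dia,
    R = vapply(el, `[[`, 0, "R"), R_L = vapply(el, `[[`, 0, "R_L"),
    L = vapply(el, `[[`, 0, "L"), C = vapply(el, `[[`, 0, "C")
  )
}

new_network_builder <- function(blood) {
  env <- new.env(parent = emptyenv())
  env$n_nodes <- 0L
  env$node_label <- character(0)
  env$node_C <- numeric(0)
  env$node_leak_g <- numeric(0)
  env$branches <- list()
  env$terminals <- list()
  env$blood <- blood
  env
}

nb_new_node <- function(env, label) {
  env$n_nodes <- env$n_nodes + 1L
  env$node_label[env$n_nodes] <- label
  env$node_C[env$n_nodes] <- 0
  env$node_leak_g[env$n_nodes] <- 0
  env$n_nodes
}

nb_add_branch <- function(env, from, to, R, L, vessel_id, seg, part) {
  env$branches[[length(env$branches) + 1L]] <-
    list(from = from, to = to, R = R, L = L,
         vessel_id = vessel_id, seg = seg, part = part)
  length(env$branches)
}

# Add a chain of segments for vessel portion [from_pos, to_pos] starting at
# `start`; returns the end node (or EXTERNAL_NODE when end_external).
# `reverse` traverses the vessel from its distal towards its proximal end
# (used for veins, where flow runs towards the central circulation).
nb_add_chain <- function(env, g, start, from_pos = 0, to_pos = g$length,
                         reverse = FALSE, leak_multiplier = NA_real_,
                         end_external = FALSE, part = "main",
                         max_seg_len = 5) {
  segs <- discretize_portion(g, from_pos, to_pos, max_seg_len, env$blood,
                             leak_multiplier)
  if (reverse) segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  node <- start
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    last <- i == nrow(segs)
    nxt <- if (last && end_external) EXTERNAL_NODE
           else nb_new_node(env, sprintf("%s:%s:%d", g$vessel_id, part, i))
    nb_add_branch(env, node, nxt, s$R, s$L, g$vessel_id, s$seg, part)
    env$node_C[node] <- env$node_C[node] + s$C / 2
    if (nxt != EXTERNAL_NODE) env$node_C[nxt] <- env$node_C[nxt] + s$C / 2
    if (!is.na(s$R_L)) {
      leak_node <- if (nxt == EXTERNAL_NODE) node else nxt
      env$node_leak_g[leak_node] <- env$node_leak_g[leak_node] + 1 / s$R_L
    }
    node <- nxt
  }
  node
}

nb_add_terminal <- function(env, node, vessel_id) {
  env$terminals[[length(env$terminals) + 1L]] <-
    list(node = node, vessel_id = vessel_id)
}

#' Build the computational domain for a fistula configuration
#'
#' Assembles the lumped-parameter network for the requested configuration:
#' the aorta and its primary branches, the arm arterial tree on the surgical
#' side, windkessel terminal placeholders on every peripheral artery, and -
#' for the postoperative configurations - the anastomosis element and the
#' venous outflow trajectory ending at the prescribed central venous
#' pressure.  The preoperative configuration contains no anastomosis and no
#' venous segments.
#'
#' @param configuration One of `"RC-AVF"`, `"BC-AVF"`, `"BB-AVF"`,
#'   `"preoperative"`.
#' @param side `"left"` or `"right"`: the arm carrying the (planned) fistula.
#' @param geometries Named list of [vessel_geometry()] objects covering the
#'   vessels the configuration requires; a missing vessel raises an
#'   "incomplete domain" error naming it.
#' @param blood A [blood_properties()].
#' @param angle Anastomosis angle in degrees (postoperative configurations).
#' @param leak_multiplier Venous side-branch leakage resistance as a multiple
#'   of each venous segment's own viscous resistance.
#' @param max_seg_len Maximum lumped-segment length in cm (default 5).
#' @return A `vascular_network` object.
#' @export
#' @examples
#' \dontrun{
#' rec <- generate_patient(default_cohort_spec(seed = 1), 1)
#' pers <- personalize_patient(rec)
#' net <- build_domain("RC-AVF", rec$side, pers$geometries)
#' }
build_domain <- function(configuration, side, geometries,
                         blood = blood_properties(), angle = 45,
                         leak_multiplier = 100, max_seg_len = 5) {
  configuration <- match.arg(configuration, config_choices())
  side <- match.arg(side, c("left", "right"))

  arteries <- setdiff(vessel_ids(), vein_vessels())
  needed <- c(arteries, required_veins(configuration))
  missing <- setdiff(needed, names(geometries))
  if (length(missing) > 0) {
    stop(sprintf("incomplete domain: %s",
                 paste(vessel_display_name(missing), collapse = ", ")))
  }

  env <- new_network_builder(blood)
  G <- geometries
  anast <- NULL

  root <- nb_new_node(env, "aortic_root")
  n_asc <- nb_add_chain(env, G$ascending_aorta, root)

  add_arm <- function(start_node) {
    nb_add_chain(env, G$vertebral, start_node)
    vt_end <- env$n_nodes
    nb_add_terminal(env, vt_end, "vertebral")

    host_split <- configuration %in% c("BC-AVF", "BB-AVF")
    if (host_split) {
      pos <- place_anastomosis(configuration, G)$position
      junction <- nb_add_chain(env, G$axillary_brachial, start_node,
                               to_pos = pos, part = "prox")
      env$monitor_branch <- length(env$branches)
      n_d <- nb_new_node(env, "axillary_brachial:distal_entry")
      elbow <- nb_add_chain(env, G$axillary_brachial, n_d, from_pos = pos,
                            part = "dist")
      anast_host <- list(junction = junction, distal_entry = n_d,
                         split_pos = pos, host = "axillary_brachial")
    } else {
      elbow <- nb_add_chain(env, G$axillary_brachial, start_node)
      env$monitor_branch <- length(env$branches)
      anast_host <- NULL
    }

    radial_split <- configuration == "RC-AVF"
    if (radial_split) {
      pos <- place_anastomosis(configuration, G)$position
      junction <- nb_add_chain(env, G$radial, elbow, to_pos = pos,
                               part = "prox")
      n_d <- nb_new_node(env, "radial:distal_entry")
      hand <- nb_add_chain(env, G$radial, n_d, from_pos = pos, part = "dist")
      nb_add_terminal(env, hand, "radial")
      anast_host <- list(junction = junction, distal_entry = n_d,
                         split_pos = pos, host = "radial")
    } else {
      hand <- nb_add_chain(env, G$radial, elbow)
      nb_add_terminal(env, hand, "radial")
    }

    u <- nb_add_chain(env, G$proximal_ulnar, elbow)
    io <- nb_add_chain(env, G$interosseus, u)
    nb_add_terminal(env, io, "interosseus")
    ud <- nb_add_chain(env, G$distal_ulnar, u)
    nb_add_terminal(env, ud, "distal_ulnar")
    anast_host
  }

  # central tree; the arm hangs off the surgical side's subclavian
  n_innom <- nb_add_chain(env, G$innominate, n_asc)
  rc_end <- nb_add_chain(env, G$right_carotid, n_innom)
  nb_add_terminal(env, rc_end, "right_carotid")
  n_rsub <- nb_add_chain(env, G$right_subclavian, n_innom)
  anast_host <- NULL
  if (side == "right") anast_host <- add_arm(n_rsub)
  else nb_add_terminal(env, n_rsub, "right_subclavian")

  n_a1 <- nb_add_chain(env, G$aortic_arch_a1, n_asc)
  lc_end <- nb_add_chain(env, G$left_carotid, n_a1)
  nb_add_terminal(env, lc_end, "left_carotid")
  n_a2 <- nb_add_chain(env, G$aortic_arch_a2, n_a1)
  n_lsub <- nb_add_chain(env, G$left_subclavian, n_a2)
  if (side == "left") anast_host <- add_arm(n_lsub)
  else nb_add_terminal(env, n_lsub, "left_subclavian")
  th_end <- nb_add_chain(env, G$thoracic_aorta, n_a2)
  nb_add_terminal(env, th_end, "thoracic_aorta")

  # venous outflow trajectory and anastomosis (postoperative only)
  if (configuration != "preoperative") {
    first_vein <- switch(configuration,
      "RC-AVF" = "distal_cephalic", "BC-AVF" = "proximal_cephalic",
      "BB-AVF" = "basilic")
    gv <- G[[first_vein]]
    vein_entry_dia <- interpolate_diameters(gv$diameter_profile, gv$length,
                                            vessel_id = first_vein)(gv$length)
    gh <- G[[anast_host$host]]
    dist_dia <- interpolate_diameters(gh$diameter_profile, gh$length,
                                      vessel_id = anast_host$host)(anast_host$split_pos)
    elem <- anastomosis_element(
      angle = angle,
      venous_limb_area = pi * vein_entry_dia^2 / 4,
      distal_limb_area = pi * dist_dia^2 / 4
    )

    v_entry <- nb_new_node(env, sprintf("%s:venous_entry", first_vein))
    node <- nb_add_chain(env, gv, v_entry, reverse = TRUE,
                         leak_multiplier = leak_multiplier, part = "vein")
    if (configuration == "RC-AVF") {
      node <- nb_add_chain(env, G$median_cubital, node, reverse = TRUE,
                           leak_multiplier = leak_multiplier, part = "vein")
      node <- nb_add_chain(env, G$proximal_cephalic, node, reverse = TRUE,
                           leak_multiplier = leak_multiplier, part = "vein")
    }
    nb_add_chain(env, G$axillary_subclavian_vein, node, reverse = TRUE,
                 leak_multiplier = leak_multiplier, end_external = TRUE,
                 part = "vein")

    anast <- list(
      elem = elem,
      junction = anast_host$junction,
      vein_entry = v_entry,
      distal_entry = anast_host$distal_entry,
      host = anast_host$host,
      R_visc_venous = anastomosis_series_resistance(elem$venous_limb_area, blood),
      R_visc_distal = anastomosis_series_resistance(elem$distal_limb_area, blood),
      alpha_venous = anastomosis_alpha(elem$loss_coefficients$venous,
                                       elem$venous_limb_area, blood),
      alpha_distal = anastomosis_alpha(elem$loss_coefficients$distal,
                                       elem$distal_limb_area, blood)
    )
  }

  br <- do.call(rbind, lapply(env$branches, function(b) {
    data.frame(from = b$from, to = b$to, R = b$R, L = b$L,
               vessel_id = b$vessel_id, seg = b$seg, part = b$part)
  }))
  br$branch <- seq_len(nrow(br))
  term <- do.call(rbind, lapply(env$terminals, function(t) {
    data.frame(node = t$node, vessel_id = t$vessel_id,
               Z_wk = NA_real_, R_wk = NA_real_, C_wk = NA_real_)
  }))

  structure(list(
    nodes = data.frame(node = seq_len(env$n_nodes), label = env$node_label,
                       C = env$node_C, leak_g = env$node_leak_g),
    branches = br,
    terminals = term,
    anastomosis = anast,
    inflow_node = root,
    monitor_branch = env$monitor_branch,
    blood = blood,
    configuration = configuration,
    side = side,
    geometries = geometries
  ), class = "vascular_network")
}

#' @export
print.vascular_network <- function(x, ...) {
  cat(sprintf("<vascular_network> %s (%s arm)\n", x$configuration, x$side))
  cat(sprintf("  %d nodes, %d segments, %d windkessel terminals, anastomosis: %s\n",
              nrow(x$nodes), nrow(x$branches), nrow(x$terminals),
              if (is.null(x$anastomosis)) "none"
              else sprintf("%s @ %.0f deg", x$anastomosis$host,
                           x$anastomosis$elem$angle)))
  invisible(x)
}

#' Personalize the windkessel terminals from pressure and flow measurements
#'
#' Assigns each peripheral windkessel a total resistance consistent with the
#' measured mean arterial pressure and mean flows.  Mean flow targets per
#' terminal are: the measured radial and ulnar flows (rescaled to sum to the
#' measured brachial flow) with a fixed literature share of the ulnar trunk
#' for the interosseus artery; the remaining cardiac output is distributed
#' over the central terminals by literature weights.  Branch mean flows then
#' follow from conservation on the preoperative tree, node pressures from the
#' serial viscous drops below the measured mean arterial pressure at the
#' aortic root, and each terminal's total resistance from Ohm's law over the
#' remaining pressure difference to the venous pressure.  The total is split
#' as `Z_wk = z_fraction * R_total`, `R_wk = (1 - z_fraction) * R_total`,
#' with `C_wk = tau / R_wk`.
#'
#' @param network A preoperative `vascular_network`.
#' @param map_pressure Mean arterial pressure in mmHg.
#' @param mean_flows Named numeric (ml/min) with entries `aorta`, `brachial`,
#'   `radial`, `ulnar`.
#' @param venous_pressure Venous reference pressure in mmHg (default 10).
#' @param z_fraction Characteristic-impedance share of the total terminal
#'   resistance (default 0.1).
#' @param tau Peripheral time constant `R_wk * C_wk` in seconds (default 1.5).
#' @return data.frame mapping terminal `vessel_id`/`node` to `Z_wk`, `R_wk`,
#'   `C_wk` (clinical units).
#' @export
personalize_windkessels <- function(network, map_pressure, mean_flows,
                                    venous_pressure = 10,
                                    z_fraction = 0.1, tau = 1.5) {
  stopifnot(inherits(network, "vascular_network"))
  if (is.null(network$anastomosis) == FALSE) {
    stop("windkessels are personalized on the preoperative network")
  }
  req <- c("aorta", "brachial", "radial", "ulnar")
  if (!all(req %in% names(mean_flows))) {
    stop("mean_flows must contain aorta, brachial, radial and ulnar entries")
  }
  q <- mlmin_to_mls(unlist(mean_flows[req]))
  if (any(q <= 0)) stop("mean flows must be positive")
  if (q[["aorta"]] < q[["brachial"]]) {
    stop("inconsistent measurements: aortic flow below brachial flow")
  }

  q_r <- q[["brachial"]] * q[["radial"]] / (q[["radial"]] + q[["ulnar"]])
  q_utrunk <- q[["brachial"]] - q_r
  q_int <- INTEROSSEUS_FRACTION * q_utrunk
  q_ud <- q_utrunk - q_int

  term <- network$terminals
  targets <- setNames(rep(NA_real_, nrow(term)), term$vessel_id)
  targets["radial"] <- q_r
  targets["interosseus"] <- q_int
  targets["distal_ulnar"] <- q_ud

  pool <- names(targets)[is.na(targets)]
  lit <- literature_geometry()
  w <- lit$terminal_weight[match(pool, lit$vessel_id)]
  q_rest <- q[["aorta"]] - q[["brachial"]]
  if (q_rest <= 0) stop("inconsistent measurements: no flow left for central terminals")
  targets[pool] <- q_rest * w / sum(w)

  # branch mean flows by conservation (branches are created parent-first)
  br <- network$branches
  demand <- numeric(nrow(network$nodes))
  demand[term$node] <- targets[match(term$vessel_id, names(targets))]
  flow <- numeric(nrow(br))
  for (i in rev(seq_len(nrow(br)))) {
    flow[i] <- demand[br$to[i]]
    demand[br$from[i]] <- demand[br$from[i]] + flow[i]
  }

  p <- numeric(nrow(network$nodes))
  p[network$inflow_node] <- map_pressure
  for (i in seq_len(nrow(br))) {
    p[br$to[i]] <- p[br$from[i]] - br$R[i] * flow[i]
  }

  r_tot <- (p[term$node] - venous_pressure) / targets[match(term$vessel_id, names(targets))]
  if (any(r_tot <= 0)) {
    bad <- term$vessel_id[r_tot <= 0][1]
    stop(sprintf(
      "inconsistent measurements: modeled serial resistance exceeds the total towards the %s terminal",
      bad))
  }
  data.frame(
    node = term$node,
    vessel_id = term$vessel_id,
    Z_wk = z_fraction * r_tot,
    R_wk = (1 - z_fraction) * r_tot,
    C_wk = tau / ((1 - z_fraction) * r_tot),
    row.names = NULL
  )
}

#' Attach (personalized) windkessel terminals to a network
#'
#' Terminals are matched by the vessel they close, so a set personalized on
#' the preoperative network can be carried unchanged to the postoperative
#' configurations.
#'
#' @param network A `vascular_network`.
#' @param wk data.frame from [personalize_windkessels()].
#' @param R_scale,C_scale Optional scale factors applied to the resistances
#'   (`Z_wk`, `R_wk`) and compliances (exposed to the uncertainty layer).
#' @return The network with populated terminal parameters.
#' @export
attach_terminals <- function(network, wk, R_scale = 1, C_scale = 1) {
  stopifnot(inherits(network, "vascular_network"))
  i <- match(network$terminals$vessel_id, wk$vessel_id)
  if (anyNA(i)) {
    stop(sprintf("no windkessel for terminal vessel %s",
                 network$terminals$vessel_id[which(is.na(i))[1]]))
  }
  network$terminals$Z_wk <- wk$Z_wk[i] * R_scale
  network$terminals$R_wk <- wk$R_wk[i] * R_scale
  network$terminals$C_wk <- wk$C_wk[i] * C_scale
  network
}
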