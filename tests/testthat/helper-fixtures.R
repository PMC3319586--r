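# Shared fixtures, memoized so expensive simulations run once per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_patient <- function() {
  memo("patient", generate_patient(default_cohort_spec(), 4))
}

fixture_personalization <- function() {
  memo("pers", personalize_patient(fixture_patient()))
}

# Preoperative network with personalized terminals, plus its simulation.
fixture_preop <- function() {
  memo("preop", {
    rec <- fixture_patient()
    pers <- fixture_personalization()
    net <- build_domain("preoperative", rec$side, pers$geometries)
    wk <- personalize_windkessels(net, rec$map_pressure, rec$mean_flows)
    net <- attach_terminals(net, wk)
    list(network = net, wk = wk,
         result = simulate_network(net, rec$aortic_flow_waveform,
                                   rec$cardiac_period))
  })
}

# Minimal hand-built network: one node closed by a single windkessel.
single_windkessel_network <- function(Z = 5, R_wk = 45, C_wk = 1e-4,
                                      C_node = 1e-6) {
  structure(list(
    nodes = data.frame(node = 1L, label = "n1", C = C_node, leak_g = 0),
    branches = data.frame(from = integer(0), to = integer(0), R = numeric(0),
                          L = numeric(0), vessel_id = character(0),
                          seg = integer(0), part = character(0),
                          branch = integer(0)),
    terminals = data.frame(node = 1L, vessel_id = "single", Z_wk = Z,
                           R_wk = R_wk, C_wk = C_wk),
    anastomosis = NULL,
    inflow_node = 1L,
    monitor_branch = NULL,
    blood = blood_properties(),
    configuration = "preoperative",
    side = "left",
    geometries = list()
  ), class = "vascular_network")
}

# Strip all reactive elements so the network is purely resistive.
zero_reactive <- function(network) {
  network$nodes$C <- 0
  network$branches$L <- 0
  network$terminals$C_wk <- 0
  network
}

# Independent direct solve of a resistive network with constant inflow:
# assembles the conductance Laplacian from the network tables and solves for
# the node pressures (windkessels as a series Z + R path to the venous
# reference).
resistive_oracle <- function(network, q_in, p_ven) {
  n <- nrow(network$nodes)
  Gm <- matrix(0, n, n)
  rhs <- numeric(n)
  br <- network$branches
  for (b in seq_len(nrow(br))) {
    g <- 1 / br$R[b]
    i <- br$from[b]; j <- br$to[b]
    if (i > 0 && j > 0) {
      Gm[i, i] <- Gm[i, i] + g; Gm[i, j] <- Gm[i, j] - g
      Gm[j, j] <- Gm[j, j] + g; Gm[j, i] <- Gm[j, i] - g
    } else if (j == 0) {
      Gm[i, i] <- Gm[i, i] + g; rhs[i] <- rhs[i] + g * p_ven
    } else {
      Gm[j, j] <- Gm[j, j] + g; rhs[j] <- rhs[j] + g * p_ven
    }
  }
  for (t_i in seq_len(nrow(network$terminals))) {
    k <- network$terminals$node[t_i]
    g <- 1 / (network$terminals$Z_wk[t_i] + network$terminals$R_wk[t_i])
    Gm[k, k] <- Gm[k, k] + g
    rhs[k] <- rhs[k] + g * p_ven
  }
  lk <- which(network$nodes$leak_g > 0)
  for (k in lk) {
    Gm[k, k] <- Gm[k, k] + network$nodes$leak_g[k]
    rhs[k] <- rhs[k] + network$nodes$leak_g[k] * p_ven
  }
  rhs[network$inflow_node] <- rhs[network$inflow_node] + q_in
  solve(Gm, rhs)
}
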