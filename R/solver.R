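# Time integration of the lumped network.
#
# States: node pressures (every internal node), segment flows (branches with
# inertance), and windkessel internal pressures.  The governing equations are
# M dx/dt = A x + b(t) with diagonal M (compliances/inertances); branches
# without inertance and all windkessel/leakage paths enter A as conductances.
# A fixed-step backward-Euler scheme is used: with the implicit matrix
# factored once per simulation, each step is a single matrix-vector product,
# and the flow- and angle-dependent anastomosis resistors are applied as a
# rank-2 Sherman-Morrison-Woodbury correction, Picard-refreshed within the
# step.  Backward Euler also solves all-resistive (purely algebraic)
# networks exactly, which gives a sharp independent check against a direct
# linear solve.

#' Solver controls
#'
#' @param steps_per_cycle Fixed number of time steps per cardiac cycle
#'   (default 1000, i.e. a maximum step of `cardiac_period / 1000`).
#' @param max_cycles Maximum number of cardiac cycles before giving up on
#'   periodicity (default 50).
#' @param tol Relative cycle-to-cycle change of mean aortic pressure and mean
#'   brachial flow below which the periodic steady state is declared
#'   (default 1e-3).
#' @param picard_tol Relative tolerance on the anastomosis conductances
#'   within each implicit step (default 1e-6).
#' @param picard_max Maximum Picard refreshes per step (default 25).
#' @param map_tol Relative tolerance on the restored mean aortic pressure in
#'   the baroreflex iteration (default 1e-3).
#' @param s_max Upper bound of the baroreflex inflow scale factor (default 5).
#' @return A `simulation_controls` list.
#' @export
simulation_controls <- function(steps_per_cycle = 1000, max_cycles = 50,
                                tol = 1e-3, picard_tol = 1e-6,
                                picard_max = 25, map_tol = 1e-3, s_max = 5) {
  structure(list(steps_per_cycle = steps_per_cycle, max_cycles = max_cycles,
                 tol = tol, picard_tol = picard_tol, picard_max = picard_max,
                 map_tol = map_tol, s_max = s_max),
            class = "simulation_controls")
}

# Build the state-space matrices and the factored implicit operator.
assemble_system <- function(network, venous_pressure, dt) {
  nodes <- network$nodes
  br <- network$branches
  term <- network$terminals
  if (nrow(term) > 0 && anyNA(term$R_wk)) {
    stop("windkessel terminals are not personalized; call attach_terminals()")
  }

  n_nodes <- nrow(nodes)
  dyn <- which(br$L > 0)
  stat <- which(br$L <= 0)
  wk_state <- which(term$Z_wk > 1e-12)
  wk_fold <- setdiff(seq_len(nrow(term)), wk_state)

  iq <- if (length(dyn)) n_nodes + seq_along(dyn) else integer(0)
  iw <- if (length(wk_state)) n_nodes + length(dyn) + seq_along(wk_state) else integer(0)
  ns <- n_nodes + length(dyn) + length(wk_state)

  A <- matrix(0, ns, ns)
  M <- numeric(ns)
  b0 <- numeric(ns)
  M[seq_len(n_nodes)] <- nodes$C
  pv <- venous_pressure

  # leakage to the venous reference
  leak <- which(nodes$leak_g > 0)
  for (k in leak) {
    A[k, k] <- A[k, k] - nodes$leak_g[k]
    b0[k] <- b0[k] + nodes$leak_g[k] * pv
  }

  # inertance branches: flow states
  for (s in seq_along(dyn)) {
    b <- dyn[s]; q <- iq[s]
    i <- br$from[b]; j <- br$to[b]
    M[q] <- br$L[b]
    A[q, q] <- -br$R[b]
    if (i != EXTERNAL_NODE) { A[q, i] <- A[q, i] + 1; A[i, q] <- A[i, q] - 1 }
    else b0[q] <- b0[q] + pv
    if (j != EXTERNAL_NODE) { A[q, j] <- A[q, j] - 1; A[j, q] <- A[j, q] + 1 }
    else b0[q] <- b0[q] - pv
  }

  # resistive branches: conductance stamps
  for (b in stat) {
    g <- 1 / br$R[b]
    i <- br$from[b]; j <- br$to[b]
    if (i != EXTERNAL_NODE && j != EXTERNAL_NODE) {
      A[i, i] <- A[i, i] - g; A[i, j] <- A[i, j] + g
      A[j, j] <- A[j, j] - g; A[j, i] <- A[j, i] + g
    } else if (j == EXTERNAL_NODE) {
      A[i, i] <- A[i, i] - g; b0[i] <- b0[i] + g * pv
    } else {
      A[j, j] <- A[j, j] - g; b0[j] <- b0[j] + g * pv
    }
  }

  # windkessel terminals
  for (s in seq_along(wk_state)) {
    t_i <- wk_state[s]; c_idx <- iw[s]
    k <- term$node[t_i]
    Z <- term$Z_wk[t_i]; Rw <- term$R_wk[t_i]; Cw <- term$C_wk[t_i]
    M[c_idx] <- Cw
    A[k, k] <- A[k, k] - 1 / Z
    A[k, c_idx] <- A[k, c_idx] + 1 / Z
    A[c_idx, k] <- A[c_idx, k] + 1 / Z
    A[c_idx, c_idx] <- A[c_idx, c_idx] - (1 / Z + 1 / Rw)
    b0[c_idx] <- b0[c_idx] + pv / Rw
  }
  for (t_i in wk_fold) {
    k <- term$node[t_i]
    A[k, k] <- A[k, k] - 1 / term$R_wk[t_i]
    b0[k] <- b0[k] + pv / term$R_wk[t_i]
    M[k] <- M[k] + term$C_wk[t_i]
  }

  inflow <- network$inflow_node

  an <- network$anastomosis
  U <- NULL
  if (!is.null(an)) {
    U <- matrix(0, ns, 2)
    U[an$junction, 1] <- 1; U[an$vein_entry, 1] <- -1
    U[an$junction, 2] <- 1; U[an$distal_entry, 2] <- -1
  }

  Aimp <- diag(M / dt, ns) - A
  B <- solve(Aimp)
  G <- B * matrix(M / dt, ns, ns, byrow = TRUE)
  cb <- drop(B %*% b0)
  ci <- B[, inflow]

  sys <- list(
    ns = ns, n_nodes = n_nodes, dt = dt,
    A = A, M = M, b0 = b0, B = B, G = G, cb = cb, ci = ci,
    inflow = inflow, iq = iq, dyn = dyn, stat = stat,
    iw = iw, wk_state = wk_state, wk_fold = wk_fold,
    venous_pressure = pv, network = network
  )
  if (!is.null(U)) {
    sys$U <- U
    sys$W <- B %*% U
    sys$S <- crossprod(U, sys$W)
    sys$anast <- list(
      Rv = c(an$R_visc_venous, an$R_visc_distal),
      alpha = c(an$alpha_venous, an$alpha_distal),
      junction = an$junction, vein_entry = an$vein_entry,
      distal_entry = an$distal_entry
    )
  }
  sys
}

# DC (steady) solution of the network for a constant inflow, used as the
# initial condition; Picard iteration resolves the anastomosis conductances.
dc_solution <- function(sys, q_mean) {
  b <- sys$b0
  b[sys$inflow] <- b[sys$inflow] + q_mean
  if (is.null(sys$U)) return(solve(-sys$A, b))
  g <- 1 / (sys$anast$Rv + sys$anast$alpha * abs(q_mean))
  x <- NULL
  for (it in 1:50) {
    Aeff <- -sys$A + sys$U %*% (g * t(sys$U))
    x <- solve(Aeff, b)
    dp <- drop(crossprod(sys$U, x))
    q <- g * dp
    g_new <- 1 / (sys$anast$Rv + sys$anast$alpha * abs(q))
    if (max(abs(g_new - g) / g) < 1e-10) { g <- g_new; break }
    g <- g_new
  }
  attr(x, "g") <- g
  x
}

# Integrate whole cardiac cycles until the periodic steady state.
run_cycles <- function(sys, qin, controls, x0 = NULL, monitor_branch = NULL) {
  N <- length(qin)
  ns <- sys$ns
  if (is.null(x0)) x0 <- dc_solution(sys, mean(qin))
  x <- as.numeric(x0)

  has_an <- !is.null(sys$U)
  if (has_an) {
    g <- attr(x0, "g")
    if (is.null(g)) g <- 1 / (sys$anast$Rv + sys$anast$alpha * abs(mean(qin)))
    S <- sys$S; W <- sys$W; U <- sys$U
    Rv <- sys$anast$Rv; alpha <- sys$anast$alpha
    jn <- sys$anast$junction; vn <- sys$anast$vein_entry
    dn <- sys$anast$distal_entry
    W1 <- W[, 1]; W2 <- W[, 2]
    S11 <- S[1, 1]; S12 <- S[1, 2]; S21 <- S[2, 1]; S22 <- S[2, 2]
  }

  X <- matrix(0, ns, N + 1)
  qan <- if (has_an) matrix(0, 2, N + 1) else NULL
  monitor_idx <- NULL
  if (!is.null(monitor_branch)) {
    s <- match(monitor_branch, sys$dyn)
    monitor_idx <- if (!is.na(s)) sys$iq[s] else NULL
  }

  map_prev <- NA_real_; qb_prev <- NA_real_
  converged <- FALSE; cycles <- 0L

  for (cyc in seq_len(controls$max_cycles)) {
    X[, 1] <- x
    if (has_an) qan[, 1] <- g * drop(crossprod(U, x))
    for (i in seq_len(N)) {
      x0s <- drop(sys$G %*% x) + sys$cb + qin[i] * sys$ci
      if (has_an) {
        t2a <- x0s[jn] - x0s[vn]
        t2b <- x0s[jn] - x0s[dn]
        for (it in seq_len(controls$picard_max)) {
          a11 <- 1 / g[1] + S11; a22 <- 1 / g[2] + S22
          det <- a11 * a22 - S12 * S21
          y1 <- (a22 * t2a - S12 * t2b) / det
          y2 <- (a11 * t2b - S21 * t2a) / det
          q2 <- c(g[1] * (t2a - S11 * y1 - S12 * y2),
                  g[2] * (t2b - S21 * y1 - S22 * y2))
          g_new <- 1 / (Rv + alpha * abs(q2))
          delta <- max(abs(g_new - g) / g)
          g <- g_new
          if (delta < controls$picard_tol) break
        }
        x <- x0s - W1 * y1 - W2 * y2
        qan[, i + 1] <- q2
      } else {
        x <- x0s
      }
      X[, i + 1] <- x
    }
    cycles <- cyc
    map <- mean(X[sys$inflow, -1])
    qb <- if (!is.null(monitor_idx)) mean(X[monitor_idx, -1]) else mean(qin)
    if (cyc >= 2) {
      # floors (1e-3 mmHg / 1e-3 ml/s) keep the relative test meaningful
      # when a trace relaxes towards zero
      d_map <- abs(map - map_prev) / max(abs(map_prev), 1e-3)
      d_qb <- abs(qb - qb_prev) / max(abs(qb_prev), 1e-3)
      if (d_map < controls$tol && d_qb < controls$tol) { converged <- TRUE }
    }
    map_prev <- map; qb_prev <- qb
    if (converged) break
  }

  list(X = X, qan = qan, converged = converged, cycles = cycles,
       map = map_prev, qb = qb_prev)
}

#' Simulate a vascular network over cardiac cycles
#'
#' Integrates the lumped network from a steady initial condition until the
#' periodic steady state: the relative cycle-to-cycle change of mean aortic
#' pressure and mean brachial flow must drop below `controls$tol` within
#' `controls$max_cycles` cycles, otherwise the result is flagged as not
#' converged.  The aortic inflow waveform is prescribed at the root; the
#' central venous pressure is held at `venous_pressure` at the venous outflow
#' and behind every windkessel.
#'
#' @param network A `vascular_network` with personalized terminals.
#' @param inflow Aortic inflow over one cycle: either a function of time
#'   (s -> ml/s) or a data.frame with columns `time` (s) and `flow` (ml/s).
#' @param cardiac_period Cardiac period in s.
#' @param venous_pressure Central venous pressure in mmHg (default 10).
#' @param controls A [simulation_controls()] list.
#' @param init_state Optional state vector to start from (warm start).
#' @param inflow_scale Scalar multiplying the inflow waveform (baroreflex).
#' @return A `simulation_result`: `time`, `pressures` (nodes x steps, mmHg),
#'   `flows` (branches x steps, ml/s), `mean_aortic_pressure` (mmHg),
#'   `mean_brachial_flow` (ml/min), `converged`, `cycles_run`, plus the
#'   anastomosis flow traces when present.
#' @export
simulate_network <- function(network, inflow, cardiac_period,
                             venous_pressure = 10,
                             controls = simulation_controls(),
                             init_state = NULL, inflow_scale = 1) {
  stopifnot(inherits(network, "vascular_network"))
  dt <- cardiac_period / controls$steps_per_cycle
  sys <- assemble_system(network, venous_pressure, dt)
  qin <- sample_inflow(inflow, cardiac_period, controls$steps_per_cycle) *
    inflow_scale
  out <- run_cycles(sys, qin, controls, x0 = init_state,
                    monitor_branch = network$monitor_branch)
  build_result(sys, out, qin, cardiac_period)
}

sample_inflow <- function(inflow, period, n_steps) {
  tt <- (seq_len(n_steps)) * period / n_steps
  if (is.function(inflow)) return(inflow(tt %% period))
  df <- as.data.frame(inflow)
  if (!all(c("time", "flow") %in% names(df))) {
    stop("inflow waveform needs 'time' and 'flow' columns")
  }
  stats::approx(df$time, df$flow, xout = tt %% period, rule = 2)$y
}

build_result <- function(sys, out, qin, cardiac_period) {
  N <- length(qin)
  net <- sys$network
  br <- net$branches
  n_br <- nrow(br)
  flows <- matrix(0, n_br, N + 1)
  for (s in seq_along(sys$dyn)) flows[sys$dyn[s], ] <- out$X[sys$iq[s], ]
  for (b in sys$stat) {
    i <- br$from[b]; j <- br$to[b]
    pi_ <- if (i == EXTERNAL_NODE) sys$venous_pressure else out$X[i, ]
    pj_ <- if (j == EXTERNAL_NODE) sys$venous_pressure else out$X[j, ]
    flows[b, ] <- (pi_ - pj_) / br$R[b]
  }
  mb <- net$monitor_branch
  qb_mls <- if (!is.null(mb)) mean(flows[mb, -1]) else mean(qin)
  structure(list(
    time = seq(0, cardiac_period, length.out = N + 1),
    pressures = out$X[seq_len(sys$n_nodes), , drop = FALSE],
    flows = flows,
    anastomosis_flows = out$qan,
    inflow = qin,
    mean_aortic_pressure = out$map,
    mean_brachial_flow = mls_to_mlmin(qb_mls),
    converged = out$converged,
    cycles_run = out$cycles,
    states = out$X,
    sys = sys,
    network = net,
    cardiac_period = cardiac_period
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %s: MAP %.1f mmHg, brachial flow %.0f ml/min, %d cycles%s\n",
    x$network$configuration, x$mean_aortic_pressure, x$mean_brachial_flow,
    x$cycles_run, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Mean flow through a vessel over the final cycle
#'
#' @param result A `simulation_result`.
#' @param vessel_id Vessel identifier.
#' @param location `"distal"` (last segment) or `"proximal"` (first segment).
#' @return Mean flow in ml/min.
#' @export
vessel_mean_flow <- function(result, vessel_id,
                             location = c("distal", "proximal")) {
  location <- match.arg(location)
  br <- result$network$branches
  idx <- which(br$vessel_id == vessel_id)
  if (length(idx) == 0) stop(sprintf("vessel '%s' not in this network", vessel_id))
  b <- if (location == "distal") max(idx) else min(idx)
  mls_to_mlmin(mean(result$flows[b, -1]))
}

#' Per-node mass-balance residual of a simulation
#'
#' Recomputes, for every internal node and time step of the final cycle, the
#' discrete balance of inflows, outflows, leakage, windkessel exchange and
#' compliance storage; residuals are reported relative to the mean aortic
#' inflow (the cycle throughput).
#'
#' @param result A `simulation_result`.
#' @return Maximum over internal nodes of the mean absolute relative
#'   residual.
#' @export
mass_balance <- function(result) {
  sys <- result$sys
  X <- result$states
  N <- ncol(X) - 1
  dt <- sys$dt
  qin <- result$inflow
  b_t <- matrix(sys$b0, sys$ns, N)
  b_t[sys$inflow, ] <- b_t[sys$inflow, ] + qin
  lhs <- (sys$M / dt) * (X[, -1, drop = FALSE] - X[, -(N + 1), drop = FALSE])
  rhs <- sys$A %*% X[, -1, drop = FALSE] + b_t
  if (!is.null(sys$U)) {
    # anastomosis branch flows leave the junction and enter the entry nodes
    qan <- result$anastomosis_flows[, -1, drop = FALSE]
    rhs[sys$anast$junction, ] <- rhs[sys$anast$junction, ] - qan[1, ] - qan[2, ]
    rhs[sys$anast$vein_entry, ] <- rhs[sys$anast$vein_entry, ] + qan[1, ]
    rhs[sys$anast$distal_entry, ] <- rhs[sys$anast$distal_entry, ] + qan[2, ]
  }
  resid <- lhs - rhs
  node_rows <- seq_len(sys$n_nodes)
  max(rowMeans(abs(resid[node_rows, , drop = FALSE]))) / max(mean(qin), 1e-12)
}

#' Baroreflex: rescale the aortic inflow to restore mean aortic pressure
#'
#' After virtual fistula creation the total systemic resistance drops, so the
#' preoperative inflow no longer sustains the preoperative mean aortic
#' pressure.  The baroreflex surrogate scales the preoperative inflow
#' waveform by a factor `s >= 1`, found by a bracketed secant iteration,
#' until the postoperative mean aortic pressure matches the preoperative one
#' to `controls$map_tol` relative; all other parameters are held constant.
#'
#' @param network_postop Postoperative `vascular_network` with terminals.
#' @param preop_result Converged preoperative `simulation_result`.
#' @param inflow Preoperative aortic inflow waveform (function or
#'   data.frame `time`/`flow`).
#' @param controls A [simulation_controls()].
#' @param venous_pressure Central venous pressure in mmHg.
#' @return List: `s` (scale factor), `result` (postoperative
#'   `simulation_result` at `s`), `scaled_inflow` (data.frame over one
#'   cycle), `baroreflex_converged`, `n_evaluations`.
#' @export
baroreflex_scale <- function(network_postop, preop_result, inflow,
                             controls = simulation_controls(),
                             venous_pressure = 10) {
  if (!preop_result$converged) {
    stop("preoperative simulation did not converge; cannot run the baroreflex")
  }
  target <- preop_result$mean_aortic_pressure
  period <- preop_result$cardiac_period
  dt <- period / controls$steps_per_cycle
  sys <- assemble_system(network_postop, venous_pressure, dt)
  qbase <- sample_inflow(inflow, period, controls$steps_per_cycle)
  mb <- network_postop$monitor_branch

  warm <- NULL
  evals <- 0L
  eval_map <- function(s) {
    out <- run_cycles(sys, s * qbase, controls, x0 = warm, monitor_branch = mb)
    warm <<- out$X[, ncol(out$X)]
    evals <<- evals + 1L
    out
  }

  s_lo <- 1; out_lo <- eval_map(s_lo)
  f_lo <- out_lo$map - target
  best_s <- s_lo; best_out <- out_lo
  ok <- abs(f_lo) / target < controls$map_tol
  failed <- FALSE

  if (!ok && f_lo > 0) {
    # network is not more permissive than preoperative (no fistula): s = 1
    ok <- TRUE
  }

  if (!ok) {
    pv <- venous_pressure
    s_hi <- min(controls$s_max, max(1.01, (target - pv) / max(out_lo$map - pv, 1e-9)))
    out_hi <- eval_map(s_hi)
    f_hi <- out_hi$map - target
    best_s <- s_hi; best_out <- out_hi
    while (f_hi < 0 && s_hi < controls$s_max && evals < 30) {
      s_lo <- s_hi; f_lo <- f_hi
      s_hi <- min(controls$s_max, s_hi * 1.5)
      out_hi <- eval_map(s_hi)
      f_hi <- out_hi$map - target
      best_s <- s_hi; best_out <- out_hi
    }
    if (f_hi < 0) {
      failed <- TRUE  # no s in [1, s_max] restores the pressure
    } else {
      repeat {
        if (abs(f_hi) / target < controls$map_tol) {
          best_s <- s_hi; best_out <- out_hi; ok <- TRUE; break
        }
        if (abs(f_lo) / target < controls$map_tol && f_lo != f_hi) {
          # keep iterating from the tighter side only if lo is acceptable
        }
        if (evals >= 30) { best_s <- s_hi; best_out <- out_hi; break }
        s_new <- s_hi - f_hi * (s_hi - s_lo) / (f_hi - f_lo)
        if (!is.finite(s_new) || s_new <= min(s_lo, s_hi) ||
            s_new >= max(s_lo, s_hi)) {
          s_new <- (s_lo + s_hi) / 2
        }
        out_new <- eval_map(s_new)
        f_new <- out_new$map - target
        if (f_new < 0) { s_lo <- s_new; f_lo <- f_new }
        else { s_hi <- s_new; f_hi <- f_new; out_hi <- out_new }
        if (abs(f_new) / target < controls$map_tol) {
          best_s <- s_new; best_out <- out_new; ok <- TRUE; break
        }
      }
    }
  }

  result <- build_result(sys, best_out, best_s * qbase, period)
  tt <- (seq_along(qbase)) * period / length(qbase)
  list(
    s = best_s,
    result = result,
    scaled_inflow = data.frame(time = tt, flow = best_s * qbase),
    baroreflex_converged = ok && !failed,
    n_evaluations = evals
  )
}

#' Predict the immediate postoperative brachial flow for a configuration
#'
#' Runs the full pipeline for one patient and one fistula configuration:
#' personalization, preoperative simulation (which fixes the windkessel
#' terminals and the baroreflex pressure target), virtual surgery, baroreflex
#' inflow scaling, and extraction of the mean brachial artery flow over the
#' final cycle.
#'
#' @param record A [patient_record()].
#' @param configuration `"RC-AVF"`, `"BC-AVF"`, `"BB-AVF"` or
#'   `"preoperative"` (the latter returns the preoperative flows).
#' @param overrides Personalization perturbations (see
#'   [personalize_patient()]); used by the uncertainty layer.
#' @param controls A [simulation_controls()].
#' @return List: `flow` (mean brachial flow, ml/min), `configuration`,
#'   `converged`, `s` (baroreflex scale; 1 preoperatively),
#'   `result`, `preop_result`, `baroreflex_converged`.
#' @export
predict_postop_flow <- function(record, configuration,
                                overrides = list(),
                                controls = simulation_controls()) {
  configuration <- match.arg(configuration, config_choices())
  pers <- personalize_patient(record, overrides)

  preop <- build_domain("preoperative", pers$side, pers$geometries,
                        blood = pers$blood)
  wk <- personalize_windkessels(preop, record$map_pressure, record$mean_flows,
                                venous_pressure = pers$venous_pressure)
  preop <- attach_terminals(preop, wk, pers$wk_R_scale, pers$wk_C_scale)
  preop_res <- simulate_network(preop, record$aortic_flow_waveform,
                                record$cardiac_period,
                                venous_pressure = pers$venous_pressure,
                                controls = controls)
  if (configuration == "preoperative") {
    return(list(flow = preop_res$mean_brachial_flow,
                configuration = configuration,
                converged = preop_res$converged, s = 1,
                result = preop_res, preop_result = preop_res,
                baroreflex_converged = TRUE))
  }

  postop <- build_domain(configuration, pers$side, pers$geometries,
                         blood = pers$blood, angle = pers$angle,
                         leak_multiplier = pers$leak_multiplier)
  postop <- attach_terminals(postop, wk, pers$wk_R_scale, pers$wk_C_scale)
  brf <- baroreflex_scale(postop, preop_res, record$aortic_flow_waveform,
                          controls = controls,
                          venous_pressure = pers$venous_pressure)
  list(
    flow = brf$result$mean_brachial_flow,
    configuration = configuration,
    converged = preop_res$converged && brf$result$converged &&
      brf$baroreflex_converged,
    s = brf$s,
    result = brf$result,
    preop_result = preop_res,
    baroreflex_converged = brf$baroreflex_converged
  )
}
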