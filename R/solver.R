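#' Periodic inlet flow-rate waveform
#'
#' One cardiac cycle of an inlet flow-rate time series. Samples live on
#' `[0, period)`; the waveform is treated as periodic with linear
#' interpolation between samples (wrapping from the last sample back to the
#' first).
#'
#' @param time sample times in s, strictly increasing, within `[0, period)`.
#' @param flow flow rates in m^3/s, non-negative for inlet waveforms.
#' @param period cycle duration T in s (> 0); default 1 s.
#' @param label one of `"left_ICA"`, `"right_ICA"`, `"BA"`, or `NA`.
#' @return An object of class `cow_waveform`.
#' @examples
#' t <- seq(0, 0.98, by = 0.02)
#' wf <- waveform(t, 4e-6 * (1 + 0.5 * sin(2 * pi * t)), period = 1,
#'                label = "left_ICA")
#' waveform_mean(wf)
#' @export
waveform <- function(time, flow, period = 1, label = NA_character_) {
  time <- as.numeric(time); flow <- as.numeric(flow)
  if (length(time) < 1L || length(time) != length(flow)) {
    stop("`time` and `flow` must be non-empty and equal length",
         call. = FALSE)
  }
  if (!is.finite(period) || period <= 0) {
    stop("`period` must be positive", call. = FALSE)
  }
  if (any(time < 0) || any(time >= period)) {
    stop("sample times must lie in [0, period)", call. = FALSE)
  }
  if (length(time) > 1L && any(diff(time) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  if (any(flow < 0)) {
    stop("inlet flow rates must be non-negative", call. = FALSE)
  }
  if (!is.na(label) && !label %in% c("left_ICA", "right_ICA", "BA")) {
    stop("waveform label must be left_ICA, right_ICA or BA", call. = FALSE)
  }
  structure(list(time = time, flow = flow, period = period, label = label),
            class = "cow_waveform")
}

#' @export
print.cow_waveform <- function(x, ...) {
  cat(sprintf("<cow_waveform> %s: T = %g s, %d samples, mean = %.3g m^3/s\n",
              if (is.na(x$label)) "(unlabelled)" else x$label,
              x$period, length(x$time), waveform_mean(x)))
  invisible(x)
}

#' Evaluate a waveform at arbitrary times
#'
#' Periodic linear interpolation: times are folded into `[0, period)` and the
#' flow is interpolated between neighbouring samples, wrapping across the
#' cycle boundary.
#'
#' @param wf a [waveform()].
#' @param t numeric vector of times in s (any real values).
#' @return Flow rates in m^3/s at `t`.
#' @export
waveform_at <- function(wf, t) {
  stopifnot(inherits(wf, "cow_waveform"))
  tt <- t %% wf$period
  # close the cycle for interpolation: value at `period` is the t=0 sample
  xs <- c(wf$time, wf$period + wf$time[1L])
  ys <- c(wf$flow, wf$flow[1L])
  if (wf$time[1L] > 0) {   # cover [0, first sample) by wrapping the tail
    xs <- c(wf$time[length(wf$time)] - wf$period, xs)
    ys <- c(wf$flow[length(wf$flow)], ys)
  }
  stats::approx(xs, ys, xout = tt, rule = 2)$y
}

#' Cycle mean of a waveform
#'
#' Trapezoidal mean over one full period of the periodic extension.
#'
#' @param wf a [waveform()].
#' @return Mean flow in m^3/s.
#' @export
waveform_mean <- function(wf) {
  stopifnot(inherits(wf, "cow_waveform"))
  xs <- c(wf$time, wf$period + wf$time[1L])
  ys <- c(wf$flow, wf$flow[1L])
  sum(diff(xs) * (ys[-1L] + ys[-length(ys)]) / 2) / wf$period
}

#' Pulsatile solver configuration
#'
#' Time discretization of the pulsatile run: the defaults (time step 0.02 s,
#' cardiac cycle 1 s, three cycles simulated, statistics reported from the
#' last cycle) follow common practice in cerebral CFD. Because the resistive
#' network is stateless the earlier cycles are identical to the reported one;
#' they are retained so the configuration matches the transient-solver
#' convention it stands in for.
#'
#' @param time_step solver step in s; must divide the period.
#' @param n_cycles number of cardiac cycles (>= 1).
#' @param report_cycle which cycle the reported solution covers
#'   (default: the last).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(time_step = 0.02, n_cycles = 3,
                          report_cycle = n_cycles) {
  if (!is.finite(time_step) || time_step <= 0) {
    stop("`time_step` must be positive", call. = FALSE)
  }
  if (n_cycles < 1L || report_cycle < 1L || report_cycle > n_cycles) {
    stop("need n_cycles >= 1 and 1 <= report_cycle <= n_cycles",
         call. = FALSE)
  }
  structure(list(time_step = time_step, n_cycles = as.integer(n_cycles),
                 report_cycle = as.integer(report_cycle)),
            class = "solver_config")
}

.solution <- function(net, times, pressures, flows, wss, inlet_total) {
  structure(list(network = net, times = times, pressures = pressures,
                 flows = flows, wss = wss, inlet_total = inlet_total),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> %d time point(s), %d nodes, %d segments\n",
              length(x$times), nrow(x$pressures), nrow(x$flows)))
  invisible(x)
}

# one nodal solve shared by the steady and pulsatile drivers;
# `inflow` is a named vector over inlet node ids
.solve_nodal <- function(sys, net, inflow_by_node) {
  b <- numeric(length(sys$free_nodes))
  names(b) <- sys$free_nodes
  b[names(inflow_by_node)] <- inflow_by_node
  p <- tryCatch(solve(sys$G, b), error = function(e) {
    stop("singular conductance system (disconnected after outlet ",
         "elimination?): ", conditionMessage(e), call. = FALSE)
  })
  pall <- numeric(nrow(net$nodes))
  names(pall) <- net$nodes$id
  pall[sys$free_nodes] <- p          # outlets stay at zero gauge
  q <- (pall[sys$endpoints$from] - pall[sys$endpoints$to]) / sys$resistance
  names(q) <- sys$endpoints$id
  list(p = pall, q = q)
}

#' Steady flow solution of a CoW network
#'
#' Solves nodal pressures from Kirchhoff conservation with Poiseuille
#' segment flows (`Q = dP/R`), prescribed volumetric inflows at the inlets
#' and zero gauge pressure at every outlet — the resistive approximation
#' justified in the cerebral circulation, where flow distribution is
#' dominated by vascular resistance rather than by outlet pressure
#' differences.
#'
#' @param net a [cow_network()].
#' @param inlet_flows named numeric vector of inflows in m^3/s, named by
#'   waveform label (`left_ICA`, `right_ICA`, `BA`); every inlet of the
#'   network must be covered.
#' @param fluid a [fluid_properties()]; default standard blood.
#' @return A `flow_solution` with a single time point: nodal pressures (Pa),
#'   signed segment flows (m^3/s, positive from `from_node` to `to_node`),
#'   and Poiseuille wall shear stress per segment (Pa).
#' @examples
#' cw <- build_network(generate_cow(case_template("symmetric", seed = 1)))
#' sol <- solve_steady(cw, c(left_ICA = 4e-6, right_ICA = 4e-6, BA = 2e-6))
#' sol$flows[, 1]
#' @export
solve_steady <- function(net, inlet_flows, fluid = fluid_properties()) {
  stopifnot(inherits(net, "cow_network"))
  missing_lab <- setdiff(unname(net$inlets), names(inlet_flows))
  if (length(missing_lab)) {
    stop("no inflow prescribed for inlet label(s): ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  sys <- conductance_system(net, fluid)
  inflow <- inlet_flows[unname(net$inlets)]
  names(inflow) <- names(net$inlets)
  st <- .solve_nodal(sys, net, inflow)
  wss <- vapply(names(net$segments), function(id) {
    segment_wss(st$q[[id]], net$segments[[id]], fluid)
  }, numeric(1))
  .solution(net, times = 0,
            pressures = matrix(unname(st$p), ncol = 1,
                               dimnames = list(names(st$p), NULL)),
            flows = matrix(unname(st$q), ncol = 1,
                           dimnames = list(names(st$q), NULL)),
            wss = matrix(unname(wss), ncol = 1,
                         dimnames = list(names(wss), NULL)),
            inlet_total = sum(inflow))
}

#' Pulsatile flow solution of a CoW network
#'
#' Quasi-steady pulsatile driver: the resistive network carries no
#' compliance or inertance, so each time step is an independent steady solve
#' under the instantaneous inlet flows interpolated from the waveforms. The
#' conductance matrix is assembled and factorized once and reused across all
#' steps. The returned solution covers the reporting cycle, including both
#' cycle endpoints so that cycle integrals (TAWSS, OSI) use a full closed
#' period.
#'
#' @param net a [cow_network()].
#' @param waveforms named list of [waveform()] objects keyed by label
#'   (`left_ICA`, `right_ICA`, `BA`); all must share the same period.
#' @param fluid a [fluid_properties()].
#' @param config a [solver_config()].
#' @return A `flow_solution` over the reported cycle: matrices `pressures`
#'   (node x time, Pa), `flows` (segment x time, m^3/s, signed), `wss`
#'   (segment x time, Pa), plus the total inlet inflow series.
#' @export
solve_pulsatile <- function(net, waveforms, fluid = fluid_properties(),
                            config = solver_config()) {
  stopifnot(inherits(net, "cow_network"), inherits(config, "solver_config"))
  labels <- unname(net$inlets)
  missing_lab <- setdiff(labels, names(waveforms))
  if (length(missing_lab)) {
    stop("no waveform supplied for inlet label(s): ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  periods <- vapply(waveforms[labels], `[[`, numeric(1), "period")
  if (diff(range(periods)) > 1e-12 * max(periods)) {
    stop("all inlet waveforms must share the same period", call. = FALSE)
  }
  period <- periods[[1L]]
  n_steps <- round(period / config$time_step)
  if (abs(n_steps * config$time_step - period) > 1e-9 * period) {
    stop("time_step must divide the waveform period", call. = FALSE)
  }
  sys <- conductance_system(net, fluid)
  # absolute times of the reported cycle, both endpoints included
  t0 <- (config$report_cycle - 1L) * period
  times <- t0 + seq(0, n_steps) * config$time_step
  nt <- length(times)

  inflow_by_label <- vapply(labels, function(lab) {
    waveform_at(waveforms[[lab]], times)
  }, numeric(nt))
  if (nt == 1L) inflow_by_label <- matrix(inflow_by_label, nrow = 1L)
  colnames(inflow_by_label) <- labels

  # all right-hand sides at once: one factorization serves the whole cycle
  B <- matrix(0, nrow = length(sys$free_nodes), ncol = nt,
              dimnames = list(sys$free_nodes, NULL))
  for (nd in names(net$inlets)) {
    B[nd, ] <- inflow_by_label[, net$inlets[[nd]]]
  }
  P_free <- solve(sys$G, B)
  P <- matrix(0, nrow = nrow(net$nodes), ncol = nt,
              dimnames = list(net$nodes$id, NULL))
  P[sys$free_nodes, ] <- P_free
  Q <- (P[sys$endpoints$from, , drop = FALSE] -
        P[sys$endpoints$to, , drop = FALSE]) / sys$resistance
  rownames(Q) <- sys$endpoints$id
  W <- Q
  for (id in rownames(Q)) {
    W[id, ] <- segment_wss(Q[id, ], net$segments[[id]], fluid)
  }
  .solution(net, times = times, pressures = P, flows = Q, wss = W,
            inlet_total = rowSums(inflow_by_label))
}

#' Poiseuille wall shear stress of a segment flow
#'
#' Fully developed laminar pipe flow has wall shear stress
#' `tau_w = 4 mu |Q| / (pi r^3)`. For tapered segments the minimum profile
#' radius is used (the narrowest station carries the highest WSS, a
#' deterministic worst-case convention). Segments with only a resistance
#' override and no radius yield `NA`, since WSS is a geometric quantity.
#'
#' @param flow flow rate(s) in m^3/s; sign is ignored.
#' @param segment a [vessel_segment()].
#' @param fluid a [fluid_properties()].
#' @return Wall shear stress in Pa (vectorized over `flow`), >= 0.
#' @examples
#' s <- vessel_segment("s", "a", "b", length = 0.01, radius = 2e-3)
#' segment_wss(4e-6, s, fluid_properties())   # ~2.55 Pa
#' @export
segment_wss <- function(flow, segment, fluid) {
  stopifnot(inherits(segment, "vessel_segment"),
            inherits(fluid, "fluid_properties"))
  if (is.null(segment$radius_profile)) {
    return(rep(NA_real_, length(flow)))
  }
  r <- min(segment$radius_profile$radius)
  4 * fluid$viscosity * abs(flow) / (pi * r^3)
}

#' Signed wall shear stress series of a segment
#'
#' As [segment_wss()] but carrying the sign of the flow, for use in
#' direction-sensitive statistics (OSI).
#'
#' @inheritParams segment_wss
#' @return Signed WSS in Pa.
#' @export
segment_wss_signed <- function(flow, segment, fluid) {
  sign(flow) * segment_wss(flow, segment, fluid)
}

#' Aneurysm inflow fractions from the two A1 feeders
#'
#' Splits the cycle-integrated inflow into the aneurysm node between the
#' left and right A1 segments. Only positive (toward-the-node) flow counts
#' as inflow; a feeder whose flow reverses contributes only its forward
#' lobes. An A1 role absent from the network (half models) contributes zero.
#' Both A1 segments, when present, must be incident to the aneurysm node.
#'
#' @param sol a `flow_solution` covering one full cycle.
#' @param roles role map; defaults to the solved network's.
#' @return Named numeric vector `c(f_left, f_right)`, each in `[0, 1]`,
#'   summing to 1 when the A1 segments are the only feeders.
#' @export
acom_inflow_fractions <- function(sol, roles = sol$network$roles) {
  stopifnot(inherits(sol, "flow_solution"))
  net <- sol$network
  an <- net$nodes$id[net$nodes$kind == "aneurysm"]
  if (length(an) != 1L) {
    stop("network must contain exactly one aneurysm node", call. = FALSE)
  }
  feeder_integral <- function(role) {
    id <- roles[[role]]
    if (is.null(id)) return(0)
    seg <- net$segments[[id]]
    if (is.null(seg)) stop("role ", role, " maps to unknown segment",
                           call. = FALSE)
    # signed flow oriented INTO the aneurysm node
    q <- sol$flows[id, ]
    if (seg$to_node == an) {
      # keep orientation
    } else if (seg$from_node == an) {
      q <- -q
    } else {
      stop("segment '", id, "' (", role, ") is not incident to the ",
           "aneurysm node; inflow attribution is ambiguous", call. = FALSE)
    }
    qin <- pmax(q, 0)
    if (length(sol$times) == 1L) return(qin)
    sum(diff(sol$times) * (qin[-1L] + qin[-length(qin)]) / 2)
  }
  vleft <- feeder_integral("left_A1")
  vright <- feeder_integral("right_A1")
  total <- vleft + vright
  if (total <= 0) {
    stop("total cycle-integrated inflow into the aneurysm node is zero: ",
         "inflow fractions are undefined", call. = FALSE)
  }
  c(f_left = vleft / total, f_right = vright / total)
}

#' Conservation residual of a flow solution
#'
#' Largest absolute net flow imbalance over all interior (junction and
#' aneurysm) nodes and all time steps, normalized by the largest
#' instantaneous total inlet flow. A correct nodal solve keeps this at
#' rounding level.
#'
#' @param sol a `flow_solution`.
#' @return A single non-negative number (relative residual).
#' @export
conservation_residual <- function(sol) {
  stopifnot(inherits(sol, "flow_solution"))
  net <- sol$network
  interior <- net$nodes$id[net$nodes$kind %in% c("junction", "aneurysm")]
  if (length(interior) == 0L) return(0)
  ep <- .segment_endpoints(net)
  worst <- 0
  for (nd in interior) {
    net_flow <- colSums(sol$flows[ep$id[ep$to == nd], , drop = FALSE]) -
      colSums(sol$flows[ep$id[ep$from == nd], , drop = FALSE])
    worst <- max(worst, max(abs(net_flow)))
  }
  worst / max(sol$inlet_total)
}
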