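# Pulse-wave solver front end: inlet waveform synthesis, WK3/impedance
# helpers, and the driver around the compiled implicit stepper.

#' Build the inlet flow waveform
#'
#' The inlet flow is `Q(t) = CO * Vs * q(t)` with a unit-integral shape
#' `q(t)` over one cardiac cycle: a systolic half-sine of configurable
#' ejection duration, an optional small dicrotic dip, and zero diastolic
#' flow. The time-mean over a cycle equals the prescribed cardiac output.
#'
#' @param CO cardiac output, L/min.
#' @param HR heart rate, bpm; the cycle period is `60/HR` s.
#' @param nt time steps per cardiac cycle.
#' @param shape `"halfsine"` (pulsatile) or `"constant"` (steady inflow,
#'   for steady-state checks).
#' @param systolic_fraction ejection duration as a fraction of the cycle.
#' @param dicrotic_dip area of the early-diastolic negative lobe as a
#'   fraction of stroke volume (0 disables it).
#' @param dip_width_fraction width of the dip as a fraction of the cycle.
#' @return list of class `inlet_waveform` with `t` (s, cell-end times),
#'   `q` (1/s), `Q` (mL/s), `dt`, `tc`, `CO`, `HR`, `nt`.
#' @export
build_inlet <- function(CO, HR, nt = 500, shape = c("halfsine", "constant"),
                        systolic_fraction = 0.37, dicrotic_dip = 0.02,
                        dip_width_fraction = 0.08) {
  stopifnot(CO > 0, HR > 0, nt >= 100 || identical(shape, "constant"))
  shape <- match.arg(shape)
  tc <- 60 / HR
  dt <- tc / nt
  t <- seq_len(nt) * dt
  if (shape == "constant") {
    q <- rep(1 / tc, nt)
  } else {
    Ts <- systolic_fraction * tc
    q <- ifelse(t <= Ts, (pi / (2 * Ts)) * sin(pi * t / Ts), 0)
    if (dicrotic_dip > 0) {
      wd <- dip_width_fraction * tc
      in_dip <- t > Ts & t <= Ts + wd
      q[in_dip] <- q[in_dip] - dicrotic_dip * (pi / (2 * wd)) *
        sin(pi * (t[in_dip] - Ts) / wd)
    }
    q <- q / (sum(q) * dt) # exact unit integral on the grid
  }
  Vs <- CO * 1000 / 60 * tc # stroke volume, mL
  structure(list(t = t, q = q, Q = Vs * q, dt = dt, tc = tc,
                 CO = CO, HR = HR, nt = nt),
            class = "inlet_waveform")
}

#' Frictional force per unit length
#'
#' `f = -2 (zeta + 2) pi mu Q / A`; `zeta = 2` recovers the Poiseuille
#' value `-8 pi mu Q / A`.
#'
#' @param Q flow, m^3/s.
#' @param A area, m^2.
#' @param zeta velocity-profile constant.
#' @param mu viscosity, Pa s.
#' @return force per unit length, N/m.
#' @export
friction_term <- function(Q, A, zeta = 9, mu = 0.004) {
  stopifnot(all(A > 0))
  -2 * (zeta + 2) * pi * mu * Q / A
}

#' Characteristic impedance of a segment
#'
#' Water-hammer impedance `Zc = rho c / Aref` with the wave speed from the
#' Bramwell-Hill relation `c = 1/sqrt(rho Dref)`, i.e.
#' `Zc = sqrt(rho / (Aref^2 Dref))`.
#'
#' @param Aref reference area, cm^2.
#' @param Dref reference distensibility, 1/kPa.
#' @param rho blood density, kg/m^3.
#' @return impedance in mmHg s/mL.
#' @export
characteristic_impedance <- function(Aref, Dref, rho = 1050) {
  stopifnot(all(Aref > 0), all(Dref > 0))
  A_si <- Aref * 1e-4       # m^2
  D_si <- Dref / 1000       # 1/Pa
  sqrt(rho / (A_si^2 * D_si)) / PA_S_M3_PER_MMHG_S_ML
}

#' One implicit update of the WK3 terminal pressure
#'
#' Backward-Euler update of `C dPc/dt = Q - (Pc - Pout)/R2` followed by
#' `P = R1 Q + Pc`; the same discretization used inside the solver.
#'
#' @param terminal list/row with `R1`, `R2`, `C`, `Pout` (mmHg-based units).
#' @param Q inflow at the new time level, mL/s.
#' @param Pc chamber pressure at the previous time level, mmHg.
#' @param dt time step, s.
#' @return list with `P` (terminal pressure, mmHg) and `Pc` (updated).
#' @export
wk3_boundary <- function(terminal, Q, Pc, dt) {
  den <- terminal$C / dt + 1 / terminal$R2
  Pc_new <- (terminal$C * Pc / dt + Q + terminal$Pout / terminal$R2) / den
  list(P = terminal$R1 * Q + Pc_new, Pc = Pc_new)
}

# ---- solver input packing ---------------------------------------------

# Per-node geometric arrays in SI, with linear diameter taper.
#' @keywords internal
pack_network <- function(net) {
  seg <- net$segments
  nseg <- nrow(seg)
  nn <- seg$n_nodes
  noff <- c(0L, cumsum(nn))[seq_len(nseg)]
  Aref <- numeric(sum(nn)); Dref <- numeric(sum(nn))
  for (i in seq_len(nseg)) {
    d1 <- seg$diameter_cm[i]
    d2 <- if (is.na(seg$diameter_distal_cm[i])) d1 else seg$diameter_distal_cm[i]
    d <- seq(d1, d2, length.out = nn[i])
    idx <- noff[i] + seq_len(nn[i])
    Aref[idx] <- pi * d^2 / 4 * 1e-4            # m^2
    # distensibility scales along the taper with the wave-speed law,
    # anchored at the segment's (possibly remodeled) proximal value
    Dref[idx] <- seg$Dref_kPa[i] * (d / d1)^(2 * net$wall$b2) / 1000 # 1/Pa
  }
  # boundary nodes: root inlet, one per junction (keyed by parent segment),
  # one per leaf
  seg_ids <- seg$id
  children <- segment_children(net)
  has_child <- vapply(children, length, 1L) > 0
  bnd_ids <- c("@inlet",
               paste0("@junc_", seg_ids[has_child], recycle0 = TRUE),
               paste0("@term_", leaf_segments(net), recycle0 = TRUE))
  bnd_type <- c(0L, rep(1L, sum(has_child)),
                rep(2L, length(leaf_segments(net))))
  bidx <- stats::setNames(seq_along(bnd_ids) - 1L, bnd_ids)
  bnd_prox <- integer(nseg); bnd_dist <- integer(nseg)
  for (i in seq_len(nseg)) {
    id <- seg_ids[i]; par <- seg$parent[i]
    bnd_prox[i] <- if (is.na(par)) bidx[["@inlet"]] else bidx[[paste0("@junc_", par)]]
    bnd_dist[i] <- if (has_child[[id]]) bidx[[paste0("@junc_", id)]]
                   else bidx[[paste0("@term_", id)]]
  }
  nb <- length(bnd_ids)
  tR1 <- rep(1, nb); tR2 <- rep(1, nb); tC <- rep(1, nb); tPout <- rep(0, nb)
  term <- net$terminals
  for (i in seq_len(nrow(term))) {
    b <- bidx[[paste0("@term_", term$segment_id[i])]] + 1L
    tR1[b] <- term$R1[i] * PA_S_M3_PER_MMHG_S_ML
    tR2[b] <- term$R2[i] * PA_S_M3_PER_MMHG_S_ML
    tC[b] <- term$C[i] * 1e-6 / PA_PER_MMHG     # mL/mmHg -> m^3/Pa
    tPout[b] <- term$Pout[i] * PA_PER_MMHG
  }
  list(n_nodes = as.integer(nn), node_offset = as.integer(noff),
       dz = seg$dz_cm / 100, Aref = Aref, Dref = Dref,
       bnd_prox = as.integer(bnd_prox), bnd_dist = as.integer(bnd_dist),
       bnd_type = as.integer(bnd_type),
       term_R1 = tR1, term_R2 = tR2, term_C = tC, term_Pout = tPout,
       bnd_ids = bnd_ids)
}

# DC-informed initial state: uniform pressure at the Windkessel-predicted
# mean, zero flow, chamber pressures at their DC division. Cuts the
# start-up transient so runs are near-periodic well before the reporting
# cycle.
#' @keywords internal
dc_init_state <- function(net, packed, inlet) {
  term <- net$terminals
  RT <- term$R1 + term$R2
  co_mls <- inlet$CO * 1000 / 60
  map_dc <- co_mls / sum(1 / RT) + mean(term$Pout) # mmHg
  P0 <- rep(map_dc * PA_PER_MMHG, sum(packed$n_nodes))
  nb <- length(packed$bnd_type)
  Pc <- numeric(nb)
  for (i in seq_len(nrow(term))) {
    b <- which(packed$bnd_ids == paste0("@term_", term$segment_id[i]))
    Pc[b] <- (term$Pout[i] + (map_dc - term$Pout[i]) *
                term$R2[i] / RT[i]) * PA_PER_MMHG
  }
  list(P = P0, Qf = numeric(sum(packed$n_nodes - 1L)),
       Qin = numeric(length(packed$n_nodes)),
       Qout = numeric(length(packed$n_nodes)), Pc = Pc)
}

#' @keywords internal
wall_si <- function(wall) {
  list(a1 = wall$a1, b1 = wall$b1, PmaxC = wall$PmaxC * 1000,
       Pwidth = wall$Pwidth * 1000, Pref = wall$Pref * PA_PER_MMHG)
}

#' Run a pulsatile simulation to periodic steady state
#'
#' Integrates the 1D network equations with the implicit finite-difference
#' scheme for `n_cycles` cardiac cycles and reports the final cycle.
#'
#' @param net a validated `vessel_network`.
#' @param inlet an [build_inlet()] waveform.
#' @param n_cycles cardiac cycles to integrate (the last one is reported).
#' @param init_state optional solver state from a previous run (warm
#'   start); see the `state` element of the returned object.
#' @param picard_tol relative tolerance of the within-step nonlinear
#'   iteration.
#' @param picard_maxit within-step iteration cap.
#' @return object of class `simulation_result`: matrices `P` (mmHg), `Q`
#'   (mL/s), `A` (cm^2) of size nodes x nt over the reporting cycle; the
#'   node map; per-cycle periodicity metrics; inflow/outflow volumes (mL);
#'   and the final solver `state`.
#' @export
run_simulation <- function(net, inlet, n_cycles = 10, init_state = NULL,
                           picard_tol = 1e-8, picard_maxit = 50) {
  packed <- pack_network(net)
  if (is.null(init_state)) init_state <- dc_init_state(net, packed, inlet)
  inflow <- rep(inlet$Q, n_cycles) * 1e-6 # mL/s -> m^3/s
  out <- .pulse_solver_cpp(packed, inflow, inlet$dt, inlet$nt,
                           as.integer(n_cycles), wall_si(net$wall),
                           net$blood,
                           list(picard_tol = picard_tol,
                                picard_maxit = as.integer(picard_maxit)),
                           init_state)
  nmap <- node_map(net)
  term_names <- sub("^@term_", "", packed$bnd_ids[packed$bnd_type == 2L])
  term_vol <- out$terminal_volume[packed$bnd_type == 2L] * 1e6
  res <- structure(list(
    P = out$P / PA_PER_MMHG,
    Q = out$Q * 1e6,
    A = out$A * 1e4,
    t = inlet$t,
    node_map = nmap,
    cycle_metric = as.numeric(out$cycle_metric),
    inflow_volume = out$inflow_volume * 1e6,
    terminal_volume = stats::setNames(term_vol, term_names),
    state = out$state,
    inlet = inlet, zeta = net$blood$zeta),
    class = "simulation_result")
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>", nrow(x$P), "nodes x", ncol(x$P), "steps;",
      "final periodicity metric =",
      signif(utils::tail(stats::na.omit(x$cycle_metric), 1), 3), "\n")
  invisible(x)
}

#' Node bookkeeping for a network
#' @keywords internal
node_map <- function(net) {
  seg <- net$segments
  data.frame(segment = rep(seg$id, seg$n_nodes),
             local = unlist(lapply(seg$n_nodes, seq_len)),
             n_nodes = rep(seg$n_nodes, seg$n_nodes),
             stringsAsFactors = FALSE)
}

#' Index of a probe node
#'
#' @param result a `simulation_result` (or a `vessel_network`).
#' @param segment segment id.
#' @param where `"mid"`, `"start"` or `"end"` of the segment.
#' @return integer row index into the waveform matrices.
#' @export
probe_index <- function(result, segment, where = c("mid", "start", "end")) {
  where <- match.arg(where)
  nmap <- if (inherits(result, "simulation_result")) result$node_map else node_map(result)
  idx <- which(nmap$segment == segment)
  if (!length(idx)) stop("unknown probe segment '", segment, "'")
  n <- length(idx)
  idx[switch(where, start = 1L, end = n, mid = as.integer(ceiling(n / 2)))]
}

#' Extract a probe waveform
#'
#' @inheritParams probe_index
#' @return data.frame with `t` (s), `P_mmHg`, `Q_mL_s`, `A_cm2`, `v_cm_s`
#'   (centerline velocity, `(zeta+2)/zeta` times the mean velocity).
#' @export
probe_waveform <- function(result, segment, where = "mid") {
  i <- probe_index(result, segment, where)
  vbar <- result$Q[i, ] / result$A[i, ] # cm/s (mL/s / cm^2)
  zeta <- result$zeta
  data.frame(t = result$t, P_mmHg = result$P[i, ], Q_mL_s = result$Q[i, ],
             A_cm2 = result$A[i, ], v_cm_s = vbar * (zeta + 2) / zeta)
}

#' Mean flow through a segment (mid-segment, reporting cycle)
#' @param result a `simulation_result`.
#' @param segment segment id.
#' @return mean flow, mL/s.
#' @export
segment_mean_flow <- function(result, segment) {
  mean(result$Q[probe_index(result, segment, "mid"), ])
}

#' Mean pressure at a probe
#' @inheritParams segment_mean_flow
#' @param where probe position within the segment.
#' @return mean pressure, mmHg.
#' @export
segment_mean_pressure <- function(result, segment, where = "mid") {
  mean(result$P[probe_index(result, segment, where), ])
}

#' Cycle volume balance
#'
#' Inflow volume minus total terminal outflow volume over the reporting
#' cycle, as a fraction of the inflow volume. Near periodic steady state
#' the wall and Windkessel storage terms cancel and this is close to zero.
#'
#' @param result a `simulation_result`.
#' @return signed relative volume error.
#' @export
volume_balance <- function(result) {
  (result$inflow_volume - sum(result$terminal_volume)) / result$inflow_volume
}
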