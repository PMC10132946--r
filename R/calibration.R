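# The staged calibration loop: terminal resistances to MAP and regional
# flows (step 1), reference diameters to wall-shear targets (step 2),
# terminal compliances to SBP and UA-PI (step 3), iterated until all
# targets are met simultaneously.

#' Calibration controls
#'
#' @param tol relative target tolerance (default 2 percent).
#' @param damping multiplicative damping of the fixed-point resistance and
#'   diameter updates.
#' @param max_iter_step iteration cap inside each step.
#' @param max_outer outer loop cap over the three steps.
#' @param nt time steps per cardiac cycle.
#' @param n_cycles_inner cycles per tuning simulation (warm-started from
#'   the previous solver state, so the periodic regime carries over).
#' @param n_cycles_final cycles of the reporting simulation.
#' @param aRTC_bounds admissible range of the terminal time constant, s.
#' @param verbose print per-iteration tuning logs.
#' @return list of class `calibration_control`.
#' @export
calibration_control <- function(tol = 0.02, damping = 0.8, max_iter_step = 50,
                                max_outer = 20, nt = 500, n_cycles_inner = 5,
                                n_cycles_final = 10,
                                aRTC_bounds = c(1e-3, 30), verbose = FALSE) {
  structure(as.list(environment()), class = "calibration_control")
}

# One tuning simulation plus the measurements every step needs.
#' @keywords internal
measure_network <- function(net, inlet, control, state = NULL,
                            n_cycles = control$n_cycles_inner) {
  res <- run_simulation(net, inlet, n_cycles = n_cycles, init_state = state)
  term <- net$terminals
  q_term <- res$terminal_volume[term$segment_id] / inlet$tc # mL/s
  group_flows <- tapply(q_term, term$group, sum)
  seg <- net$segments
  qbar <- vapply(seg$id, function(id) segment_mean_flow(res, id), 0)
  a_vivo <- vapply(seg$id, function(id)
    mean(res$A[probe_index(res, id, "mid"), ]), 0)
  d_vivo <- sqrt(4 * a_vivo / pi)
  tau <- mean_wall_shear(qbar, d_vivo, net$blood$mu)
  uterine <- seg$id[seg$region == "uterine"]
  ua_pi <- if (length(uterine)) {
    v <- probe_waveform(res, uterine[1], "mid")$v_cm_s
    pulsatility_index(v)
  } else NA_real_
  p_ao <- res$P[probe_index(res, net$inlet_segment, "start"), ]
  list(result = res, state = res$state,
       MAP = mean(p_ao), SBP = max(p_ao), DBP = min(p_ao),
       group_flows = group_flows, q_term = q_term,
       uterine_flow = sum(q_term[term$group == "uterine"]),
       seg_flow = qbar, d_vivo = stats::setNames(d_vivo, seg$id),
       tau = stats::setNames(tau, seg$id), UA_PI = ua_pi)
}

# Regional flow targets (mL/s) per terminal group.
#' @keywords internal
group_targets <- function(net, targets) {
  co_mls <- targets$CO * 1000 / 60
  g <- c(targets$fractions * co_mls, uterine = targets$uterine_flow)
  g["trunk"] <- co_mls - sum(g)
  g[unique(net$terminals$group)]
}

#' @keywords internal
step1_residuals <- function(meas, net, targets) {
  gt <- group_targets(net, targets)
  c(MAP = abs(meas$MAP - targets$MAP) / targets$MAP,
    stats::setNames(abs(meas$group_flows[names(gt)] - gt) / gt,
                    paste0("flow_", names(gt))))
}

#' Step 1: tune terminal resistances to MAP and regional flows
#'
#' Damped multiplicative fixed-point update: each terminal group's total
#' resistance is scaled by its flow mismatch, then all terminals are
#' rescaled together so that the DC-predicted mean pressure meets the MAP
#' target (flows redistribute by resistance ratios; the overall scale sets
#' MAP at the prescribed inflow). `R1` is re-derived from the
#' characteristic impedance with the 5--40 percent clamp after every
#' update.
#'
#' @param net a `vessel_network`.
#' @param targets a [targets_for()] target set.
#' @param inlet an [build_inlet()] waveform.
#' @param control a [calibration_control()].
#' @param state optional warm-start solver state.
#' @return list with the tuned `net`, last `meas`urement, iteration count,
#'   and final `residuals`.
#' @export
step1_tune_resistances <- function(net, targets, inlet,
                                   control = calibration_control(),
                                   state = NULL) {
  gt <- group_targets(net, targets)
  co_mls <- targets$CO * 1000 / 60
  for (it in seq_len(control$max_iter_step)) {
    meas <- measure_network(net, inlet, control, state)
    state <- meas$state
    resid <- step1_residuals(meas, net, targets)
    if (control$verbose)
      message(sprintf("  step1 it %d: MAP %.2f (tgt %.2f), max resid %.4f",
                      it, meas$MAP, targets$MAP, max(resid)))
    if (max(resid) <= control$tol)
      return(list(net = net, meas = meas, iterations = it - 1L,
                  residuals = resid, state = state))
    term <- net$terminals
    RT <- stats::setNames(term$R1 + term$R2, term$segment_id)
    fg <- (meas$group_flows[term$group] / gt[term$group])^control$damping
    RT_new <- RT * as.numeric(fg)
    # rescale all terminals so the DC prediction hits the MAP target
    Rp_old <- 1 / sum(1 / RT)
    Rp_new <- 1 / sum(1 / RT_new)
    k <- (targets$MAP - meas$MAP + co_mls * Rp_old) / (co_mls * Rp_new)
    k <- max(k, 0.05)
    net <- refresh_terminals(net, RT_new * k)
  }
  stop("step 1 failed to converge after ", control$max_iter_step,
       " iterations; residuals: ",
       paste(names(resid), signif(resid, 3), sep = "=", collapse = ", "))
}

# Refresh every segment's reference distensibility from its current
# diameter. The nongravid tree (s = 0) and all non-uterine vessels follow
# the wave-speed law; the gravid uterine circuit follows the sigmoidal
# remodeling law anchored at its nongravid reference. The scenario's
# preexisting-stiffness multiplier acts on the systemic (non-uterine)
# vessels, whose stiffness the clinical pulse-wave metrics probe.
#' @keywords internal
refresh_wall <- function(net, targets, rp = remodeling_params()) {
  seg <- net$segments
  ut <- seg$region %in% c("uterine", "arcuate", "radial_ut")
  for (i in seq_len(nrow(seg))) {
    if (ut[i] && targets$s > 0) {
      g <- growth_stretches(seg$diameter_cm[i] / seg$diameter0_cm[i],
                            targets$lambda_z, targets$s)
      seg$Dref_kPa[i] <- remodel_reference_distensibility(seg$Dref0_kPa[i], g, rp)
    } else if (ut[i]) {
      seg$Dref_kPa[i] <-
        reference_distensibility(seg$diameter_cm[i], net$blood$rho, net$wall)
    } else {
      seg$Dref_kPa[i] <- targets$stiffness *
        reference_distensibility(seg$diameter_cm[i], net$blood$rho, net$wall)
    }
  }
  net$segments <- seg
  net
}

#' Step 2: grow reference diameters to wall-shear targets
#'
#' Each segment's reference diameter is updated by the cube-root rule
#' implied by `tau = 32 mu Q / (pi d^3)` at its simulated mean flow, the
#' wall law is refreshed (wave-speed law for the baseline tree, remodeling
#' law for the gravid uterine circuit), and the step-1 resistance update is
#' interleaved so MAP and flows stay on target while the tree grows.
#'
#' @inheritParams step1_tune_resistances
#' @return as [step1_tune_resistances()], with shear residuals included.
#' @export
step2_tune_diameters <- function(net, targets, inlet,
                                 control = calibration_control(),
                                 state = NULL) {
  for (it in seq_len(control$max_iter_step)) {
    s1 <- step1_tune_resistances(net, targets, inlet, control, state)
    net <- s1$net; meas <- s1$meas; state <- s1$state
    tauT <- net$segments$tau_target_Pa *
      ifelse(net$segments$region %in% c("uterine", "arcuate", "radial_ut"),
             targets$tau_uterine_mom, 1)
    resid_tau <- abs(meas$tau - tauT) / tauT
    if (control$verbose)
      message(sprintf("  step2 it %d: max shear resid %.4f", it, max(resid_tau)))
    if (max(resid_tau) <= control$tol)
      return(list(net = net, meas = meas, iterations = it - 1L,
                  residuals = c(s1$residuals,
                                shear = max(resid_tau)), state = state))
    ratio <- (meas$tau / tauT)^(control$damping / 3)
    seg <- net$segments
    seg$diameter_cm <- seg$diameter_cm * ratio
    seg$Aref_cm2 <- pi * seg$diameter_cm^2 / 4
    net$segments <- seg
    net <- refresh_wall(net, targets)
    net <- refresh_terminals(net)
  }
  stop("step 2 failed to converge after ", control$max_iter_step,
       " iterations; max shear residual ", signif(max(resid_tau), 3))
}

# Set the terminal time constant of a subset of terminals and re-derive C.
#' @keywords internal
set_aRTC <- function(net, which_terms, aRTC) {
  term <- net$terminals
  term$aRTC[term$segment_id %in% which_terms] <- aRTC
  net$terminals <- term
  refresh_terminals(net)
}

# Bracketing/secant search for a scalar control in log space.
#' @keywords internal
tune_scalar <- function(eval_f, u0, lo, hi, tol, maxit = 12, verbose = FALSE,
                        label = "") {
  # eval_f(u) returns list(err = log(measured/target), payload = ...)
  u <- min(max(u0, lo), hi)
  e <- eval_f(u)
  best <- list(u = u, e = e)
  if (abs(e$err) <= tol) return(best)
  hist_u <- u; hist_e <- e$err
  u2 <- min(max(u + 0.5 * sign(-e$err + 1e-12), lo), hi)
  for (it in seq_len(maxit)) {
    if (any(abs(hist_u - u2) < 1e-3)) break # control pinned / search stalled
    e2 <- eval_f(u2)
    if (verbose) message(sprintf("    tune %s: u=%.3f err=%.4f", label, u2, e2$err))
    hist_u <- c(hist_u, u2); hist_e <- c(hist_e, e2$err)
    if (abs(e2$err) < abs(best$e$err)) best <- list(u = u2, e = e2)
    if (abs(e2$err) <= tol) return(best)
    # bracket available?
    pos <- hist_u[hist_e > 0]; neg <- hist_u[hist_e < 0]
    if (length(pos) && length(neg)) {
      # secant through the two points closest to the root, clamped inside
      # the tightest bracket
      i_p <- pos[which.min(abs(hist_e[hist_e > 0]))]
      i_n <- neg[which.min(abs(hist_e[hist_e < 0]))]
      e_p <- min(hist_e[hist_e > 0]); e_n <- max(hist_e[hist_e < 0])
      u_try <- i_n + (i_p - i_n) * (-e_n) / (e_p - e_n)
      b_lo <- min(i_p, i_n); b_hi <- max(i_p, i_n)
      if (!is.finite(u_try) || u_try <= b_lo || u_try >= b_hi)
        u_try <- (b_lo + b_hi) / 2
      u2 <- u_try
    } else {
      # keep stepping in the direction that reduces |err|
      d <- if (length(hist_u) >= 2 &&
               diff(utils::tail(abs(hist_e), 2)) < 0)
        utils::tail(diff(hist_u), 1) else -utils::tail(diff(hist_u), 1)
      if (d == 0) d <- 0.5
      u2 <- min(max(u2 + 1.5 * d, lo), hi)
    }
  }
  # leave the evaluated state at the best control found
  if (abs(utils::tail(hist_u, 1) - best$u) > 1e-9) best$e <- eval_f(best$u)
  best
}

#' Step 3: tune terminal compliances to SBP and UA-PI
#'
#' Two scalar controls are adjusted in log space by a bracketing secant
#' search: the global terminal time constant `aRTC` (all terminals except
#' the uterine radials) against the systolic pressure target, and the
#' time constant of the placentally engaged uterine radials (all radials
#' for the nongravid state, `s = 0`) against the uterine artery
#' pulsatility index target. Non-engaged radials keep their nongravid
#' value. The two searches alternate until both targets are met.
#'
#' @inheritParams step1_tune_resistances
#' @return as [step1_tune_resistances()].
#' @export
step3_tune_compliances <- function(net, targets, inlet,
                                   control = calibration_control(),
                                   state = NULL) {
  term <- net$terminals
  seg <- net$segments
  radials <- seg$id[seg$region == "radial_ut"]
  tuned_radials <- if (targets$s == 0) radials else
    seg$id[seg$region == "radial_ut" & seg$placental_engaged]
  others <- setdiff(term$segment_id, radials)
  lo <- log(control$aRTC_bounds[1]); hi <- log(control$aRTC_bounds[2])
  env <- new.env()
  env$net <- net; env$state <- state; env$meas <- NULL
  eval_sbp <- function(u) {
    env$net <- set_aRTC(env$net, others, exp(u))
    m <- measure_network(env$net, inlet, control, env$state)
    env$state <- m$state; env$meas <- m
    list(err = log(m$SBP / targets$SBP), payload = NULL)
  }
  eval_pi <- function(u) {
    env$net <- set_aRTC(env$net, tuned_radials, exp(u))
    m <- measure_network(env$net, inlet, control, env$state)
    env$state <- m$state; env$meas <- m
    list(err = log(m$UA_PI / targets$UA_PI), payload = NULL)
  }
  tol_log <- log(1 + control$tol)
  iters <- 0L
  for (round in 1:4) {
    u_g <- log(term$aRTC[match(others[1], term$segment_id)])
    b1 <- tune_scalar(eval_sbp, u_g, lo, hi, tol_log,
                      verbose = control$verbose, label = "aRTC")
    u_r <- log(env$net$terminals$aRTC[
      match(tuned_radials[1], env$net$terminals$segment_id)])
    b2 <- tune_scalar(eval_pi, u_r, lo, hi, tol_log,
                      verbose = control$verbose, label = "aRTC_radial")
    term <- env$net$terminals
    iters <- iters + 1L
    m <- env$meas
    ok_sbp <- abs(m$SBP - targets$SBP) / targets$SBP <= control$tol
    ok_pi <- abs(m$UA_PI - targets$UA_PI) / targets$UA_PI <= control$tol
    if (ok_sbp && ok_pi) break
  }
  m <- env$meas
  list(net = env$net, meas = m, iterations = iters,
       residuals = c(SBP = abs(m$SBP - targets$SBP) / targets$SBP,
                     UA_PI = abs(m$UA_PI - targets$UA_PI) / targets$UA_PI),
       state = env$state)
}

#' Calibrate the network to one scenario and gestational age
#'
#' Runs the three tuning steps in order, iterating the loop until every
#' target (MAP, regional flows, wall shear, SBP, UA-PI) is within the
#' relative tolerance simultaneously, then verifies with a reporting
#' simulation.
#'
#' @param net a `vessel_network` carrying nongravid reference state
#'   (`diameter0_cm`, `Dref0_kPa`, `tau_target_Pa`; see
#'   [calibrate_nongravid()]).
#' @param scenario a [scenario_spec()].
#' @param s gestational age, weeks.
#' @param baseline a [pregnancy_baseline()].
#' @param control a [calibration_control()].
#' @param state optional warm-start solver state.
#' @return object of class `calibration_result`: the tuned network, the
#'   `converged` flag, named residuals, iteration counts, the target set,
#'   the reporting `simulation_result`, and summary `metrics`.
#' @export
calibrate <- function(net, scenario, s, baseline = pregnancy_baseline(),
                      control = calibration_control(), state = NULL) {
  targets <- targets_for(s, scenario, baseline, tolerance = control$tol)
  inlet <- build_inlet(targets$CO, targets$HR, nt = control$nt)
  net <- refresh_wall(net, targets)
  net <- refresh_terminals(net)
  iterations <- list(step1 = 0L, step2 = 0L, step3 = 0L, outer = 0L)
  converged <- FALSE
  prev_max <- Inf
  for (outer in seq_len(control$max_outer)) {
    s1 <- step1_tune_resistances(net, targets, inlet, control, state)
    net <- s1$net; state <- s1$state
    s2 <- step2_tune_diameters(net, targets, inlet, control, state)
    net <- s2$net; state <- s2$state
    s3 <- step3_tune_compliances(net, targets, inlet, control, state)
    net <- s3$net; state <- s3$state
    iterations$step1 <- iterations$step1 + s1$iterations
    iterations$step2 <- iterations$step2 + s2$iterations
    iterations$step3 <- iterations$step3 + s3$iterations
    iterations$outer <- outer
    resid <- c(step1_residuals(s3$meas, net, targets),
               shear = unname(s2$residuals["shear"]), s3$residuals)
    if (control$verbose)
      message(sprintf("outer %d: max residual %.4f", outer, max(resid)))
    if (max(resid) <= control$tol) { converged <- TRUE; break }
    # stop early when the loop has stalled (e.g. a compliance control
    # pinned at its bound): further rounds repeat the same state
    if (max(resid) > 0.95 * prev_max && outer >= 2) break
    prev_max <- max(resid)
  }
  final <- run_simulation(net, inlet, n_cycles = control$n_cycles_final,
                          init_state = state)
  metrics <- simulation_metrics(final, net)
  meas_final <- list(MAP = metrics$MAP, SBP = metrics$SBP,
                     UA_PI = metrics$UA_PI)
  structure(list(network = net, converged = converged,
                 residuals = resid, iterations = iterations,
                 targets = targets, result = final, metrics = metrics,
                 state = final$state),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>", x$targets$scenario, "at", x$targets$s,
      "weeks;", if (x$converged) "converged" else "NOT converged",
      "(max residual", signif(max(x$residuals), 3), ")\n")
  cat(sprintf("  MAP %.1f mmHg (target %.1f), SBP %.1f, UA-PI %.2f (target %.2f)\n",
              x$metrics$MAP, x$targets$MAP, x$metrics$SBP,
              x$metrics$UA_PI, x$targets$UA_PI))
  invisible(x)
}

#' Establish the nongravid reference state
#'
#' Calibrates the generated tree to the normal-scenario targets at
#' conception: step 1 sets the terminal resistances, the wall-shear targets
#' are then bootstrapped from the simulated nongravid shear field (with the
#' arcuate and radial uterine targets coupled to the uterine-artery value
#' by the 1.05x and 1.10x rules), step 2 conforms the diameters, and step 3
#' sets the compliances. The resulting diameters and distensibilities are
#' frozen as the nongravid reference (`diameter0_cm`, `Dref0_kPa`) that
#' gestational growth stretches and remodeling are measured against.
#'
#' @param net a freshly generated `vessel_network`.
#' @param baseline a [pregnancy_baseline()].
#' @param control a [calibration_control()].
#' @return a `calibration_result` whose `network` is the nongravid
#'   reference.
#' @export
calibrate_nongravid <- function(net, baseline = pregnancy_baseline(),
                                control = calibration_control()) {
  scenario <- scenario_spec("normal")
  targets <- targets_for(0, scenario, baseline, tolerance = control$tol)
  inlet <- build_inlet(targets$CO, targets$HR, nt = control$nt)
  s1 <- step1_tune_resistances(net, targets, inlet, control)
  net <- s1$net
  # bootstrap shear targets from the nongravid flow field
  tau <- s1$meas$tau
  seg <- net$segments
  ut_mean <- mean(tau[seg$id[seg$region == "uterine"]])
  tauT <- ifelse(seg$region == "uterine", ut_mean,
          ifelse(seg$region == "arcuate", 1.05 * ut_mean,
          ifelse(seg$region == "radial_ut", 1.10 * ut_mean, tau[seg$id])))
  net$segments$tau_target_Pa <- as.numeric(tauT)
  cal <- calibrate(net, scenario, 0, baseline, control, state = s1$state)
  # freeze the nongravid reference state
  cal$network$segments$diameter0_cm <- cal$network$segments$diameter_cm
  cal$network$segments$Dref0_kPa <- reference_distensibility(
    cal$network$segments$diameter_cm, cal$network$blood$rho, cal$network$wall)
  cal$network <- refresh_wall(cal$network, cal$targets)
  cal
}

#' Calibrate a scenario across gestational ages
#'
#' Sweeps the gestational ages in ascending order, warm-starting each
#' calibration from the previous age's tuned network and solver state (the
#' fluid-solid-growth-remodeling trajectory).
#'
#' @param ref_net the nongravid reference network from
#'   [calibrate_nongravid()].
#' @param scenario a [scenario_spec()].
#' @param ages gestational ages, weeks.
#' @param baseline a [pregnancy_baseline()].
#' @param control a [calibration_control()].
#' @return named list of `calibration_result`s keyed by age.
#' @export
calibrate_sweep <- function(ref_net, scenario, ages,
                            baseline = pregnancy_baseline(),
                            control = calibration_control()) {
  ages <- sort(ages)
  out <- list()
  net <- ref_net
  state <- NULL
  for (s in ages) {
    cal <- calibrate(net, scenario, s, baseline, control, state)
    out[[as.character(s)]] <- cal
    net <- cal$network
    state <- cal$state
  }
  out
}
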