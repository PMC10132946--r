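# Hemodynamic summary metrics computed from simulated waveforms.

#' Pulsatility index of a velocity waveform
#'
#' Gosling's index `(max v - min v) / mean v` over one full cycle, the
#' standard obstetric-Doppler definition used for the uterine artery.
#'
#' @param v velocity samples over one cycle (any consistent unit).
#' @return dimensionless PI.
#' @export
pulsatility_index <- function(v) {
  m <- mean(v)
  if (m <= 0) stop("domain error: nonpositive mean velocity (reversed mean flow?)")
  (max(v) - min(v)) / m
}

#' Mean wall shear stress from mean flow and diameter
#'
#' Poiseuille relation `tau = 32 mu Qbar / (pi d^3)`.
#'
#' @param Q_bar mean flow, mL/s.
#' @param d diameter, cm.
#' @param mu viscosity, Pa s.
#' @return wall shear stress, Pa.
#' @export
mean_wall_shear <- function(Q_bar, d, mu = 0.004) {
  stopifnot(all(d > 0))
  32 * mu * (Q_bar * 1e-6) / (pi * (d / 100)^3)
}

#' Total peripheral resistance
#'
#' `TPR = MAP / CO` with the venous pressure neglected.
#'
#' @param MAP mean arterial pressure, mmHg.
#' @param CO cardiac output, L/min.
#' @return TPR, mmHg min/L.
#' @export
total_peripheral_resistance <- function(MAP, CO) {
  if (any(CO <= 0)) stop("domain error: nonpositive cardiac output")
  MAP / CO
}

#' Multiples of the mean
#'
#' Ratio of a quantity in a complicated pregnancy to the matched
#' normal-pregnancy value.
#'
#' @param value,normal_value the two values (same units).
#' @return dimensionless MoM.
#' @export
mom <- function(value, normal_value) {
  if (any(normal_value == 0)) stop("domain error: zero normal value in MoM")
  value / normal_value
}

#' Root mean square error between data points and a model curve
#'
#' @param data numeric vector of observed values.
#' @param model numeric vector of model values at the same gestational ages.
#' @return `sqrt(mean((data - model)^2))`.
#' @export
rmse <- function(data, model) {
  if (length(data) == 0) stop("domain error: empty data")
  stopifnot(length(data) == length(model))
  sqrt(mean((data - model)^2))
}

#' Waveform foot by the intersecting-tangent method
#'
#' The foot is where the tangent at the point of steepest systolic upstroke
#' intersects the horizontal line through the cycle minimum.
#'
#' @param t time grid, s.
#' @param p pressure samples over one cycle.
#' @return foot time, s.
#' @export
waveform_foot <- function(t, p) {
  n <- length(p)
  dp <- c(diff(p), p[1] - p[n]) / c(diff(t), t[2] - t[1])
  # steepest upstroke in the first half of the cycle after the minimum
  i_min <- which.min(p)
  order_idx <- c(seq(i_min, n), seq_len(i_min - 1))
  upstroke <- order_idx[seq_len(ceiling(n / 2))]
  i_up <- upstroke[which.max(dp[upstroke])]
  t_up <- t[i_up]
  # unwrap time if the upstroke wrapped past the cycle end
  if (i_up < i_min) t_up <- t_up + (t[n] - t[1] + (t[2] - t[1]))
  t_foot <- t_up - (p[i_up] - min(p)) / dp[i_up]
  t_foot
}

#' Foot-to-foot pulse wave velocity
#'
#' Transit-time PWV between two pressure waveforms on the same time grid,
#' with feet located by the intersecting-tangent method. For the clinical
#' carotid-femoral convention, pass the subtracted path length
#' (inlet-to-femoral minus inlet-to-carotid distance).
#'
#' @param t time grid, s.
#' @param p_proximal,p_distal pressure waveforms at the two sites.
#' @param path_length_cm path length between the sites, cm.
#' @param tc cycle period, s (used to unwrap a negative transit time when
#'   the distal foot falls in the next cycle).
#' @return PWV, m/s.
#' @export
pwv_foot_to_foot <- function(t, p_proximal, p_distal, path_length_cm,
                             tc = max(t)) {
  stopifnot(path_length_cm > 0)
  dt_transit <- waveform_foot(t, p_distal) - waveform_foot(t, p_proximal)
  if (dt_transit <= -tc / 2) dt_transit <- dt_transit + tc
  if (dt_transit <= 0) stop("measurement error: nonpositive transit time (sites mis-ordered?)")
  (path_length_cm / 100) / dt_transit
}

#' Blood pressure summary of one cycle
#'
#' @param p pressure samples over one cycle, mmHg.
#' @return list with `SBP`, `DBP`, `MAP` (time mean), and `PP = SBP - DBP`.
#' @export
pressure_summary <- function(p) {
  list(SBP = max(p), DBP = min(p), MAP = mean(p), PP = max(p) - min(p))
}

#' Augmentation index from an aortic pressure waveform
#'
#' `P1` is the first systolic peak after the foot (the advancing pressure
#' wave); `P2` is the largest pressure in the later systolic window (the
#' composite of advancing and reflected waves). `AIx = 100 (P2 - P1) / PP`
#' and the heart-rate-normalized `AIx75 = 0.39 (HR - 75) + AIx`. With weak
#' or late reflections `P2 < P1` and the augmentation is negative
#' (young-type waveform); stiffer trees return earlier, stronger
#' reflections and a higher AIx. When no systolic peak is detectable the
#' result is flagged undefined (`NA`) rather than an error.
#'
#' @param t time grid, s.
#' @param p aortic pressure over one cycle, mmHg.
#' @param HR heart rate, bpm.
#' @param smooth half-width (samples) of the moving-average smoothing
#'   applied before peak detection.
#' @return list with `P1`, `P2`, `AP`, `AIx` (percent of pulse pressure),
#'   `AIx75`, `SBP`, `DBP`, `PP`.
#' @export
augmentation_index <- function(t, p, HR, smooth = 5) {
  n <- length(p)
  ps <- pressure_summary(p)
  # rotate so the cycle starts at the foot (diastolic minimum)
  i0 <- which.min(p)
  pr <- p[c(seq(i0, n), seq_len(i0 - 1))]
  pr_s <- pr
  if (smooth > 0) {
    k <- 2 * smooth + 1
    prx <- stats::filter(rep(pr, 3), rep(1 / k, k), sides = 2)
    pr_s <- as.numeric(prx[(n + 1):(2 * n)])
  }
  d <- diff(pr_s)
  locmax <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  locmax <- locmax[locmax > round(0.02 * n) & locmax < round(0.6 * n)]
  if (!length(locmax)) {
    return(list(P1 = NA_real_, P2 = NA_real_, AP = NA_real_, AIx = NA_real_,
                AIx75 = NA_real_, SBP = ps$SBP, DBP = ps$DBP, PP = ps$PP))
  }
  i1 <- locmax[1]
  win <- seq(min(i1 + round(0.04 * n), n), round(0.6 * n))
  P1 <- pr[i1]
  P2 <- max(pr[win])
  # no reflected energy: pressure has decayed to near-diastolic right
  # after the first peak, so the augmentation is undefined
  if (P2 < min(pr) + 0.3 * ps$PP) {
    return(list(P1 = P1, P2 = NA_real_, AP = NA_real_, AIx = NA_real_,
                AIx75 = NA_real_, SBP = ps$SBP, DBP = ps$DBP, PP = ps$PP))
  }
  AP <- P2 - P1
  AIx <- 100 * AP / ps$PP
  list(P1 = P1, P2 = P2, AP = AP, AIx = AIx,
       AIx75 = 0.39 * (HR - 75) + AIx, SBP = ps$SBP, DBP = ps$DBP, PP = ps$PP)
}

#' Summary metrics of a simulation at standard probe sites
#'
#' @param result a `simulation_result`.
#' @param net the simulated `vessel_network`.
#' @param probes named list of probe sites; defaults cover the aortic root,
#'   carotid, femoral, radial arm and uterine arteries of the reduced tree.
#' @return list with pressure summary at the aortic root, uterine PI,
#'   bilateral uterine flow (mL/s), cf-PWV and cr-PWV (m/s), and AIx75.
#' @export
simulation_metrics <- function(result, net, probes = NULL) {
  seg <- net$segments
  uterine <- seg$id[seg$region == "uterine"]
  aorta_root <- net$inlet_segment
  p_ao <- result$P[probe_index(result, aorta_root, "start"), ]
  ps <- pressure_summary(p_ao)
  ua_pi <- if (length(uterine)) {
    v <- probe_waveform(result, uterine[1], "mid")$v_cm_s
    pulsatility_index(v)
  } else NA_real_
  ua_flow <- if (length(uterine))
    sum(vapply(uterine, function(s) segment_mean_flow(result, s), 0)) else NA_real_
  # PWV paths along the tree
  pwv <- tryCatch({
    pl <- path_lengths(net)
    len <- stats::setNames(seg$length_cm, seg$id)
    probe_dist <- function(id) pl[[id]] - len[[id]] / 2 # mid-segment probe
    pair_pwv <- function(prox, dist) {
      if (!all(c(prox, dist) %in% seg$id)) return(NA_real_)
      pwv_foot_to_foot(result$t,
                       result$P[probe_index(result, prox, "mid"), ],
                       result$P[probe_index(result, dist, "mid"), ],
                       probe_dist(dist) - probe_dist(prox),
                       tc = result$inlet$tc)
    }
    list(cf = pair_pwv("carotid", "femoral_L"),
         cr = pair_pwv("carotid", "radial_arm"))
  }, error = function(e) list(cf = NA_real_, cr = NA_real_))
  aix <- augmentation_index(result$t, p_ao, result$inlet$HR)
  list(SBP = ps$SBP, DBP = ps$DBP, MAP = ps$MAP, PP = ps$PP,
       UA_PI = ua_pi, UA_flow = ua_flow,
       cf_PWV = pwv$cf, cr_PWV = pwv$cr,
       AIx = aix$AIx, AIx75 = aix$AIx75)
}

# Distance from the inlet to the distal end of each segment, cm.
#' @keywords internal
path_lengths <- function(net) {
  seg <- net$segments
  len <- stats::setNames(seg$length_cm, seg$id)
  parent <- stats::setNames(seg$parent, seg$id)
  out <- list()
  for (id in seg$id) {
    d <- 0; cur <- id
    while (!is.na(cur)) { d <- d + len[[cur]]; cur <- parent[[cur]] }
    out[[id]] <- d
  }
  out
}
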