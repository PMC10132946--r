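# Gestational input/target trajectories for the three illustrative
# pregnancy scenarios (normal, early preeclampsia, late preeclampsia),
# encoded as anchor points with monotone piecewise-cubic interpolation.

#' A gestational anchor curve
#'
#' Monotone piecewise-cubic (Fritsch-Carlson) interpolation through anchor
#' points on gestational age; evaluation at an anchor returns the anchor
#' value exactly and no overshoot is introduced between anchors.
#'
#' @param s anchor gestational ages, weeks (sorted, within 0--40).
#' @param value anchor values.
#' @return function of `s` of class `gestational_curve`.
#' @export
gestational_curve <- function(s, value) {
  stopifnot(length(s) == length(value), !is.unsorted(s), s[1] >= 0,
            s[length(s)] <= 40)
  n <- length(s)
  if (n == 1) {
    f <- function(x) rep(value, length(x))
  } else {
    # Fritsch-Butland slopes: zero at interior extrema, so the cubic
    # Hermite interpolant never leaves the range of neighbouring anchors
    h <- diff(s)
    delta <- diff(value) / h
    m <- numeric(n)
    if (n > 2) {
      for (i in 2:(n - 1)) {
        if (delta[i - 1] * delta[i] <= 0) {
          m[i] <- 0
        } else {
          w1 <- 2 * h[i] + h[i - 1]
          w2 <- h[i] + 2 * h[i - 1]
          m[i] <- (w1 + w2) / (w1 / delta[i - 1] + w2 / delta[i])
        }
      }
    }
    clip <- function(m_end, d) if (d == 0) 0 else sign(d) * min(abs(m_end), 3 * abs(d))
    m[1] <- clip(delta[1], delta[1])
    m[n] <- clip(delta[n - 1], delta[n - 1])
    f <- function(x) {
      i <- findInterval(x, s, rightmost.closed = TRUE)
      i <- pmin(pmax(i, 1L), n - 1L)
      t_ <- (x - s[i]) / h[i]
      h00 <- (1 + 2 * t_) * (1 - t_)^2
      h10 <- t_ * (1 - t_)^2
      h01 <- t_^2 * (3 - 2 * t_)
      h11 <- t_^2 * (t_ - 1)
      h00 * value[i] + h10 * h[i] * m[i] + h01 * value[i + 1] +
        h11 * h[i] * m[i + 1]
    }
  }
  structure(function(x) {
    if (any(x < 0 | x > 40)) stop("domain error: gestational age outside [0, 40] weeks")
    f(pmin(pmax(x, s[1]), s[length(s)]))
  }, class = c("gestational_curve", "function"),
  anchors = data.frame(s = s, value = value))
}

#' Normal-pregnancy baseline trajectories
#'
#' Absolute gestational curves for the uncomplicated pregnancy: cardiac
#' output rising 30 percent from conception to term, heart rate rising from
#' 70 to 85 bpm, a mid-gestational dip in mean arterial pressure, a
#' bilateral uterine flow fraction rising from 1 to 10 percent of cardiac
#' output (a greater than 8-fold flow increase), the characteristic fall of
#' the uterine artery pulsatility index, and the axial growth stretch of
#' uterine vessels.
#'
#' @param CO0,HR0,MAP0 nongravid cardiac output (L/min), heart rate (bpm)
#'   and mean pressure (mmHg).
#' @param pp_factor systolic target as a multiple of the mean pressure
#'   target (the pulse-pressure factor used to set the SBP target).
#' @param fractions regional flow fractions of CO (cerebral, limb, renal);
#'   the trunk absorbs the remainder after the uterine fraction.
#' @return list of class `pregnancy_baseline` of gestational curves and
#'   constants.
#' @export
pregnancy_baseline <- function(CO0 = 5.0, HR0 = 70, MAP0 = 85,
                               pp_factor = 1.38,
                               fractions = c(cerebral = 0.12, limb = 0.20,
                                             renal = 0.20)) {
  rel <- function(s, v) gestational_curve(s, v)
  structure(list(
    CO = rel(c(0, 8, 16, 24, 32, 40), CO0 * c(1, 1.12, 1.22, 1.28, 1.30, 1.30)),
    HR = rel(c(0, 12, 24, 32, 40), HR0 + c(0, 4, 9, 13, 15)),
    MAP = rel(c(0, 12, 20, 32, 40), MAP0 * c(1, 0.97, 0.953, 0.976, 1)),
    uterine_fraction = rel(c(0, 8, 16, 24, 32, 40),
                           c(0.010, 0.020, 0.045, 0.070, 0.090, 0.100)),
    UA_PI = rel(c(0, 8, 12, 16, 20, 28, 32, 36, 40),
                c(3.6, 2.7, 2.10, 1.55, 1.20, 0.95, 0.85, 0.82, 0.80)),
    lambda_z = rel(c(0, 12, 20, 32, 40), c(1, 1.15, 1.30, 1.50, 1.60)),
    tau_uterine_mom = rel(c(0, 40), c(1, 1)),
    pp_factor = pp_factor, fractions = fractions,
    CO0 = CO0, HR0 = HR0, MAP0 = MAP0), class = "pregnancy_baseline")
}

#' Scenario specification
#'
#' Multiples-of-the-mean multiplier curves applied to the normal baseline.
#' The normal scenario is the identity. The early-preeclampsia scenario
#' carries lower cardiac output (0.82 at 12 weeks, 0.80 beyond 20), total
#' peripheral resistance rising from 1.1-fold at conception through
#' 1.24-fold at 12 weeks to 1.7-fold at 32 weeks, a uterine artery
#' pulsatility index 1.4-fold higher at 12 weeks reaching 2.0-fold in the
#' third trimester, reduced uterine flow, impaired uterine axial growth,
#' and a preexisting-stiffness reduction of reference distensibility. The
#' late-preeclampsia scenario has slightly elevated cardiac output
#' (1.07-fold at 12 weeks, 1.05 beyond 20), near-normal resistance until 32
#' weeks rising to 1.14-fold at 36, and a mildly elevated pulsatility index
#' (1.1--1.2-fold through 32 weeks). The mean-pressure target is derived as
#' `MAP = MAP_normal x TPR_MoM x CO_MoM`, so the resistance anchors are
#' honored exactly by construction.
#'
#' @param name one of `"normal"`, `"early_pe"`, `"late_pe"`.
#' @param stiffness_multiplier factor (< 1 stiffer) applied to the
#'   reference distensibility of the systemic (non-uterine) vessels in the
#'   preeclampsia scenarios, representing preexisting large-artery
#'   stiffness; the uterine circuit follows its own remodeling law.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("normal", "early_pe", "late_pe"),
                          stiffness_multiplier = NULL) {
  name <- match.arg(name)
  one <- gestational_curve(c(0, 40), c(1, 1))
  sc <- switch(name,
    normal = list(co_mom = one, tpr_mom = one, uapi_mom = one,
                  ua_flow_mom = one, lambda_z_scale = 1, stiffness = 1),
    early_pe = list(
      co_mom = gestational_curve(c(0, 12, 20, 40), c(0.97, 0.82, 0.80, 0.80)),
      tpr_mom = gestational_curve(c(0, 12, 20, 32, 40),
                                  c(1.10, 1.24, 1.42, 1.70, 1.70)),
      uapi_mom = gestational_curve(c(0, 12, 20, 32, 40),
                                   c(1.12, 1.40, 1.70, 2.00, 2.00)),
      ua_flow_mom = gestational_curve(c(0, 12, 20, 32, 40),
                                      c(1.0, 0.80, 0.60, 0.47, 0.45)),
      lambda_z_scale = 0.5, stiffness = 0.88),
    late_pe = list(
      co_mom = gestational_curve(c(0, 12, 20, 40), c(1.00, 1.07, 1.05, 1.05)),
      tpr_mom = gestational_curve(c(0, 12, 32, 36, 40),
                                  c(1.00, 0.981, 1.00, 1.14, 1.18)),
      uapi_mom = gestational_curve(c(0, 12, 20, 32, 40),
                                   c(1.12, 1.10, 1.12, 1.18, 1.22)),
      ua_flow_mom = gestational_curve(c(0, 12, 32, 40),
                                      c(1.0, 0.97, 0.87, 0.85)),
      lambda_z_scale = 1, stiffness = 0.88))
  if (!is.null(stiffness_multiplier)) sc$stiffness <- stiffness_multiplier
  structure(c(list(name = name), sc), class = "scenario_spec")
}

#' Calibration targets at one gestational age
#'
#' Evaluates the scenario's multiplier curves against the normal baseline:
#' cardiac output and heart rate (prescribed inputs), the mean and systolic
#' pressure targets, regional flow fractions, the bilateral uterine flow
#' target, the uterine artery pulsatility index target, the uterine axial
#' growth stretch, and the stiffness multiplier.
#'
#' @param s gestational age, weeks (0--40).
#' @param scenario a [scenario_spec()].
#' @param baseline a [pregnancy_baseline()].
#' @param tolerance relative calibration tolerance (default 2 percent).
#' @return list of class `target_set`.
#' @export
targets_for <- function(s, scenario = scenario_spec("normal"),
                        baseline = pregnancy_baseline(), tolerance = 0.02) {
  if (s < 0 || s > 40) stop("domain error: gestational age outside [0, 40] weeks")
  co_n <- baseline$CO(s)
  co <- co_n * scenario$co_mom(s)
  map <- baseline$MAP(s) * scenario$tpr_mom(s) * scenario$co_mom(s)
  uf_n <- co_n * baseline$uterine_fraction(s) * 1000 / 60 # mL/s bilateral
  lz <- 1 + (baseline$lambda_z(s) - 1) * scenario$lambda_z_scale
  structure(list(
    s = s, scenario = scenario$name,
    CO = co, HR = baseline$HR(s),
    MAP = map, SBP = map * baseline$pp_factor,
    UA_PI = baseline$UA_PI(s) * scenario$uapi_mom(s),
    uterine_flow = uf_n * scenario$ua_flow_mom(s),
    fractions = baseline$fractions,
    tau_uterine_mom = baseline$tau_uterine_mom(s),
    lambda_z = lz, stiffness = scenario$stiffness,
    tolerance = tolerance), class = "target_set")
}

#' Uterine growth stretches at a gestational age
#'
#' The circumferential stretch is the ratio of the segment's current
#' reference diameter to its nongravid value (set by the shear-driven
#' growth of the calibration loop); the axial stretch follows the
#' prescribed gestational curve. Non-uterine segments keep unit axial
#' stretch (all segment lengths are fixed).
#'
#' @param net a `vessel_network` whose segments carry `diameter0_cm`.
#' @param segment_id segment to evaluate.
#' @param targets a [targets_for()] target set (supplies `lambda_z`).
#' @return a [growth_stretches()] object.
#' @export
uterine_growth <- function(net, segment_id, targets) {
  srow <- net$segments[net$segments$id == segment_id, ]
  if (nrow(srow) != 1) stop("unknown segment '", segment_id, "'")
  uterine_circuit <- srow$region %in% c("uterine", "arcuate", "radial_ut")
  growth_stretches(
    lambda_theta = srow$diameter_cm / srow$diameter0_cm,
    lambda_z = if (uterine_circuit) targets$lambda_z else 1,
    s = targets$s)
}
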