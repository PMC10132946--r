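# Vessel wall mechanics: reference distensibility, strain-stiffening
# distensibility, the integrated area--pressure law and its inverse, and the
# sigmoidal remodeling law for gestational changes in reference
# distensibility of growing (uterine-circuit) vessels.

#' Wall-law parameters
#'
#' Parameters of the pressure-dependent distensibility law and of the
#' empirical wave-speed relation that sets the reference distensibility of
#' each vessel from its diameter.
#'
#' The distensibility at pressure `P` (kPa) is
#' \deqn{D_P = \left[a_1 + \frac{b_1}{1 + ((P - P_{maxC})/P_{width})^2}\right] D_{ref},}
#' peaking at `PmaxC` and decaying to `a1 * Dref` far from it: the
#' strain-stiffening response of arteries. The reference distensibility at
#' `Pref` follows from an empirical pulse-wave-speed law
#' \eqn{c = a_2 / \bar d^{\,b_2}} via the Bramwell–Hill relation
#' \eqn{D_{ref} = 1/(\rho c^2)}.
#'
#' @param a1,b1 dimensionless shape parameters of the distensibility bell.
#' @param PmaxC pressure of maximal distensibility, kPa.
#' @param Pwidth width of the distensibility bell, kPa.
#' @param Pref reference pressure, mmHg; areas and `Dref` are defined there.
#' @param a2 wave-speed coefficient, m/s, for diameters in cm.
#' @param b2 wave-speed diameter exponent (dimensionless). Defaults give a
#'   nongravid ascending-aorta (2.5 cm) speed of about 5 m/s and a radial
#'   artery (0.35 cm) speed of about 9 m/s.
#' @return A list of class `wall_law_params`.
#' @export
wall_law_params <- function(a1 = 0.4, b1 = 5, PmaxC = 2.67, Pwidth = 4.0,
                            Pref = 100, a2 = 6.58, b2 = 0.30) {
  stopifnot(a1 > 0, b1 > 0, Pwidth > 0, a2 > 0)
  structure(list(a1 = a1, b1 = b1, PmaxC = PmaxC, Pwidth = Pwidth,
                 Pref = Pref, a2 = a2, b2 = b2),
            class = "wall_law_params")
}

#' Reference distensibility from vessel diameter
#'
#' Evaluates the empirical wave-speed law `c = a2 / d^b2` and converts it to
#' a distensibility through the Bramwell–Hill relation `Dref = 1/(rho c^2)`.
#'
#' @param d_bar reference diameter at `Pref`, cm.
#' @param rho blood density, kg/m^3.
#' @param params a [wall_law_params()] object.
#' @return Reference distensibility, 1/kPa.
#' @export
reference_distensibility <- function(d_bar, rho = 1050,
                                     params = wall_law_params()) {
  if (any(d_bar <= 0)) stop("diameter must be positive")
  c_ms <- params$a2 / d_bar^params$b2
  1 / (rho * c_ms^2) * 1000 # 1/Pa -> 1/kPa
}

#' Distensibility at a given pressure
#'
#' @param P pressure, kPa.
#' @param Dref reference distensibility, 1/kPa.
#' @param params a [wall_law_params()] object.
#' @return Distensibility at `P`, 1/kPa.
#' @export
distensibility_at_pressure <- function(P, Dref, params = wall_law_params()) {
  stopifnot(all(Dref > 0))
  x <- (P - params$PmaxC) / params$Pwidth
  (params$a1 + params$b1 / (1 + x^2)) * Dref
}

#' Lumen area as a function of pressure
#'
#' The exact integral of `dA/dP = D_P(P) A` with `A(Pref) = Aref`, giving a
#' strictly increasing area--pressure law.
#'
#' @param P pressure, kPa.
#' @param Aref reference area at `Pref`, cm^2.
#' @param Dref reference distensibility, 1/kPa.
#' @param params a [wall_law_params()] object.
#' @return Lumen area, cm^2.
#' @export
area_from_pressure <- function(P, Aref, Dref, params = wall_law_params()) {
  stopifnot(all(Aref > 0))
  Pref <- mmhg_to_kpa(params$Pref)
  at1 <- atan((P - params$PmaxC) / params$Pwidth)
  at0 <- atan((Pref - params$PmaxC) / params$Pwidth)
  Aref * exp(params$a1 * Dref * (P - Pref) +
             params$b1 * Dref * params$Pwidth * (at1 - at0))
}

#' Pressure from lumen area (inverse tube law)
#'
#' Inverts [area_from_pressure()] by safeguarded Newton iteration on the
#' monotone law (bisection fallback keeps the iterate bracketed).
#'
#' @param A lumen area, cm^2.
#' @inheritParams area_from_pressure
#' @param tol relative tolerance on the recovered area.
#' @param maxit iteration cap.
#' @return Pressure, kPa.
#' @export
pressure_from_area <- function(A, Aref, Dref, params = wall_law_params(),
                               tol = 1e-12, maxit = 100) {
  stopifnot(all(A > 0))
  vapply(A, function(a) {
    Pref <- mmhg_to_kpa(params$Pref)
    # bracket
    lo <- Pref; hi <- Pref
    while (area_from_pressure(lo, Aref, Dref, params) > a) lo <- lo - 10
    while (area_from_pressure(hi, Aref, Dref, params) < a) hi <- hi + 10
    p <- Pref
    for (i in seq_len(maxit)) {
      f <- area_from_pressure(p, Aref, Dref, params)
      dfdp <- distensibility_at_pressure(p, Dref, params) * f
      step <- (f - a) / dfdp
      p_new <- p - step
      if (p_new < lo || p_new > hi) p_new <- (lo + hi) / 2
      if (area_from_pressure(p_new, Aref, Dref, params) > a) hi <- p_new else lo <- p_new
      if (abs(area_from_pressure(p_new, Aref, Dref, params) - a) <= tol * a) {
        return(p_new)
      }
      p <- p_new
    }
    stop("pressure_from_area failed to converge (A = ", a,
         ", last P = ", p, " kPa)")
  }, numeric(1))
}

#' Remodeling parameters for gestational distensibility changes
#'
#' @param kr1,kr2,kr3 sigmoid parameters: slope, inflection growth, and
#'   asymptotic fractional change. The default negative `kr3` makes growing
#'   uterine vessels stiffen (lower `Dref`) as the combined growth stretch
#'   increases.
#' @return A list of class `remodeling_params`, including the normalization
#'   `Ro`, the value of the sigmoid bracket at unit combined stretch.
#' @export
remodeling_params <- function(kr1 = 2.2, kr2 = 1.7, kr3 = -0.85) {
  Ro <- 1 + kr3 / (1 + exp(-kr1 * (1 - kr2)))
  if (Ro == 0) stop("degenerate remodeling parameters: Ro = 0")
  structure(list(kr1 = kr1, kr2 = kr2, kr3 = kr3, Ro = Ro),
            class = "remodeling_params")
}

#' Growth stretches of a gravid vessel
#'
#' @param lambda_theta fractional diameter increase `d(s)/d(0)`.
#' @param lambda_z fractional length increase `l(s)/l(0)`.
#' @param s gestational age, weeks.
#' @return A list of class `growth_stretches`.
#' @export
growth_stretches <- function(lambda_theta = 1, lambda_z = 1, s = 0) {
  stopifnot(lambda_theta >= 0, lambda_z >= 0)
  structure(list(lambda_theta = lambda_theta, lambda_z = lambda_z, s = s),
            class = "growth_stretches")
}

#' Remodel the reference distensibility of a growing vessel
#'
#' Sigmoidal map from the combined growth stretch
#' `x = lambda_theta * lambda_z` to the gravid reference distensibility:
#' \deqn{D_{ref}(s) = \frac{D_{ref,0}}{R_o}\left[1 +
#'   \frac{k_{r3}}{1 + e^{-k_{r1}(x - k_{r2})}}\right],}
#' normalized so that `x = 1` returns the nongravid value exactly.
#'
#' @param Dref0 nongravid reference distensibility, 1/kPa.
#' @param g a [growth_stretches()] object.
#' @param rp a [remodeling_params()] object.
#' @return Gravid reference distensibility, 1/kPa.
#' @export
remodel_reference_distensibility <- function(Dref0, g, rp = remodeling_params()) {
  stopifnot(all(Dref0 > 0))
  x <- g$lambda_theta * g$lambda_z
  Dref0 / rp$Ro * (1 + rp$kr3 / (1 + exp(-rp$kr1 * (x - rp$kr2))))
}
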