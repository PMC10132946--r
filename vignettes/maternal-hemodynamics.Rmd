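---
title: "Modeling maternal hemodynamics across gestation with gravipulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling maternal hemodynamics across gestation with gravipulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gravipulse simulates pulsatile blood flow in a reduced model of the maternal
arterial tree and lets that tree grow and remodel across gestation, so that
normal pregnancy can be compared with early and late forms of preeclampsia
through the hemodynamic quantities obstetricians actually measure: cardiac
output (CO), mean arterial pressure (MAP), total peripheral resistance
(TPR = MAP/CO), the uterine artery pulsatility index (UA-PI), uterine blood
flow, carotid–femoral pulse wave velocity (cf-PWV) and the augmentation
index (AIx75). This vignette explains the model, its assumptions, the
numerical scheme, and the design decisions taken where the problem was
genuinely open.

## The flow model

Each arterial segment is a tapered elastic tube carrying one-dimensional
pulsatile flow. With lumen area $A(z,t)$, pressure $P(z,t)$ and volumetric
flow $Q(z,t)$, mass and momentum balance read

$$C_A \frac{\partial P}{\partial t} + \frac{\partial Q}{\partial z} = 0,
\qquad
\frac{\partial Q}{\partial t}
 + \frac{\partial}{\partial z}\!\left(\frac{Q^2}{A}\right)
 + \frac{A}{\rho}\frac{\partial P}{\partial z} = \frac{f}{\rho},$$

where $C_A = D_P\,A$ is the area compliance and the friction per unit
length follows from an imposed power-law velocity profile with shape
constant $\zeta$:

$$f = -2(\zeta + 2)\,\pi\mu\,\frac{Q}{A}.$$

$\zeta = 2$ recovers Poiseuille friction $-8\pi\mu Q/A$; the package
default is $\zeta = 9$, the blunt profile typical of large arteries
(configurable — the value is not identifiable from the targets we
calibrate against). Blood is Newtonian with $\mu = 4$ mPa·s and
$\rho = 1050$ kg/m³; at these vessel calibers diameter-dependent viscosity
effects are negligible and are not modeled.

At a junction the model imposes conservation of flow,
$\sum_i Q_i = 0$, and continuity of total (static plus dynamic) pressure,
$P_i + \tfrac{\rho}{2}\bar u_i^2$ equal across all branches, neglecting
minor losses.

### Wall mechanics

The wall law has three ingredients:

1. **Reference distensibility.** At the reference pressure
   $P_\mathrm{ref} = 100$ mmHg, a vessel of diameter $\bar d$ (cm) has a
   pulse-wave speed from the empirical power law $c = a_2/\bar d^{\,b_2}$,
   which the Bramwell–Hill relation converts to
   $D_\mathrm{ref} = 1/(\rho c^2)$. The coefficients are configuration,
   not constants: the defaults $a_2 = 6.58$, $b_2 = 0.30$ were chosen once
   so that a 2.5 cm ascending aorta propagates at about 5 m/s and a
   0.35 cm radial artery at about 9 m/s, the usual clinical bracket.

2. **Strain stiffening.** The distensibility at pressure $P$ (kPa) is
   $$D_P = \left[a_1 + \frac{b_1}{1 + \left((P - P_{maxC})/P_{width}\right)^2}
   \right] D_\mathrm{ref},$$
   with $a_1 = 0.4$, $b_1 = 5$, $P_{maxC} = 2.67$ kPa,
   $P_{width} = 4$ kPa: a bell centered below physiologic pressure, so the
   wall stiffens as pressure rises. Integrating $dA/dP = D_P A$ exactly
   gives the area–pressure law used by the solver
   (`area_from_pressure()`), a strictly monotone exponential-arctangent
   form anchored at $A(P_\mathrm{ref}) = A_\mathrm{ref}$.

3. **Gestational remodeling.** Uterine-circuit vessels that grow during
   pregnancy change material properties. With circumferential and axial
   growth stretches $\lambda_\theta = d(s)/d(0)$ and
   $\lambda_z = \ell(s)/\ell(0)$, the gravid reference distensibility is a
   sigmoid in the combined stretch $x = \lambda_\theta \lambda_z$:
   $$D_\mathrm{ref}(s) = \frac{D_\mathrm{ref,0}}{R_o}
   \left[1 + \frac{k_{r3}}{1 + e^{-k_{r1}(x - k_{r2})}}\right],$$
   normalized by $R_o$, the bracket at $x = 1$, so the nongravid state is
   a fixed point. Defaults $k_{r1} = 2.2$, $k_{r2} = 1.7$,
   $k_{r3} = -0.85$: a strongly grown vessel asymptotically keeps about
   18% of its nongravid distensibility per unit reference area. The
   nongravid tree ($s = 0$) always uses the wave-speed law directly;
   remodeling only applies to the gravid uterine circuit. Segment lengths
   are fixed; $\lambda_z$ follows a prescribed gestational curve.

### Boundary conditions

The inlet (ascending aorta) carries a prescribed flow waveform
$Q(t) = \mathrm{CO}\cdot t_c \cdot q(t)$ with unit-integral shape $q(t)$:
a systolic half-sine over a configurable ejection fraction of the cycle
(default 37%), a small dicrotic dip (2% of stroke volume), and zero
diastolic flow. The published waveform this stands in for is not
tabulated anywhere we can reproduce; all calibrated targets are means and
ratios that are insensitive to the fine shape.

Every terminal segment ends in a three-element Windkessel: proximal
resistance $R_1$, compliance $C$, distal resistance $R_2$, total
$R_T = R_1 + R_2$, outflow pressure $P_\mathrm{out} = 0$ (venous pressure
neglected, consistent with computing TPR without a venous term). $R_1$ is
set to the characteristic (water-hammer) impedance of the feeding segment,
$Z_c = \sqrt{\rho/(A_\mathrm{ref}^2 D_\mathrm{ref})}$, clamped to between
5% and 40% of $R_T$; compliances are carried through the terminal time
constant $aRTC = R_T C$.

## The reduced arterial tree

`generate_reduced_tree()` builds a 31-segment stand-in for the full
anatomical network: an aortic trunk with carotid→cerebral,
subclavian→radial-arm, visceral, renal, and bilateral iliac→femoral
branches, plus the uterine circuit on each side — internal iliac → uterine
artery → arcuate arteries → radial arteries, the radials carrying the WK3
terminals of the uteroplacental bed (a configurable subset "placentally
engaged"). Nongravid baselines: CO 5 L/min, HR 70 bpm, MAP 85 mmHg,
bilateral uterine flow 1% of CO, regional fractions 12% cerebral, 20%
limb, 20% renal, remainder visceral trunk. The axial grid step is 0.5 cm
(half the segment length for segments shorter than 0.75 cm, so every
segment has at least two elements).

The tree's geometry and the absolute target curves below were designed
*jointly*: a reduced tree has far less distributed compliance and far
fewer uteroplacental vessels than the real bed, which bounds from below
the uterine pulsatility it can produce (about 3.4 nongravid and 0.79 at
term on the default tree) and narrows the attainable aortic pulse
pressure under the $R_1 = Z_c$ clamp (SBP/MAP roughly 1.31–1.47). The
nongravid uterine diameter (0.26 cm) and the UA-PI and SBP anchor values
were therefore chosen, once, inside both the clinical ranges and the
tree's attainable band. What passing tests show is that the *calibration
loop* reproduces prescribed trajectories and their between-scenario
ratios on this tree — not that the reduced tree is an anatomical model of
any particular patient.

## Gestational scenarios

`pregnancy_baseline()` holds the normal-pregnancy curves as anchor points
with monotone piecewise-cubic interpolation (Fritsch–Butland slopes: the
interpolant is exact at anchors and never overshoots between them):

* CO rising 30% from 5.0 L/min at conception to 6.5 L/min at term;
  HR 70 → 85 bpm;
* MAP dipping ~5% mid-gestation and recovering to 85 mmHg at term;
  SBP target = 1.38 × MAP (the pulse-pressure factor, chosen mid-range of
  what the tree attains);
* bilateral uterine flow fraction 1% → 10% of CO (a >8-fold flow rise);
* UA-PI falling from 3.6 (nongravid) through 2.1 (12 weeks) to 0.80 at
  term;
* uterine axial growth stretch $\lambda_z$ 1 → 1.6.

`scenario_spec()` expresses the two preeclampsia phenotypes as
multiples-of-the-mean (MoM) multiplier curves on this baseline:

* **early_pe** — CO 0.97 at conception, 0.82 at 12 weeks, 0.80 beyond 20;
  TPR 1.10 / 1.24 / 1.70-fold at 0 / 12 / 32 weeks; UA-PI 1.40-fold at 12
  weeks rising to 2.00-fold in the third trimester; uterine flow falling
  to 0.47 MoM; halved uterine axial growth; systemic distensibility
  scaled by 0.88.
* **late_pe** — CO 1.07-fold at 12 weeks, 1.05 beyond 20; TPR near normal
  until 32 weeks then 1.14-fold at 36; UA-PI 1.10-fold at 12 weeks,
  within 1.1–1.2 through 32 weeks; systemic distensibility scaled by
  0.88.

The MAP target is *constructed* as MAP$_\mathrm{normal}$ × TPR-MoM ×
CO-MoM, so the resistance trajectory is honored exactly whenever MAP and
CO are on target (the published narrative values for MAP and TPR at 12
weeks are mutually inconsistent by a few percent; the TPR and CO anchors
are primary here). The preexisting-stiffness multiplier acts on the
systemic (non-uterine) vessels only: it represents the elevated
large-artery stiffness that cf-PWV and AIx75 probe, and the uterine
circuit carries its own remodeling law. Both preeclampsia scenarios also
start pregnancy with a mildly (12%) elevated UA-PI target, the
pulsatility a stiffer systemic tree transmits into the uterine circuit.

## The calibration loop

At each gestational age, `calibrate()` tunes the network in three staged
steps, iterated until every target is within a 2% relative tolerance
simultaneously:

1. **Resistances** (`step1_tune_resistances`): terminal $R_T$ values are
   scaled per regional group (cerebral, limb, renal, visceral trunk,
   uterine) by a damped multiplicative update on the flow mismatch, then
   rescaled together so the DC circuit prediction matches the MAP target
   (with the inlet flow prescribed, relative resistances set the flow
   split and the overall scale sets MAP). $R_1$ is re-derived from $Z_c$
   with the 5–40% clamp after every update.
2. **Diameters** (`step2_tune_diameters`): every segment grows or shrinks
   toward its mean wall-shear target by the cube-root rule implied by
   $\bar\tau_w = 32\mu\bar Q/(\pi d^3)$, with the wall law refreshed and a
   step-1 update interleaved in every pass. The nongravid shear targets
   are bootstrapped from the tree's own calibrated nongravid flow field
   (`calibrate_nongravid()`), with the arcuate and radial targets coupled
   to the uterine-artery value by factors 1.05 and 1.10. Uterine shear
   targets keep their nongravid value across gestation, so uterine growth
   is purely flow-driven.
3. **Compliances** (`step3_tune_compliances`): two scalar controls are
   searched in log space with a bracketing secant — the global terminal
   time constant against the SBP target, and the time constant of the
   placentally engaged radial arteries against the UA-PI target
   (nongravid: all radials; non-engaged radials stay at their nongravid
   value). The search is sign-agnostic: on this tree UA-PI *rises* with
   radial compliance, because $R_1 = Z_c$ screens the terminal capacitor
   at pulse frequencies and a compliant bed admits larger flow
   oscillation at the probe — the opposite of the isolated-Windkessel
   intuition, which we verify separately (terminal pulse pressure falls
   monotonically with C on a single tube).

A gestational sweep (`calibrate_sweep()`) runs ages in order, each
calibration warm-starting from the previous age's tuned network and
periodic solver state — the growth-and-remodeling trajectory. The
circumferential growth stretch of each uterine vessel is its calibrated
diameter over the nongravid reference diameter.

## Numerical scheme

The solver (`run_simulation()`, compiled core) integrates the equations
with backward Euler in time on a staggered grid (pressures at nodes,
flows at faces), `nt = 500` steps per cardiac cycle,
`dt = 60/(HR·nt)` s. Each time step is solved implicitly: the nonlinear
coefficients (area, compliance, convective flux, friction denominator,
junction dynamic-pressure offsets) are converged by Picard iteration with
adaptive under-relaxation; within each pass the interior of every segment
is condensed by three tridiagonal solves to an affine relation between
its two boundary pressures and boundary flows, and a small dense system
over the boundary nodes (inlet, junctions, terminals) closes the network
exactly — junction flow balance and the WK3 recurrences are equations of
that system, so mass is conserved to solver precision at every node and
junction. The iteration tolerance is $10^{-8}$ relative (about
$10^{-4}$ Pa); an iterate stalled within two orders of that at its
round-off floor is accepted. The initial state is a uniform pressure at
the Windkessel-predicted mean with zero flow and DC-divided chamber
pressures, which removes most of the start-up transient; runs report the
10th cycle, by which the cycle-to-cycle periodicity metric (worst-case
relative L∞ change of any nodal pressure waveform) is below $10^{-3}$.
Degenerate inputs are guarded: areas are positive by construction of the
tube law, non-finite pressures abort with the step index, and a cycle
count can be raised when a configuration with very long time constants
settles slowly.

Problem sizes used by the shipped tests: the default 31-segment tree
(≈ 515 grid nodes) at nt = 500 for end-to-end checks, a compact 23-segment
variant at nt = 250 with warm-started 4–5 cycle tuning runs for
calibration unit tests, and single tubes or one bifurcation for the
solver's analytic limits.

## Known limitations

* The reduced tree under-represents distributed arterial compliance and
  the uteroplacental microcirculation; absolute pulse pressures, PI floors
  and augmentation magnitudes inherit that, and only prescribed targets
  and between-scenario ratios should be interpreted.
* The simulated aortic waveform has a dominant incident peak, so the
  augmentation index is typically mildly negative (young-type, as
  commonly reported in pregnancy). The detector takes `P1` at the first
  systolic peak and `P2` as the late-systolic maximum — a definition
  chosen for stability across scenarios after inflection-based shoulder
  detection proved to flip sign between ages on these waveforms; a
  waveform whose pressure decays to near-diastolic right after its peak
  is flagged undefined. AIx magnitudes are therefore detector-specific;
  between-scenario *differences* in AIx75 remain meaningful.
* Scenario trajectories are prescribed, not emergent: the package
  reproduces and dissects phenotypes, it does not predict onset.
* The wave-speed coefficients $a_2, b_2$, the profile constant $\zeta$,
  the inlet shape, and the SBP pulse-pressure factor are configuration
  with defaults stated above; none are identified by the calibration
  targets.

## Reproducing the study

```r
library(gravipulse)
report <- run_study(run_config(ages = c(0, 12, 20, 32, 36, 40), seed = 1))
subset(report$mom_table, metric %in% c("CO", "TPR", "UA_PI"))
```

`scripts/acceptance.R` in the source repository runs the same pipeline at
the comparison ages and writes the headline MoM ratios as JSON.
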