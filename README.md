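# gravipulse

A 1D fluid–solid–growth–remodeling (FSGR) simulator of the maternal
arterial circulation across pregnancy, for researchers in computational
physiology and maternal–fetal medicine who want a mechanistic testbed for
the hemodynamics of normal pregnancy and of early and late preeclampsia.

Pregnancy remodels the maternal circulation profoundly: cardiac output
rises by a third, uterine blood flow increases more than eight-fold, and
the uterine artery Doppler pulsatility index (UA-PI) falls several-fold —
and the two clinical phenotypes of preeclampsia distort these
trajectories in characteristically different ways. gravipulse simulates
these trajectories on a reduced branching arterial tree and reports them
as the ratios (multiples of the mean, MoM) clinicians use to compare a
complicated pregnancy against normal.

## The model

* **Pulse-wave propagation.** Each vessel is a tapered elastic tube
  carrying 1D pulsatile flow: `C_A ∂P/∂t + ∂Q/∂z = 0` and
  `∂Q/∂t + ∂(Q²/A)/∂z + (A/ρ) ∂P/∂z = f/ρ`, with power-law-profile
  friction `f = −2(ζ+2)πμQ/A`. Junctions impose flow conservation and
  total-pressure continuity; each terminal carries a three-element
  Windkessel (R1, C, R2) with `R1` set to the feeding segment's
  characteristic impedance clamped to 5–40% of the total resistance. An
  implicit (backward-Euler) finite-difference scheme with 500 steps per
  cardiac cycle integrates ten cycles and reports the last.
* **Strain-stiffening wall.** The distensibility at pressure `P` is
  `D_P = [a1 + b1/(1 + ((P−PmaxC)/Pwidth)²)] D_ref`, integrated exactly
  into a monotone area–pressure law; `D_ref` follows from an empirical
  diameter–wave-speed power law via Bramwell–Hill.
* **Growth and remodeling.** Every vessel grows radially to restore its
  mean wall shear stress `τ̄ = 32μQ̄/(πd³)` to target; gravid uterine
  vessels additionally remodel their reference distensibility through a
  sigmoid in the combined growth stretch λθ·λz, anchored at the
  nongravid state.
* **Staged calibration.** At each gestational age a three-step loop tunes
  terminal resistances to MAP and regional flows, vessel diameters to
  wall-shear targets, and terminal compliances to systolic pressure and
  UA-PI, to within 2%.

## Worked example

```r
library(gravipulse)

net <- generate_reduced_tree(seed = 1)          # 31-segment synthetic tree
ref <- calibrate_nongravid(net)                 # nongravid reference state
ref
#> <calibration_result> normal at 0 weeks; converged (max residual 0.00968 )
#>   MAP 85.0 mmHg (target 85.0), SBP 117.3, UA-PI 3.57 (target 3.60)

cal <- calibrate(ref$network, scenario_spec("early_pe"), s = 12,
                 state = ref$state)
cal
#> <calibration_result> early_pe at 12 weeks; converged (max residual 0.016 )
#>   MAP 83.9 mmHg (target 83.8), SBP 116.1, UA-PI 2.89 (target 2.94)
```

The nongravid tree settles at its 85 mmHg mean pressure with a
nonpregnant-range uterine pulsatility index near 3.6. At 12 weeks of an
early-preeclampsia pregnancy the calibrated tree carries 18% less cardiac
output at a slightly higher mean pressure (TPR 1.24-fold normal) and a
UA-PI 1.4-fold the normal 12-week value — the first-trimester Doppler
signature of impaired uteroplacental remodeling.

A full study across scenarios and gestational ages:

```r
report <- run_study(run_config(ages = c(0, 12, 20, 32, 36, 40), seed = 1))
subset(report$mom_table, scenario == "early_pe" & metric == "TPR")
```

`report$mom_table` holds CO, MAP, TPR, UA-PI, uterine flow, cf-PWV and
AIx75 for every scenario and age, with their MoM against the normal
scenario. A thin command-line front end is included at
`inst/cli/gravipulse.R` (verbs `make-network`, `scenario`, `calibrate`,
`run-study`).

## Scope

The tree is an explicit reduced stand-in, not patient anatomy: absolute
pulse pressures and augmentation magnitudes inherit its compressed
compliance, and only prescribed targets and between-scenario ratios
should be interpreted. Scenario trajectories are prescribed inputs — the
package dissects phenotypes, it does not predict who develops them. See
the methods vignette (`vignettes/maternal-hemodynamics.Rmd`) for the
model, parameter defaults, numerical choices, and limitations.
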