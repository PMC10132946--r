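# Calibration-loop behavior on the compact uterine-bearing tree. These
# tests run short simulations (nt = 250, warm-started cycles) to keep the
# suite fast; the tolerances they assert are the loop's own 2% target
# tolerance.

ctrl <- fast_control()

ref_cache <- new.env()
nongravid_ref <- function() {
  if (is.null(ref_cache$ref)) {
    ref_cache$ref <- calibrate_nongravid(small_tree(), control = ctrl)
  }
  ref_cache$ref
}

test_that("step 1 recovers MAP and regional flows from perturbed starts", {
  targets <- targets_for(0)
  inlet <- build_inlet(targets$CO, targets$HR, nt = ctrl$nt)
  for (seed in 1:3) {
    net <- small_tree()
    set.seed(seed)
    RT <- (net$terminals$R1 + net$terminals$R2) *
      stats::runif(nrow(net$terminals), 0.5, 2)
    net <- refresh_terminals(net, stats::setNames(RT, net$terminals$segment_id))
    out <- step1_tune_resistances(net, targets, inlet, ctrl)
    expect_true(max(out$residuals) <= ctrl$tol)
    expect_equal(out$meas$MAP, targets$MAP, tolerance = ctrl$tol)
    expect_equal(out$meas$uterine_flow, targets$uterine_flow,
                 tolerance = ctrl$tol)
  }
})

test_that("step 1 is a fixed point when targets are already met", {
  ref <- nongravid_ref()
  targets <- targets_for(0)
  inlet <- build_inlet(targets$CO, targets$HR, nt = ctrl$nt)
  out <- step1_tune_resistances(ref$network, targets, inlet, ctrl,
                                state = ref$state)
  expect_identical(out$iterations, 0L)
  expect_identical(out$net$terminals$R1, ref$network$terminals$R1)
})

test_that("step 2 leaves diameters at their shear fixed point and obeys the
           cube-root growth rule", {
  ref <- nongravid_ref()
  targets <- targets_for(0)
  inlet <- build_inlet(targets$CO, targets$HR, nt = ctrl$nt)
  out <- step2_tune_diameters(ref$network, targets, inlet, ctrl, ref$state)
  expect_equal(out$net$segments$diameter_cm, ref$network$segments$diameter_cm,
               tolerance = 0.02)
  # halving every shear target grows every diameter by ~2^(1/3)
  net2 <- out$net
  net2$segments$tau_target_Pa <- net2$segments$tau_target_Pa / 2
  out2 <- step2_tune_diameters(net2, targets, inlet, ctrl, out$state)
  ratio <- out2$net$segments$diameter_cm / out$net$segments$diameter_cm
  expect_equal(unname(ratio), rep(2^(1 / 3), length(ratio)), tolerance = 0.03)
  # arcuate and radial shear targets keep the 1.05x / 1.10x coupling
  seg <- out$net$segments
  tau_ut <- seg$tau_target_Pa[seg$region == "uterine"][1]
  expect_equal(seg$tau_target_Pa[seg$region == "arcuate"],
               rep(1.05 * tau_ut, sum(seg$region == "arcuate")))
  expect_equal(seg$tau_target_Pa[seg$region == "radial_ut"],
               rep(1.10 * tau_ut, sum(seg$region == "radial_ut")))
})

test_that("nongravid calibration meets every target within tolerance", {
  ref <- nongravid_ref()
  expect_true(ref$converged)
  expect_true(max(ref$residuals) <= ctrl$tol)
  expect_equal(ref$metrics$MAP, 85, tolerance = ctrl$tol)
  expect_equal(ref$metrics$SBP, ref$targets$SBP, tolerance = ctrl$tol)
  expect_equal(ref$metrics$UA_PI, ref$targets$UA_PI, tolerance = ctrl$tol)
  # frozen nongravid reference state is self-consistent
  expect_equal(ref$network$segments$diameter0_cm,
               ref$network$segments$diameter_cm)
  expect_true(all(!is.na(ref$network$segments$tau_target_Pa)))
})

test_that("recalibrating a converged state changes little and stays converged", {
  ref <- nongravid_ref()
  again <- calibrate(ref$network, scenario_spec("normal"), 0, control = ctrl,
                     state = ref$state)
  expect_true(again$converged)
  expect_equal(again$network$segments$diameter_cm,
               ref$network$segments$diameter_cm, tolerance = 0.02)
  RT1 <- again$network$terminals$R1 + again$network$terminals$R2
  RT0 <- ref$network$terminals$R1 + ref$network$terminals$R2
  expect_equal(RT1, RT0, tolerance = 0.05)
})

test_that("a gravid calibration grows the uterine circuit and meets targets", {
  ref <- nongravid_ref()
  cal <- calibrate(ref$network, scenario_spec("normal"), 20, control = ctrl,
                   state = ref$state)
  expect_true(cal$converged)
  seg <- cal$network$segments
  ut <- seg$region == "uterine"
  # shear-driven growth: diameter scales with the cube root of flow gain
  flow_gain <- cal$targets$uterine_flow / targets_for(0)$uterine_flow
  expect_equal(mean(seg$diameter_cm[ut] / seg$diameter0_cm[ut]),
               flow_gain^(1 / 3), tolerance = 0.05)
  # gravid uterine vessels are remodeled: distensibility below the
  # wave-speed-law value at the same diameter
  d_now <- seg$diameter_cm[ut][1]
  expect_lt(seg$Dref_kPa[ut][1],
            reference_distensibility(d_now, 1050, cal$network$wall))
})
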