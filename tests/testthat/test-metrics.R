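test_that("pulsatility index is Gosling's index", {
  t <- seq(0, 1, length.out = 200)[-1]
  expect_equal(pulsatility_index(rep(3, 100)), 0)
  v <- 10 * (1 + 0.5 * sin(2 * pi * t))
  expect_equal(pulsatility_index(v), 1.0, tolerance = 1e-3)
  # scale invariance
  expect_equal(pulsatility_index(4.7 * v), pulsatility_index(v))
  expect_error(pulsatility_index(v - 20), "mean velocity")
})

test_that("mean wall shear follows the Poiseuille relation", {
  expect_equal(mean_wall_shear(0, 0.5), 0)
  # 4 mPa s, 500 mL/min, 5 mm vessel: ~2.7 Pa by direct arithmetic
  expect_equal(mean_wall_shear(500 / 60, 0.5, 0.004), 2.7162, tolerance = 1e-4)
  expect_equal(mean_wall_shear(1, 0.25) / mean_wall_shear(1, 0.5), 8)
})

test_that("TPR and MoM are simple ratios", {
  expect_equal(total_peripheral_resistance(90, 5), 18)
  expect_error(total_peripheral_resistance(90, 0), "cardiac output")
  expect_equal(mom(4, 5), 0.8)
  expect_equal(mom(7.3, 7.3), 1)
  expect_error(mom(1, 0), "zero")
  # MoM(TPR) = MoM(MAP) / MoM(CO)
  expect_equal(mom(total_peripheral_resistance(99, 4),
                   total_peripheral_resistance(90, 5)),
               mom(99, 90) / mom(4, 5))
})

test_that("rmse restores the root and the square", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(5, 3), 2)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("foot-to-foot PWV recovers a constructed shift exactly", {
  nt <- 500
  dt <- 0.002
  t <- seq_len(nt) * dt
  pulse <- function(t0) {
    tt <- (t - t0) %% 1
    80 + 40 * exp(-((tt - 0.2) / 0.08)^2)
  }
  p1 <- pulse(0)
  p2 <- pulse(0.100) # 100 ms later
  expect_equal(pwv_foot_to_foot(t, p1, p2, 80, tc = 1), 8.0, tolerance = 1e-3)
  # mis-ordered sites have a negative transit time (non-cyclic pulses, so
  # the reversal cannot alias onto a wrapped positive delay)
  q1 <- 80 + 40 * exp(-((t - 0.20) / 0.08)^2)
  q2 <- 80 + 40 * exp(-((t - 0.30) / 0.08)^2)
  expect_equal(pwv_foot_to_foot(t, q1, q2, 80, tc = 1), 8.0, tolerance = 1e-3)
  expect_error(pwv_foot_to_foot(t, q2, q1, 80, tc = 1), "transit")
})

test_that("PWV on a uniform tube matches Bramwell-Hill within 10%", {
  net <- tube_network(length_cm = 60, diameter_cm = 1.2, R1 = 0.3, R2 = 2.7,
                      C = 0.4)
  inlet <- build_inlet(4, 60, nt = 400)
  res <- run_simulation(net, inlet, n_cycles = 8)
  n <- nrow(res$P)
  i1 <- round(n * 0.2); i2 <- round(n * 0.8)
  path <- (i2 - i1) * net$segments$dz_cm
  pwv <- pwv_foot_to_foot(res$t, res$P[i1, ], res$P[i2, ], path,
                          tc = inlet$tc)
  # wave speed at the working pressure from the distensibility law
  P_kPa <- mean(res$P[i1, ]) * 0.1333223874
  DP <- distensibility_at_pressure(P_kPa, net$segments$Dref_kPa, net$wall)
  c_bh <- 1 / sqrt(1050 * DP / 1000)
  expect_equal(pwv, c_bh, tolerance = 0.10)
})

test_that("augmentation index heart-rate correction and degenerate cases", {
  nt <- 500
  t <- seq_len(nt) / nt
  # composite waveform: dominant incident bump plus a delayed, weaker
  # reflected bump (young-type wave: composite peak below the incident peak,
  # so the augmentation is negative)
  p <- 75 + 35 * exp(-((t - 0.18) / 0.07)^2) + 12 * exp(-((t - 0.38) / 0.10)^2)
  a75 <- augmentation_index(t, p, HR = 75)
  a85 <- augmentation_index(t, p, HR = 85)
  expect_false(is.na(a75$AIx))
  expect_lt(a75$AIx, 0)
  expect_equal(a75$AIx75, a75$AIx)
  expect_equal(a85$AIx75 - a85$AIx, 0.39 * 10)
  expect_equal(a75$AP, a75$P2 - a75$P1)
  expect_equal(a75$PP, max(p) - min(p))
  # AIx = 20%, HR = 85 gives AIx75 = 23.9 by the correction formula
  expect_equal(0.39 * (85 - 75) + 20, 23.9)
  # a pure single-peak waveform can never show positive augmentation:
  # either undefined (no reflected energy) or a pure-decay negative value
  p1 <- 75 + 35 * exp(-((t - 0.25) / 0.09)^2)
  a1 <- augmentation_index(t, p1, HR = 75)
  expect_true(is.na(a1$AIx) || a1$AIx <= 0)
})
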