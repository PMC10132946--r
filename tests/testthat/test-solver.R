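test_that("inlet waveform has the prescribed mean flow and time step", {
  inlet <- build_inlet(5, 70, nt = 500)
  expect_equal(mean(inlet$Q), 5000 / 60, tolerance = 1e-6)
  expect_equal(sum(inlet$q) * inlet$dt, 1, tolerance = 1e-12)
  # linearity in CO
  inlet2 <- build_inlet(10, 70, nt = 500)
  expect_equal(inlet2$Q, 2 * inlet$Q)
  # dt = 60 / (HR nt)
  expect_equal(build_inlet(5, 60, nt = 500)$dt, 0.002)
  expect_equal(inlet$tc, 60 / 70)
})

test_that("friction term matches the profile-dependent closed form", {
  expect_equal(friction_term(1e-6, 1e-4, zeta = 2, mu = 0.004),
               -8 * pi * 0.004 * 1e-6 / 1e-4)
  expect_equal(friction_term(0, 1e-4), 0)
  expect_equal(friction_term(3e-6, 1e-4), 3 * friction_term(1e-6, 1e-4))
})

test_that("WK3 update has the right DC and stiff-compliance limits", {
  term <- list(R1 = 1, R2 = 9, C = 0.2, Pout = 5)
  # steady inflow: P -> Pout + RT Q
  Pc <- 5
  for (i in 1:20000) {
    up <- wk3_boundary(term, Q = 2, Pc = Pc, dt = 0.01)
    Pc <- up$Pc
  }
  expect_equal(up$P, 5 + 10 * 2, tolerance = 1e-6)
  # C -> Inf freezes the chamber pressure
  term_inf <- list(R1 = 1, R2 = 9, C = 1e12, Pout = 0)
  up2 <- wk3_boundary(term_inf, Q = 2, Pc = 42, dt = 0.01)
  expect_equal(up2$Pc, 42, tolerance = 1e-9)
})

test_that("steady rigid-tube run reproduces the Poiseuille pressure drop", {
  net <- tube_network(length_cm = 10, diameter_cm = 0.5, Dref = 1e-6,
                      zeta = 2)
  inlet <- build_inlet(0.6, 60, nt = 200, shape = "constant") # 10 mL/s
  res <- run_simulation(net, inlet, n_cycles = 20)
  A <- pi * 0.5^2 / 4 * 1e-4
  dP_an <- 8 * pi * 0.004 * 10e-6 * 0.10 / A^2 / 133.3223874 # mmHg
  dP <- mean(res$P[1, ]) - mean(res$P[nrow(res$P), ])
  expect_equal(dP, dP_an, tolerance = 0.01)
  # WK3 DC relation at the terminal
  expect_equal(mean(res$P[nrow(res$P), ]), 0 + (1 + 9) * 10,
               tolerance = 0.01)
})

test_that("zero inflow at the outflow pressure is a fixed point", {
  net <- tube_network(Pout = 100) # Pout at the reference pressure
  inlet <- build_inlet(1, 60, nt = 100, shape = "constant")
  inlet$Q <- rep(0, 100)
  packed <- gravipulse:::pack_network(net)
  Pref_pa <- 100 * 133.3223874
  st <- list(P = rep(Pref_pa, sum(packed$n_nodes)),
             Qf = numeric(sum(packed$n_nodes - 1L)),
             Qin = 0, Qout = 0,
             Pc = rep(Pref_pa, length(packed$bnd_type)))
  res <- run_simulation(net, inlet, n_cycles = 1, init_state = st)
  expect_equal(max(abs(res$P - 100)), 0, tolerance = 1e-9)
  expect_equal(max(abs(res$Q)), 0, tolerance = 1e-12)
})

test_that("junction coupling conserves mass and total pressure", {
  net <- bifurcation_network()
  inlet <- build_inlet(5, 70, nt = 300)
  res <- run_simulation(net, inlet, n_cycles = 6, picard_tol = 1e-10)
  nmap <- res$node_map
  end_a <- max(which(nmap$segment == "a"))
  start_b <- min(which(nmap$segment == "b"))
  start_c <- min(which(nmap$segment == "c"))
  # flow balance at the junction, every recorded step
  resid_q <- abs(res$Q[end_a, ] - res$Q[start_b, ] - res$Q[start_c, ])
  expect_lt(max(resid_q / max(abs(res$Q[end_a, ]))), 1e-8)
  # symmetric children split the flow equally
  expect_equal(res$Q[start_b, ], res$Q[start_c, ], tolerance = 1e-10)
  # total pressure (static + dynamic) continuity across the junction
  rho <- 1050
  ptot <- function(i) res$P[i, ] * 133.3223874 +
    0.5 * rho * (res$Q[i, ] / res$A[i, ] * 1e-2)^2
  mism <- max(abs(ptot(end_a) - ptot(start_b))) / 1000 # kPa
  expect_lt(mism, 1e-6)
  # the static-pressure gap equals the dynamic-pressure difference
  expect_gt(max(abs(res$P[end_a, ] - res$P[start_b, ])), 0)
})

test_that("simulations reach a periodic steady state that conserves volume", {
  net <- tube_network(length_cm = 20, diameter_cm = 2.0, R1 = 0.12,
                      R2 = 1.02, C = 0.5, zeta = 9)
  inlet <- build_inlet(5, 70, nt = 200)
  res10 <- run_simulation(net, inlet, n_cycles = 10)
  expect_lt(utils::tail(res10$cycle_metric, 1), 1e-3)
  expect_lt(abs(volume_balance(res10)), 0.005)
  # doubling the cycle count leaves the reported waveform unchanged
  res20 <- run_simulation(net, inlet, n_cycles = 20)
  rel <- max(abs(res10$P[1, ] - res20$P[1, ])) /
    (max(res20$P[1, ]) - min(res20$P[1, ]))
  expect_lt(rel, 1e-3)
})

test_that("default fixture network converges by the reporting cycle", {
  net <- generate_reduced_tree()
  inlet <- build_inlet(5, 70, nt = 500)
  res <- run_simulation(net, inlet, n_cycles = 10)
  expect_lt(utils::tail(res$cycle_metric, 1), 1e-3)
  expect_lt(abs(volume_balance(res)), 0.005)
  expect_true(all(res$A > 0))
})

test_that("halving the time step barely changes the waveforms", {
  net <- tube_network(length_cm = 20, diameter_cm = 2.0, R1 = 0.12,
                      R2 = 1.02, C = 1)
  res1 <- run_simulation(net, build_inlet(5, 70, nt = 500), n_cycles = 8)
  res2 <- run_simulation(net, build_inlet(5, 70, nt = 1000), n_cycles = 8)
  p1 <- res1$P[1, ]
  p2 <- res2$P[1, seq(2, 1000, by = 2)]
  rel <- max(abs(p1 - p2)) / (max(p1) - min(p1))
  expect_lt(rel, 0.005)
})

test_that("terminal pulse pressure falls monotonically with compliance", {
  inlet <- build_inlet(5, 70, nt = 250)
  pp <- vapply(c(0.05, 0.2, 0.8, 3), function(C) {
    net <- tube_network(length_cm = 20, diameter_cm = 2.0, R1 = 0.12,
                        R2 = 1.02, C = C)
    res <- run_simulation(net, inlet, n_cycles = 10)
    p <- res$P[nrow(res$P), ]
    max(p) - min(p)
  }, 0)
  expect_true(all(diff(pp) < 0))
})
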