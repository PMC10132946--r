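# Small fixtures shared across test files. All built in code at test time.

# a single straight tube with one WK3 terminal
tube_network <- function(length_cm = 10, diameter_cm = 0.5, Dref = NULL,
                         R1 = 1, R2 = 9, C = 0.1, zeta = 9, Pout = 0) {
  seg <- vessel_segment("tube", "tube", "other", length_cm = length_cm,
                        diameter_cm = diameter_cm, Dref = Dref)
  term <- data.frame(segment_id = "tube", R1 = R1, R2 = R2, C = C,
                     aRTC = (R1 + R2) * C, Pout = Pout, group = "trunk",
                     stringsAsFactors = FALSE)
  vessel_network(seg, term, "tube",
                 blood = list(rho = 1050, mu = 0.004, zeta = zeta))
}

# symmetric bifurcation: one parent, two identical children
bifurcation_network <- function() {
  segs <- rbind(
    vessel_segment("a", "parent", "aorta", 10, 2.0),
    vessel_segment("b", "child b", "iliac", 10, 1.2, parent = "a"),
    vessel_segment("c", "child c", "iliac", 10, 1.2, parent = "a"))
  term <- data.frame(segment_id = c("b", "c"), R1 = 0.2, R2 = 1.8,
                     C = 0.6, aRTC = 1.2, Pout = 0, group = "trunk",
                     stringsAsFactors = FALSE)
  vessel_network(segs, term, "a")
}

# compact uterine-bearing tree for calibration tests
small_tree <- function(seed = 1L) {
  generate_reduced_tree(
    reduced_tree_config(n_arcuate_per_uterine = 1, n_radial_per_arcuate = 2),
    seed = seed)
}

fast_control <- function(...) {
  calibration_control(nt = 250, n_cycles_inner = 4, n_cycles_final = 8, ...)
}
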