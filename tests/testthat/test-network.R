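test_that("default reduced tree is valid and deterministic", {
  net <- generate_reduced_tree(seed = 1L)
  expect_length(validate_network(net), 0)
  seg <- net$segments
  expect_equal(sum(seg$region == "uterine"), 2)
  expect_equal(sum(seg$region == "arcuate"), 4)
  expect_equal(sum(seg$region == "radial_ut"), 8)
  # radial segments are the terminal vessels of the uterine circuit
  radials <- seg$id[seg$region == "radial_ut"]
  expect_true(all(radials %in% leaf_segments(net)))
  expect_true(all(radials %in% net$terminals$segment_id))
  # every leaf has exactly one WK3 terminal
  expect_setequal(leaf_segments(net), net$terminals$segment_id)
  # determinism: byte-identical serialization for the same seed
  net2 <- generate_reduced_tree(seed = 1L)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_network(net, f1); write_network(net2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("axial discretization follows the grid rule", {
  g <- segment_grid(0.6) # short segment: dz = length/2, two elements
  expect_equal(g$dz, 0.3)
  expect_equal(g$n_nodes, 3L)
  expect_equal(segment_grid(10)$dz, 0.5)
  net <- generate_reduced_tree()
  seg <- net$segments
  expect_true(all(abs(seg$dz_cm * (seg$n_nodes - 1) - seg$length_cm) < 1e-9))
  expect_true(all(seg$n_nodes - 1 >= 2))
  expect_true(all(abs(seg$Aref_cm2 - pi * seg$diameter_cm^2 / 4) <
                    1e-10 * seg$Aref_cm2))
})

test_that("validation reports rule violations by name", {
  net <- generate_reduced_tree()
  # proximal resistance outside the 5-40% impedance window
  bad <- net
  RT <- bad$terminals$R1[1] + bad$terminals$R2[1]
  bad$terminals$R1[1] <- 0.5 * RT
  bad$terminals$R2[1] <- 0.5 * RT
  expect_match(validate_network(bad), "Zc fraction outside 5-40%",
               all = FALSE)
  # a cycle is not a tree
  bad2 <- net
  bad2$segments$parent[bad2$segments$id == "asc_aorta"] <- "thoracic"
  expect_match(validate_network(bad2), "inlet|tree", all = FALSE)
  # leaf without a terminal
  bad3 <- net
  bad3$terminals <- bad3$terminals[-1, ]
  expect_match(validate_network(bad3), "without WK3 terminal", all = FALSE)
  expect_error(reduced_tree_config(n_uterine = 0), "configuration error")
})

test_that("JSON round-trip is lossless", {
  net <- generate_reduced_tree(seed = 3L)
  f <- tempfile(fileext = ".json")
  write_network(net, f)
  back <- read_network(f)
  for (col in c("length_cm", "diameter_cm", "Aref_cm2", "Dref_kPa", "dz_cm")) {
    expect_equal(back$segments[[col]], net$segments[[col]],
                 tolerance = 1e-12, label = col)
  }
  expect_identical(back$segments$id, net$segments$id)
  expect_identical(back$segments$parent, net$segments$parent)
  for (col in c("R1", "R2", "C", "Pout")) {
    expect_equal(back$terminals[[col]], net$terminals[[col]],
                 tolerance = 1e-12, label = col)
  }
  expect_length(validate_network(back), 0)

  # parse errors name the offender
  obj <- jsonlite::fromJSON(f, simplifyDataFrame = TRUE)
  obj$segments$Dref_kPa <- NULL
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, f2, digits = NA, auto_unbox = TRUE)
  expect_error(read_network(f2), "Dref")
  obj2 <- jsonlite::fromJSON(f, simplifyDataFrame = TRUE)
  obj2$terminals$segment_id[1] <- "no_such_segment"
  f3 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj2, f3, digits = NA, auto_unbox = TRUE)
  expect_error(read_network(f3), "unknown segment")
  obj3 <- jsonlite::fromJSON(f, simplifyDataFrame = TRUE)
  obj3$segments$region[2] <- "gastric"
  f4 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj3, f4, digits = NA, auto_unbox = TRUE)
  expect_error(read_network(f4), "unknown region")
})

test_that("characteristic impedance scales as the water-hammer formula", {
  z0 <- characteristic_impedance(1, 0.02)
  expect_equal(characteristic_impedance(4, 0.02), z0 / 4) # ~ 1/Aref
  expect_equal(characteristic_impedance(1, 0.08), z0 / 2) # ~ Dref^(-1/2)
  # clamp: computed Zc above 40% of RT is capped
  net <- generate_reduced_tree()
  RT <- stats::setNames(net$terminals$R1 + net$terminals$R2,
                        net$terminals$segment_id)
  net <- refresh_terminals(net, RT)
  for (i in seq_len(nrow(net$terminals))) {
    tm <- net$terminals[i, ]
    s <- net$segments[net$segments$id == tm$segment_id, ]
    zc <- characteristic_impedance(s$Aref_cm2, s$Dref_kPa, net$blood$rho)
    rt <- tm$R1 + tm$R2
    expect_equal(tm$R1, min(max(zc, 0.05 * rt), 0.40 * rt), tolerance = 1e-12)
  }
})
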