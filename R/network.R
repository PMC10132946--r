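# The branching arterial tree: segment table, WK3 terminals, topology,
# validation, JSON/CSV I/O, and the reduced synthetic tree generator.

VALID_REGIONS <- c("cerebral", "limb", "trunk", "uterine", "arcuate",
                   "radial_ut", "aorta", "carotid", "iliac", "renal", "other")

# Terminal resistance groups used by the calibration loop.
REGION_GROUP <- c(cerebral = "cerebral", limb = "limb", trunk = "trunk",
                  renal = "renal", radial_ut = "uterine")

#' Axial discretization of a segment
#'
#' The grid step is 0.5 cm; segments shorter than 0.75 cm use half their
#' length so that every segment has at least two elements. Lengths that are
#' not multiples of 0.5 cm take the nearest step that divides them evenly.
#'
#' @param length_cm segment length, cm.
#' @return list with `dz` (cm) and `n_nodes`.
#' @export
segment_grid <- function(length_cm) {
  stopifnot(length_cm > 0)
  if (length_cm < 0.75) {
    n_el <- 2L
  } else {
    n_el <- max(2L, as.integer(round(length_cm / 0.5)))
  }
  list(dz = length_cm / n_el, n_nodes = n_el + 1L)
}

#' Construct a vessel segment record
#'
#' @param id,name identifier and label.
#' @param region one of the region tags (aorta, carotid, cerebral, limb,
#'   trunk, renal, iliac, uterine, arcuate, radial_ut, other).
#' @param length_cm length, cm.
#' @param diameter_cm reference diameter at the reference pressure, cm.
#' @param diameter_distal_cm optional distal diameter for a linear taper.
#' @param Dref reference distensibility, 1/kPa; computed from the wall law
#'   when `NULL`.
#' @param parent id of the parent segment (`NA` for the inlet segment).
#' @param placental_engaged whether a radial uterine segment communicates
#'   with the placenta (step-3 compliance tuning acts on these).
#' @param params a [wall_law_params()] object.
#' @param rho blood density, kg/m^3.
#' @return one-row data.frame.
#' @export
vessel_segment <- function(id, name, region, length_cm, diameter_cm,
                           diameter_distal_cm = NA_real_, Dref = NULL,
                           parent = NA_character_, placental_engaged = FALSE,
                           params = wall_law_params(), rho = 1050) {
  stopifnot(length_cm > 0, diameter_cm > 0, region %in% VALID_REGIONS)
  if (is.null(Dref)) Dref <- reference_distensibility(diameter_cm, rho, params)
  grid <- segment_grid(length_cm)
  data.frame(id = id, name = name, region = region,
             length_cm = length_cm, diameter_cm = diameter_cm,
             diameter_distal_cm = diameter_distal_cm,
             Aref_cm2 = pi * diameter_cm^2 / 4,
             Dref_kPa = Dref, parent = parent,
             placental_engaged = placental_engaged,
             n_nodes = grid$n_nodes, dz_cm = grid$dz,
             tau_target_Pa = NA_real_,
             diameter0_cm = diameter_cm, Dref0_kPa = Dref,
             stringsAsFactors = FALSE)
}

#' Assemble a vascular network
#'
#' @param segments data.frame of segment records (rows from
#'   [vessel_segment()]); topology is encoded by the `parent` column.
#' @param terminals data.frame with columns `segment_id`, `R1`, `R2`, `C`,
#'   `Pout` (mmHg-based units: mmHg s/mL and mL/mmHg) and `aRTC` (s).
#' @param inlet_segment id of the root (ascending aorta) segment.
#' @param blood list with `rho` (kg/m^3), `mu` (Pa s), `zeta`
#'   (velocity-profile constant).
#' @param wall a [wall_law_params()] object.
#' @return object of class `vessel_network`.
#' @export
vessel_network <- function(segments, terminals, inlet_segment,
                           blood = list(rho = 1050, mu = 0.004, zeta = 9),
                           wall = wall_law_params()) {
  structure(list(segments = segments, terminals = terminals,
                 inlet_segment = inlet_segment, blood = blood, wall = wall),
            class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat("<vessel_network>", nrow(x$segments), "segments,",
      nrow(x$terminals), "WK3 terminals, inlet =", x$inlet_segment, "\n")
  tab <- table(x$segments$region)
  cat("  regions:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Children of each segment
#' @keywords internal
segment_children <- function(net) {
  split(net$segments$id, factor(net$segments$parent, levels = net$segments$id))
}

#' Junction list (parent segment, child segments)
#' @export
network_junctions <- function(net) {
  ch <- segment_children(net)
  ch <- ch[vapply(ch, length, 1L) > 0]
  lapply(names(ch), function(p) {
    list(parent_segment = p, child_segments = unname(ch[[p]]),
         N = length(ch[[p]]) + 1L)
  })
}

#' Leaf (terminal) segment ids
#' @export
leaf_segments <- function(net) {
  has_child <- net$segments$id %in% net$segments$parent
  net$segments$id[!has_child]
}

#' Validate a vascular network
#'
#' Checks the structural and numeric invariants: positive geometry, the
#' discretization rule, the area-diameter identity, tree topology (single
#' inlet, acyclic, connected), terminal coverage of all leaves, and the
#' 5--40 percent characteristic-impedance bound on the WK3 proximal
#' resistance.
#'
#' @param net a `vessel_network`.
#' @return character vector of violations (empty when valid).
#' @export
validate_network <- function(net) {
  v <- character()
  seg <- net$segments
  if (anyDuplicated(seg$id)) v <- c(v, "duplicate segment ids")
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    if (s$length_cm <= 0) v <- c(v, paste0(s$id, ": nonpositive length"))
    if (s$diameter_cm <= 0) v <- c(v, paste0(s$id, ": nonpositive diameter"))
    if (s$Dref_kPa <= 0) v <- c(v, paste0(s$id, ": nonpositive Dref"))
    if (s$n_nodes < 3) v <- c(v, paste0(s$id, ": fewer than two elements"))
    if (abs(s$dz_cm * (s$n_nodes - 1) - s$length_cm) > 1e-9)
      v <- c(v, paste0(s$id, ": dz * (n_nodes - 1) != length"))
    if (s$length_cm >= 0.75 && abs(s$dz_cm - 0.5) > 1e-9 &&
        abs(s$length_cm / round(s$length_cm / 0.5) - s$dz_cm) > 1e-9)
      v <- c(v, paste0(s$id, ": dz rule violated"))
    if (abs(s$Aref_cm2 - pi * s$diameter_cm^2 / 4) > 1e-10 * s$Aref_cm2)
      v <- c(v, paste0(s$id, ": Aref != pi d^2/4"))
    if (!s$region %in% VALID_REGIONS)
      v <- c(v, paste0(s$id, ": unknown region '", s$region, "'"))
    if (isTRUE(s$placental_engaged) && s$region != "radial_ut")
      v <- c(v, paste0(s$id, ": placental_engaged on non-radial segment"))
  }
  roots <- seg$id[is.na(seg$parent)]
  if (length(roots) != 1) {
    v <- c(v, "network must have exactly one inlet (root) segment")
  } else if (roots != net$inlet_segment) {
    v <- c(v, "inlet_segment is not the root of the tree")
  }
  bad_parent <- !is.na(seg$parent) & !(seg$parent %in% seg$id)
  if (any(bad_parent))
    v <- c(v, paste0(seg$id[bad_parent], ": parent not in network"))
  # acyclicity/connectivity by walking to the root from every segment
  if (length(roots) == 1 && !any(bad_parent)) {
    parent_of <- stats::setNames(seg$parent, seg$id)
    for (id in seg$id) {
      seen <- character(); cur <- id
      while (!is.na(cur)) {
        if (cur %in% seen) { v <- c(v, "not a tree: cycle involving segment "); break }
        seen <- c(seen, cur); cur <- parent_of[[cur]]
      }
      if (!is.na(cur)) { v <- c(v, paste0("not a tree: cycle through ", id)); break }
    }
  }
  leaves <- leaf_segments(net)
  term <- net$terminals
  if (anyDuplicated(term$segment_id)) v <- c(v, "duplicate terminal records")
  missing_t <- setdiff(leaves, term$segment_id)
  if (length(missing_t))
    v <- c(v, paste0(missing_t, ": leaf segment without WK3 terminal"))
  orphan_t <- setdiff(term$segment_id, leaves)
  if (length(orphan_t))
    v <- c(v, paste0(orphan_t, ": terminal attached to non-leaf segment"))
  for (i in seq_len(nrow(term))) {
    tm <- term[i, ]
    if (tm$R1 <= 0 || tm$R2 <= 0 || tm$C <= 0)
      v <- c(v, paste0(tm$segment_id, ": nonpositive WK3 parameter"))
    RT <- tm$R1 + tm$R2
    if (tm$R1 < 0.05 * RT - 1e-12 || tm$R1 > 0.40 * RT + 1e-12)
      v <- c(v, paste0(tm$segment_id,
                       ": Zc fraction outside 5-40% of RT"))
  }
  v
}

#' Configuration for the reduced synthetic arterial tree
#'
#' The reduced tree is a stand-in for a full anatomical arterial network:
#' an aortic trunk with carotid-to-cerebral, subclavian-to-arm, visceral,
#' renal, and bilateral iliac-to-femoral branches, plus the bilateral
#' uterine circuit (internal iliac, uterine, arcuate, radial segments, the
#' radials carrying the WK3 terminals of the uteroplacental bed).
#'
#' @param n_uterine number of uterine arteries (one per side; >= 1).
#' @param n_arcuate_per_uterine arcuate branches per uterine artery.
#' @param n_radial_per_arcuate radial branches per arcuate artery.
#' @param placental_fraction fraction of radial segments engaged with the
#'   placenta (rounded up; at least one per uterine circuit).
#' @param CO,HR,MAP nongravid baseline cardiac output (L/min), heart rate
#'   (bpm), mean arterial pressure (mmHg).
#' @param uterine_fraction nongravid bilateral uterine flow as a fraction
#'   of CO.
#' @param fractions named regional flow fractions of CO for the terminal
#'   groups `cerebral`, `limb`, `renal` (the trunk absorbs the remainder).
#' @param aRTC global terminal time constant RT*C, s.
#' @param aRTC_radial nongravid uterine-radial terminal time constant, s.
#' @param Pout Windkessel outflow pressure, mmHg (venous pressure
#'   neglected by default).
#' @param blood,wall blood properties and wall-law parameters.
#' @param jitter_sd lognormal sd applied to diameters/lengths (0 = none).
#' @return a list of class `tree_config`.
#' @export
reduced_tree_config <- function(n_uterine = 2, n_arcuate_per_uterine = 2,
                                n_radial_per_arcuate = 2,
                                placental_fraction = 0.5,
                                CO = 5.0, HR = 70, MAP = 85,
                                uterine_fraction = 0.01,
                                fractions = c(cerebral = 0.12, limb = 0.20,
                                              renal = 0.20),
                                aRTC = 1.3, aRTC_radial = 0.25,
                                Pout = 0,
                                blood = list(rho = 1050, mu = 0.004, zeta = 9),
                                wall = wall_law_params(),
                                jitter_sd = 0) {
  if (n_uterine < 1) stop("configuration error: need at least 1 uterine artery")
  if (n_arcuate_per_uterine < 1 || n_radial_per_arcuate < 1)
    stop("configuration error: invalid uterine circuit counts")
  structure(as.list(environment()), class = "tree_config")
}

#' Generate the reduced synthetic arterial tree
#'
#' Builds a valid `vessel_network` from a [reduced_tree_config()]:
#' deterministic for a fixed seed. Terminal WK3 resistances are seeded from
#' the DC balance `RT = MAP / Q_target` for each terminal's share of the
#' regional flow, `R1` is the characteristic impedance of the feeding
#' segment clamped to 5--40 percent of `RT`, and `C = aRTC / RT`.
#'
#' @param config a [reduced_tree_config()].
#' @param seed integer seed (used for the optional geometric jitter and for
#'   choosing which radial segments are placentally engaged).
#' @return a `vessel_network`.
#' @export
generate_reduced_tree <- function(config = reduced_tree_config(), seed = 1L) {
  cf <- config
  rho <- cf$blood$rho
  wall <- cf$wall
  seg_row <- function(...) vessel_segment(..., params = wall, rho = rho)

  base <- list(
    # id, name, region, length, diameter, parent
    list("asc_aorta", "ascending aorta", "aorta", 4, 2.50, NA),
    list("carotid", "common carotid", "carotid", 15, 0.70, "asc_aorta"),
    list("cerebral", "internal carotid / cerebral", "cerebral", 10, 0.40, "carotid"),
    list("subclavian", "subclavian + brachial", "limb", 10, 0.80, "asc_aorta"),
    list("radial_arm", "radial (arm)", "limb", 25, 0.35, "subclavian"),
    list("thoracic", "thoracic aorta", "aorta", 16, 2.00, "asc_aorta"),
    list("celiac", "celiac / mesenteric trunk", "trunk", 5, 0.80, "thoracic"),
    list("abdominal", "abdominal aorta", "aorta", 14, 1.60, "thoracic"),
    list("renal", "renal", "renal", 5, 0.60, "abdominal"))

  rows <- lapply(base, function(b)
    seg_row(id = b[[1]], name = b[[2]], region = b[[3]], length_cm = b[[4]],
            diameter_cm = b[[5]], parent = b[[6]]))

  sides <- if (cf$n_uterine == 1) "L" else
    c("L", "R", paste0("X", seq_len(max(0, cf$n_uterine - 2))))[seq_len(cf$n_uterine)]
  radial_ids <- character()
  for (sd_ in sides) {
    rows <- c(rows, list(
      seg_row(paste0("iliac_", sd_), paste("common iliac", sd_), "iliac",
              6, 1.00, parent = "abdominal"),
      seg_row(paste0("femoral_", sd_), paste("external iliac + femoral", sd_),
              "limb", 30, 0.70, parent = paste0("iliac_", sd_)),
      seg_row(paste0("int_iliac_", sd_), paste("internal iliac", sd_), "iliac",
              6, 0.50, parent = paste0("iliac_", sd_)),
      seg_row(paste0("pelvic_", sd_), paste("pelvic visceral", sd_), "trunk",
              5, 0.40, parent = paste0("int_iliac_", sd_)),
      seg_row(paste0("uterine_", sd_), paste("uterine", sd_), "uterine",
              10, 0.26, parent = paste0("int_iliac_", sd_))))
    for (a in seq_len(cf$n_arcuate_per_uterine)) {
      aid <- paste0("arcuate_", sd_, a)
      rows <- c(rows, list(
        seg_row(aid, paste("arcuate", sd_, a), "arcuate", 3, 0.16,
                parent = paste0("uterine_", sd_))))
      for (r in seq_len(cf$n_radial_per_arcuate)) {
        rid <- paste0("radial_", sd_, a, r)
        radial_ids <- c(radial_ids, rid)
        rows <- c(rows, list(
          seg_row(rid, paste("radial", sd_, a, r), "radial_ut", 1.5, 0.12,
                  parent = aid)))
      }
    }
  }
  segments <- do.call(rbind, rows)

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
            else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
    set.seed(seed)
    expr
  }
  withr_seed({
    if (cf$jitter_sd > 0) {
      n <- nrow(segments)
      segments$diameter_cm <- segments$diameter_cm * exp(stats::rnorm(n, 0, cf$jitter_sd))
      segments$Aref_cm2 <- pi * segments$diameter_cm^2 / 4
      segments$Dref_kPa <- reference_distensibility(segments$diameter_cm, rho, wall)
      segments$diameter0_cm <- segments$diameter_cm
      segments$Dref0_kPa <- segments$Dref_kPa
    }
    # placental engagement: a fixed-size random subset of radials, at least
    # one per uterine circuit
    n_eng <- max(cf$n_uterine, ceiling(cf$placental_fraction * length(radial_ids)))
    engaged <- sort(sample(radial_ids, n_eng))
    # guarantee one engaged radial per side
    for (sd_ in sides) {
      side_r <- radial_ids[startsWith(radial_ids, paste0("radial_", sd_))]
      if (!any(side_r %in% engaged)) engaged <- c(setdiff(engaged, engaged[1]), side_r[1])
    }
    segments$placental_engaged <- segments$id %in% engaged
  })

  net <- vessel_network(segments, terminals = empty_terminals(),
                        inlet_segment = "asc_aorta", blood = cf$blood,
                        wall = wall)
  net$terminals <- seed_terminals(net, cf)
  net$config <- cf
  bad <- validate_network(net)
  if (length(bad)) stop("generated network invalid: ", paste(bad, collapse = "; "))
  net
}

empty_terminals <- function() {
  data.frame(segment_id = character(), R1 = numeric(), R2 = numeric(),
             C = numeric(), aRTC = numeric(), Pout = numeric(),
             group = character(), stringsAsFactors = FALSE)
}

# DC seeding of the WK3 terminals from regional flow targets.
#' @keywords internal
seed_terminals <- function(net, cf) {
  leaves <- leaf_segments(net)
  seg <- net$segments
  region <- stats::setNames(seg$region, seg$id)
  group <- unname(REGION_GROUP[region[leaves]])
  CO_mls <- cf$CO * 1000 / 60
  frac <- c(cf$fractions, uterine = cf$uterine_fraction)
  frac["trunk"] <- 1 - sum(frac)
  n_in_group <- table(group)
  q_leaf <- CO_mls * frac[group] / as.numeric(n_in_group[group])
  RT <- (cf$MAP - cf$Pout) / q_leaf # mmHg s/mL
  aRTC <- ifelse(group == "uterine", cf$aRTC_radial, cf$aRTC)
  term <- data.frame(segment_id = leaves, R1 = NA_real_, R2 = NA_real_,
                     C = aRTC / RT, aRTC = aRTC, Pout = cf$Pout,
                     group = group, stringsAsFactors = FALSE)
  for (i in seq_along(leaves)) {
    s <- seg[seg$id == leaves[i], ]
    Zc <- characteristic_impedance(s$Aref_cm2, s$Dref_kPa, net$blood$rho)
    term$R1[i] <- min(max(Zc, 0.05 * RT[i]), 0.40 * RT[i])
    term$R2[i] <- RT[i] - term$R1[i]
  }
  rownames(term) <- NULL
  term
}

#' Re-derive WK3 split and compliance after changing RT or aRTC
#'
#' Applies `R1 = clamp(Zc, 5-40% RT)`, `R2 = RT - R1`, `C = aRTC / RT`.
#' @param net a `vessel_network`.
#' @param RT named vector of total terminal resistances (mmHg s/mL) keyed
#'   by segment id; defaults to the current values.
#' @return the network with updated terminals.
#' @export
refresh_terminals <- function(net, RT = NULL) {
  term <- net$terminals
  if (is.null(RT)) RT <- stats::setNames(term$R1 + term$R2, term$segment_id)
  for (i in seq_len(nrow(term))) {
    s <- net$segments[net$segments$id == term$segment_id[i], ]
    rt <- RT[[term$segment_id[i]]]
    Zc <- characteristic_impedance(s$Aref_cm2, s$Dref_kPa, net$blood$rho)
    term$R1[i] <- min(max(Zc, 0.05 * rt), 0.40 * rt)
    term$R2[i] <- rt - term$R1[i]
    term$C[i] <- term$aRTC[i] / rt
  }
  net$terminals <- term
  net
}

#' Write a network to JSON (and a CSV sidecar for inspection)
#'
#' @param net a `vessel_network`.
#' @param path output JSON path; a `.csv` flat export (one row per segment
#'   and per terminal) is written alongside when `csv = TRUE`.
#' @param csv also write the flat CSV export.
#' @export
write_network <- function(net, path, csv = FALSE) {
  obj <- list(segments = net$segments,
              junctions = network_junctions(net),
              terminals = net$terminals,
              inlet_segment = net$inlet_segment,
              blood = net$blood,
              wall = unclass(net$wall))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (csv) {
    utils::write.csv(net$segments, sub("\\.json$", "_segments.csv", path),
                     row.names = FALSE)
    utils::write.csv(net$terminals, sub("\\.json$", "_terminals.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a network from JSON
#'
#' @param path JSON file written by [write_network()].
#' @return a `vessel_network`.
#' @export
read_network <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  seg <- obj$segments
  required <- c("id", "region", "length_cm", "diameter_cm", "Dref_kPa",
                "Aref_cm2", "n_nodes", "dz_cm")
  for (f in required) {
    if (is.null(seg[[f]]) || anyNA(seg[[f]]))
      stop("parse error: segment field '", f, "' required")
  }
  if (anyDuplicated(seg$id))
    stop("parse error: duplicate segment id '",
         seg$id[duplicated(seg$id)][1], "'")
  bad_region <- setdiff(seg$region, VALID_REGIONS)
  if (length(bad_region))
    stop("parse error: unknown region tag '", bad_region[1], "'")
  term <- obj$terminals
  unknown <- setdiff(term$segment_id, seg$id)
  if (length(unknown))
    stop("parse error: terminal references unknown segment '", unknown[1], "'")
  wall <- do.call(wall_law_params, obj$wall[c("a1", "b1", "PmaxC", "Pwidth",
                                              "Pref", "a2", "b2")])
  vessel_network(seg, term, obj$inlet_segment, blood = obj$blood, wall = wall)
}
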