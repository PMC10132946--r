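# End-to-end orchestration: run scenarios across gestational ages and
# tabulate multiples-of-the-mean trajectories against the normal scenario.

#' Study configuration
#'
#' @param scenarios character vector of scenario names to run.
#' @param ages gestational ages (weeks); the default is the reduced
#'   schedule, the full schedule being 4-week increments 0--40.
#' @param seed integer seed for the network generator.
#' @param tree_config a [reduced_tree_config()].
#' @param baseline a [pregnancy_baseline()].
#' @param control a [calibration_control()].
#' @return list of class `run_config`.
#' @export
run_config <- function(scenarios = c("normal", "early_pe", "late_pe"),
                       ages = c(0, 12, 20, 32, 36, 40), seed = 1L,
                       tree_config = reduced_tree_config(),
                       baseline = pregnancy_baseline(),
                       control = calibration_control()) {
  stopifnot(all(ages >= 0 & ages <= 40), control$nt >= 100)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full gestational study
#'
#' Generates the reduced network, establishes the nongravid reference,
#' calibrates every requested scenario at every requested age (the normal
#' scenario is always run: it is the MoM denominator), and tabulates CO,
#' MAP, TPR, UA-PI, bilateral uterine flow, cf-PWV and AIx75 with their
#' multiples of the mean against the normal scenario.
#'
#' @param config a [run_config()].
#' @return list of class `study_report`: `mom_table` (data.frame keyed by
#'   scenario, age, metric), `calibrations` (nested list), `converged`
#'   (logical), `network` (nongravid reference).
#' @export
run_study <- function(config = run_config()) {
  net <- generate_reduced_tree(config$tree_config, seed = config$seed)
  ref <- calibrate_nongravid(net, config$baseline, config$control)
  scenarios <- union("normal", config$scenarios)
  cals <- list()
  for (sc in scenarios) {
    cals[[sc]] <- calibrate_sweep(ref$network, scenario_spec(sc),
                                  config$ages, config$baseline,
                                  config$control)
  }
  rows <- list()
  for (sc in scenarios) {
    for (a in names(cals[[sc]])) {
      cal <- cals[[sc]][[a]]
      m <- cal$metrics
      co <- measured_co(cal)
      vals <- c(CO = co, MAP = m$MAP,
                TPR = total_peripheral_resistance(m$MAP, co),
                UA_PI = m$UA_PI, UA_flow = m$UA_flow,
                cf_PWV = m$cf_PWV, AIx75 = m$AIx75)
      rows[[paste(sc, a)]] <- data.frame(
        scenario = sc, s = as.numeric(a), metric = names(vals),
        value = as.numeric(vals), converged = cal$converged,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  normal <- tab[tab$scenario == "normal", ]
  key <- paste(normal$s, normal$metric)
  tab$mom <- tab$value / normal$value[match(paste(tab$s, tab$metric), key)]
  structure(list(mom_table = tab, calibrations = cals,
                 converged = all(tab$converged), network = ref$network,
                 config = config),
            class = "study_report")
}

#' Cardiac output measured from the integrated inlet flow
#'
#' Integrates the inlet flow waveform of the reporting cycle and converts
#' to L/min.
#'
#' @param cal a `calibration_result` (or a `simulation_result`).
#' @return measured CO, L/min.
#' @export
measured_co <- function(cal) {
  res <- if (inherits(cal, "calibration_result")) cal$result else cal
  res$inflow_volume / res$inlet$tc * 60 / 1000
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", length(x$calibrations), "scenarios,",
      length(unique(x$mom_table$s)), "gestational ages;",
      if (x$converged) "all calibrations converged" else
        "SOME CALIBRATIONS DID NOT CONVERGE", "\n")
  wide <- x$mom_table[x$mom_table$scenario != "normal" &
                        x$mom_table$metric %in% c("CO", "TPR", "UA_PI"), ]
  if (nrow(wide)) {
    cat("MoM vs normal:\n")
    print(utils::head(stats::reshape(
      wide[, c("scenario", "s", "metric", "mom")],
      idvar = c("scenario", "s"), timevar = "metric",
      direction = "wide"), 20))
  }
  invisible(x)
}

#' Write the study tables to an output directory
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$mom_table, file.path(dir, "mom_table.csv"),
                   row.names = FALSE)
  write_network(report$network, file.path(dir, "reference_network.json"))
  manifest <- list(scenarios = names(report$calibrations),
                   ages = report$config$ages, seed = report$config$seed,
                   nt = report$config$control$nt,
                   converged = report$converged)
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
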