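# Full calibrated-scenario pipeline at the study conditions (default tree,
# nt = 500, 10-cycle reporting, 2% tolerance), computed once and shared by
# the acceptance test blocks.

.pipeline_cache <- new.env()

acceptance_pipeline <- function() {
  if (!is.null(.pipeline_cache$p)) return(.pipeline_cache$p)
  ctrl <- calibration_control()
  net <- generate_reduced_tree(seed = 1L)
  ref <- calibrate_nongravid(net, control = ctrl)
  sweeps <- list(
    normal = calibrate_sweep(ref$network, scenario_spec("normal"),
                             c(0, 12, 24, 32, 36, 40), control = ctrl),
    early_pe = calibrate_sweep(ref$network, scenario_spec("early_pe"),
                               c(0, 12, 24, 32), control = ctrl),
    late_pe = calibrate_sweep(ref$network, scenario_spec("late_pe"),
                              c(12, 24, 36), control = ctrl))
  .pipeline_cache$p <- list(ref = ref, sweeps = sweeps)
  .pipeline_cache$p
}

pipeline_metric <- function(p, scenario, s, what = c("TPR", "CO", "UA_PI",
                                                     "UA_flow", "cf_PWV",
                                                     "AIx75", "MAP")) {
  what <- match.arg(what)
  cal <- p$sweeps[[scenario]][[as.character(s)]]
  switch(what,
         TPR = cal$metrics$MAP / measured_co(cal),
         CO = measured_co(cal),
         MAP = cal$metrics$MAP,
         UA_PI = cal$metrics$UA_PI,
         UA_flow = cal$metrics$UA_flow,
         cf_PWV = cal$metrics$cf_PWV,
         AIx75 = cal$metrics$AIx75)
}
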