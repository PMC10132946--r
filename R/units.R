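# Unit conversion constants. Pressures are carried in kPa in the wall-law
# API (its parameters are published in kPa), in mmHg at I/O boundaries, and
# in Pa inside the compiled solver.

#' @keywords internal
KPA_PER_MMHG <- 0.1333223874

#' @keywords internal
PA_PER_MMHG <- 133.3223874

# 1 mmHg s/mL expressed in Pa s/m^3
#' @keywords internal
PA_S_M3_PER_MMHG_S_ML <- PA_PER_MMHG * 1e6

mmhg_to_kpa <- function(p) p * KPA_PER_MMHG
kpa_to_mmhg <- function(p) p / KPA_PER_MMHG
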