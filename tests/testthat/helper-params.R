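# Shared fixtures: the reference parameter set, the standard 30 s square
# protocol, and the default FRET calibration are computed once per run.

ref_params <- make_reference_params()
std_protocol <- stim_square(10, 30, 1)
std_cal <- fret_calibration()

# Zero one or more maximal conductances in place and recalibrate; used to
# build closed-membrane configurations for conservation tests.
zero_fluxes <- function(params, comps) {
  for (g in paste0("G_", comps)) params$free[[g]] <- 0
  params$calibrated <- FALSE
  suppressWarnings(calibrate_leaks(params))
}

empty_protocol <- function() {
  ash_protocol(data.frame(start = numeric(), end = numeric(),
                          s0 = numeric(), s1 = numeric()))
}

# Random valid model state (gates in [0,1], concentrations positive).
random_state <- function() {
  c(c = runif(1, 0.05, 1), c_ER = runif(1, 0.5, 20), O = runif(1),
    I = runif(1), P0 = runif(1, 0, 2), P1 = runif(1, 0, 2),
    P2 = runif(1, 0, 1), y = runif(1), p = runif(1, 0, 2),
    V = runif(1, -75, 20))
}
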