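# Full ODE system: 10 states
#   c (uM), c_ER (uM), O, I, P0, P1, P2 (dimensionless), y (fraction of
#   inhibited IPRs), p (IP3, uM), V (mV).

state_names <- function() c("c", "c_ER", "O", "I", "P0", "P1", "P2", "y", "p", "V")

#' Analytic rest state of the model
#'
#' The unstimulated fixed point: `c = c0`, `c_ER = c_ER0`, all cascade players
#' and IP3 at zero, TRPV gates at `O = 0, I = 1`, inhibited-IPR fraction at
#' `y = c0/(c0 + K4)`, and `V` at the fixed point of the graded-voltage
#' equation evaluated at `c0`.
#'
#' @param params An `ash_params` object.
#' @return Named numeric state vector of length 10.
#' @export
rest_state <- function(params) {
  fx <- params$fixed
  c0 <- fx[["c0"]]
  c(c = c0, c_ER = fx[["c_ER0"]], O = 0, I = 1, P0 = 0, P1 = 0, P2 = 0,
    y = c0 / (c0 + fx[["K4"]]), p = 0, V = voltage_fixed_point(c0, params))
}

#' Component fluxes at a model state
#'
#' Evaluates every Ca2+ flux of the mass balances at the given state.
#' Sign convention: `J_TRPV`, `J_IPR`, `J_VGCC`, `J_Leak`, `J_Leak_ER` are
#' cytosolic influxes (positive into the cytosol); `J_PMCA`, `J_SERCA` are
#' effluxes (positive out of the cytosol).
#'
#' @param state Named numeric state vector (see [rest_state()]).
#' @param params Calibrated `ash_params`.
#' @return Named numeric of the seven fluxes (uM/s).
#' @export
flux_vector <- function(state, params) {
  stopifnot_calibrated(params)
  f <- params$free
  c <- state[["c"]]; c_ER <- state[["c_ER"]]
  O_IPR <- ipr_open_probability(state[["p"]], c, state[["y"]], params)
  c(J_PMCA = hill2_pump_flux(c, f[["G_PMCA"]], f[["K_PMCA"]]),
    J_SERCA = hill2_pump_flux(c, f[["G_SERCA"]], f[["K_SERCA"]]),
    J_TRPV = trpv_flux(state[["O"]], state[["I"]], c, params),
    J_IPR = ipr_flux(c, c_ER, O_IPR, params),
    J_VGCC = vgcc_flux(state[["V"]], c, params),
    J_Leak = params$leaks[["J_Leak"]],
    J_Leak_ER = params$leaks[["J_Leak_ER"]])
}

#' Full model right-hand side
#'
#' Assembles all flux kernels and sub-system derivatives into the 10-state
#' derivative vector. The two mass balances are
#' `dc/dt = J_IPR + J_Leak_ER - J_PMCA - J_SERCA + J_TRPV + J_VGCC + J_Leak`
#' and `dc_ER/dt = gamma (J_SERCA - (J_IPR + J_Leak_ER))`.
#'
#' @param t Time (s); only used through the stimulus.
#' @param state Named numeric state vector.
#' @param protocol An `ash_protocol`, or a function of `t`, or a single
#'   stimulus value.
#' @param params Calibrated `ash_params`.
#' @return List with `deriv` (named numeric, length 10) and `fluxes`
#'   (the [flux_vector()] at the state).
#' @export
model_rhs <- function(t, state, protocol, params) {
  stopifnot_calibrated(params)
  S <- if (inherits(protocol, "ash_protocol")) eval_stimulus(protocol, t)
       else if (is.function(protocol)) protocol(t)
       else as.numeric(protocol)
  J <- flux_vector(state, params)
  casc <- cascade_rhs(state, S, params)
  rates <- ipr_inactivation_rates(state[["p"]], state[["c"]], params)
  gamma <- params$fixed[["gamma"]]
  deriv <- c(
    c = J[["J_IPR"]] + J[["J_Leak_ER"]] - J[["J_PMCA"]] - J[["J_SERCA"]] +
      J[["J_TRPV"]] + J[["J_VGCC"]] + J[["J_Leak"]],
    c_ER = gamma * (J[["J_SERCA"]] - (J[["J_IPR"]] + J[["J_Leak_ER"]])),
    O = casc[["O"]], I = casc[["I"]],
    P0 = casc[["P0"]], P1 = casc[["P1"]], P2 = casc[["P2"]],
    y = rates$phi1 * (1 - state[["y"]]) - rates$phi2 * state[["y"]],
    p = ip3_rhs(state[["P1"]], state[["P2"]], state[["c"]], state[["p"]], params),
    V = voltage_rhs(state[["c"]], state[["V"]], params))
  list(deriv = deriv, fluxes = J)
}

#' Calibrate leak fluxes for rest equilibrium
#'
#' Solves the two mass balances for the constant leak fluxes so that the
#' analytic rest state is a fixed point: at rest `p = 0` closes the IP3
#' receptor, so `J_Leak_ER = J_SERCA(c0)` and
#' `J_Leak = J_PMCA(c0) + J_SERCA(c0) - J_Leak_ER - J_TRPV(rest) - J_VGCC(rest)`
#' (the TRPV term is zero because `O = 0` at rest). When a pump is knocked out
#' the corresponding leak collapses accordingly (e.g. `G_PMCA = 0` gives a
#' membrane leak of essentially zero).
#'
#' @param params An `ash_params` object.
#' @param negative_tol Magnitude of negative leak tolerated silently (uM/s);
#'   a more negative leak signals inconsistent pump/channel strengths and
#'   triggers a warning.
#' @return The record with `leaks` filled in and `calibrated = TRUE`.
#' @export
calibrate_leaks <- function(params, negative_tol = 1e-3) {
  f <- params$free
  rest <- rest_state(params)
  c0 <- rest[["c"]]
  J_SERCA0 <- hill2_pump_flux(c0, f[["G_SERCA"]], f[["K_SERCA"]])
  J_PMCA0 <- hill2_pump_flux(c0, f[["G_PMCA"]], f[["K_PMCA"]])
  J_VGCC0 <- vgcc_flux(rest[["V"]], c0, params)
  # O_IPR(rest) = 0 since p = 0, and J_TRPV(rest) = 0 since O = 0
  J_Leak_ER <- J_SERCA0
  J_Leak <- J_PMCA0 + J_SERCA0 - J_Leak_ER - J_VGCC0
  if (min(J_Leak, J_Leak_ER) < -negative_tol) {
    warning(sprintf(
      "negative calibrated leak (J_Leak=%.4g, J_Leak_ER=%.4g uM/s): pump/channel strengths are inconsistent with the rest state",
      J_Leak, J_Leak_ER))
  }
  params$leaks <- c(J_Leak = J_Leak, J_Leak_ER = J_Leak_ER)
  params$calibrated <- TRUE
  params
}

#' In-silico knockout of a transport component
#'
#' Removes one Ca2+ transport component by zeroing its maximal flux scale and
#' recalibrating the leaks ("original" mode: all other parameters keep their
#' reference values). In "updated" mode the remaining parameters are re-fit
#' against a target dataset via [hybrid_fit()].
#'
#' @param params An `ash_params` object.
#' @param component One of `"PMCA"`, `"SERCA"`, `"TRPV"`, `"IPR"`, `"VGCC"`.
#' @param mode `"original"` (default) or `"updated"`.
#' @param dataset,cal,protocol,... For `mode = "updated"`: the target
#'   `ash_dataset`, FRET calibration, stimulus protocol, and further arguments
#'   passed to [hybrid_fit()].
#' @return Calibrated `ash_params` with the component removed (for
#'   `"updated"`, the re-fitted record from the returned `ash_fit`).
#' @export
apply_knockout <- function(params, component, mode = c("original", "updated"),
                           dataset = NULL, cal = NULL, protocol = NULL, ...) {
  mode <- match.arg(mode)
  component <- match.arg(component, c("PMCA", "SERCA", "TRPV", "IPR", "VGCC"))
  gname <- paste0("G_", component)
  # zero is outside the positivity domain of the constructor: set directly
  ko <- params
  ko$free[[gname]] <- 0
  ko$calibrated <- FALSE
  ko <- suppressWarnings(calibrate_leaks(ko))
  if (mode == "original") return(ko)
  if (is.null(dataset)) stop("mode = 'updated' needs a target dataset")
  free <- setdiff(selectable_param_names(), gname)
  fit <- hybrid_fit(dataset, free = free, init = ko, cal = cal,
                    protocol = protocol, ...)
  fit$params
}
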