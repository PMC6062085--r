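#' Physical and De Young-Keizer constants
#'
#' Fixed constants of the calcium model: volume ratio, membrane-potential
#' bounds, extracellular and initial calcium levels, the thermodynamic factor
#' RT/zF, and the original De Young-Keizer IP3-receptor constants.
#'
#' @return Named numeric vector of fixed constants.
#' @keywords internal
default_fixed_constants <- function() {
  c(
    gamma   = 5.4,      # cytosol:ER volume ratio (also absorbs fast ER buffering)
    V_max   = 20,       # mV, ceiling of the graded depolarisation
    V_rest  = -70,      # mV
    c_ES    = 2000,     # uM, extracellular Ca2+
    c0      = 0.1,      # uM, baseline cytosolic Ca2+ (100 nM)
    c_ER0   = 10,       # uM, initial ER Ca2+
    z       = 2,
    RT_zF   = 8.314462618 * 293.15 / (2 * 96485.33212) * 1000, # mV at 20 C
    # De Young & Keizer (1992) dissociation constants (uM) and backward rates (1/s)
    K1 = 0.13, K2 = 1.049, K3 = 0.9434, K4 = 0.1445, K5 = 0.08234,
    k2_minus = 0.2 * 1.049, k4_minus = 0.2 * 0.1445,
    # FRET sensor Hill constants
    fret_n = 1.7, fret_Kd = 2.5
  )
}

#' Names of the 23 free model parameters
#' @return Character vector, in canonical order.
#' @export
free_param_names <- function() {
  c("G_PMCA", "K_PMCA", "G_SERCA", "K_SERCA", "G_TRPV", "G_IPR", "G_VGCC",
    "k_O", "k_O_minus", "k_I", "k_I_minus",
    "k_P1", "k_P1_minus", "k_P2", "k_P2_minus", "K_P2",
    "k_P0", "k_P0_minus", "K_P0",
    "k_p", "k_p_minus", "K_p", "K_c")
}

#' The 13-parameter subset examined for aging / oxidative-stress effects
#'
#' Strengths and rates of the key players of the signalling mechanism (TRPV
#' activation/inactivation, IP3 turnover, IP3 receptors, PMCA, SERCA) that the
#' condition-refit stage is allowed to change while the rest stay frozen.
#'
#' @return Character vector of 13 parameter names.
#' @export
selectable_param_names <- function() {
  c("G_PMCA", "K_PMCA", "G_SERCA", "K_SERCA", "G_IPR",
    "k_p", "k_p_minus", "k_O", "k_O_minus", "k_I", "k_I_minus",
    "k_P0", "k_P0_minus")
}

#' Construct a model parameter record
#'
#' Bundles the 23 free parameters with the fixed physical constants. Leak
#' fluxes are NOT set by the constructor; call [calibrate_leaks()] before
#' simulating so that the unstimulated rest state is an equilibrium.
#'
#' @param free Named numeric vector or list overriding any of the 23 free
#'   parameters (see [free_param_names()]). Units: conductances G_* in uM/s
#'   (G_TRPV, G_IPR in 1/s against a concentration gradient; G_VGCC an
#'   effective uM/(mV s) scale), affinities K_PMCA/K_SERCA in uM^2, K_c in uM,
#'   rate constants in 1/s.
#' @param fixed Named numeric vector or list overriding fixed constants.
#' @return Object of class `ash_params`: list with elements `free` (named
#'   numeric, length 23), `fixed`, `leaks` (J_Leak, J_Leak_ER; NA until
#'   calibrated) and `calibrated` flag.
#' @seealso [make_reference_params()] for the packaged reference set.
#' @export
ash_params <- function(free = list(), fixed = list()) {
  f <- reference_free_values()
  free <- unlist(free)
  if (length(free)) {
    bad <- setdiff(names(free), free_param_names())
    if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
    f[names(free)] <- free
  }
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("all 23 free parameters must be strictly positive and finite")
  }
  fx <- default_fixed_constants()
  fixed <- unlist(fixed)
  if (length(fixed)) {
    bad <- setdiff(names(fixed), names(fx))
    if (length(bad)) stop("unknown fixed constant(s): ", paste(bad, collapse = ", "))
    fx[names(fixed)] <- fixed
  }
  structure(list(free = f, fixed = fx,
                 leaks = c(J_Leak = NA_real_, J_Leak_ER = NA_real_),
                 calibrated = FALSE),
            class = "ash_params")
}

#' @export
print.ash_params <- function(x, ...) {
  cat("ASH neuron Ca2+ model parameters\n")
  cat(sprintf("  free (23): %s ...\n",
              paste(sprintf("%s=%.4g", names(x$free)[1:5], x$free[1:5]), collapse = ", ")))
  if (x$calibrated) {
    cat(sprintf("  leaks: J_Leak=%.6g uM/s, J_Leak_ER=%.6g uM/s (calibrated)\n",
                x$leaks[["J_Leak"]], x$leaks[["J_Leak_ER"]]))
  } else {
    cat("  leaks: not calibrated (run calibrate_leaks())\n")
  }
  invisible(x)
}

#' @export
summary.ash_params <- function(object, ...) {
  df <- data.frame(parameter = names(object$free), value = unname(object$free))
  print(df, row.names = FALSE)
  invisible(df)
}

stopifnot_calibrated <- function(params) {
  if (!isTRUE(params$calibrated)) {
    stop("parameter record is not calibrated; run calibrate_leaks() first")
  }
}

#' Update free parameters of a record
#'
#' Returns a new record with the given free parameters replaced and the
#' calibration flag cleared (leaks must be recomputed).
#'
#' @param params An `ash_params` object.
#' @param ... Named scalar values, or a single named vector/list.
#' @return New, uncalibrated `ash_params`.
#' @export
set_params <- function(params, ...) {
  upd <- list(...)
  if (length(upd) == 1L && (is.null(names(upd)) || !nzchar(names(upd)[1]))) {
    upd <- upd[[1]]
  }
  upd <- unlist(upd)
  f <- params$free
  bad <- setdiff(names(upd), names(f))
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  f[names(upd)] <- upd
  ash_params(free = f, fixed = params$fixed)
}

#' Serialize a parameter record to a YAML config file
#'
#' Writes a flat `free:` block (the 23 parameters), a `fixed:` block and, if
#' calibrated, a `leaks:` block.
#'
#' @param params An `ash_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  obj <- list(free = as.list(params$free), fixed = as.list(params$fixed))
  if (params$calibrated) obj$leaks <- as.list(params$leaks)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a parameter record from a YAML config file
#'
#' @param path File written by [write_params()] (leaks are recomputed, not
#'   trusted from file).
#' @return Calibration-cleared `ash_params`.
#' @export
read_params <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$free)) stop("config has no 'free' block: ", path)
  ash_params(free = obj$free, fixed = if (is.null(obj$fixed)) list() else obj$fixed)
}
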