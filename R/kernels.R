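# Flux kernels and sub-system right-hand sides. All concentrations in uM,
# rates in 1/s, fluxes in uM/s, voltage in mV, time in s. Each kernel is
# vectorized over its state arguments.

# Guarded evaluation of x/(exp(x)-1): removable singularity at x = 0.
# Within |x| < 1e-4 use the series 1 - x/2 + x^2/12 (error O(x^4)).
expm1_ratio <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- 1 - x[small] / 2 + x[small]^2 / 12
  out[!small] <- x[!small] / expm1(x[!small])
  out
}

#' Hill-squared pump flux (PMCA / SERCA)
#'
#' Ca2+-ATPase pump flux with cooperative (Hill exponent 2) calcium binding:
#' `G * c^2 / (c^2 + K)`.
#'
#' @param c Cytosolic Ca2+ (uM).
#' @param G Maximal pump flux (uM/s).
#' @param K Affinity constant (uM^2).
#' @return Flux in uM/s, in `[0, G)`.
#' @export
hill2_pump_flux <- function(c, G, K) {
  if (any(K <= 0)) stop("pump affinity K must be > 0")
  G * c^2 / (c^2 + K)
}

#' TRPV channel Ca2+ influx
#'
#' Stimulus-gated influx from the extracellular space,
#' `G_TRPV * O * I * (c_ES - c)`. `O` and `I` are the activation and
#' inactivation gate variables.
#'
#' @param O,I Gate variables in `[0, 1]`.
#' @param c Cytosolic Ca2+ (uM).
#' @param params An `ash_params` object (uses `G_TRPV`, `c_ES`).
#' @return Influx in uM/s.
#' @export
trpv_flux <- function(O, I, c, params) {
  params$free[["G_TRPV"]] * O * I * (params$fixed[["c_ES"]] - c)
}

#' IP3 receptor open probability (reduced De Young-Keizer)
#'
#' `O_IPR = (p c (1 - y) / ((p + K1)(c + K5)))^3` where `y` is the fraction of
#' inhibited receptors.
#'
#' @param p IP3 concentration (uM).
#' @param c Cytosolic Ca2+ (uM).
#' @param y Fraction of inhibited IPRs, in `[0, 1]`.
#' @param params An `ash_params` object (uses DYK constants K1, K5).
#' @return Open probability in `[0, 1]`.
#' @export
ipr_open_probability <- function(p, c, y, params) {
  K1 <- params$fixed[["K1"]]; K5 <- params$fixed[["K5"]]
  (p * c * (1 - y) / ((p + K1) * (c + K5)))^3
}

#' Inactivation rates of the reduced De Young-Keizer IPR model
#'
#' Effective forward/backward rates for the inhibited fraction `y`:
#' `phi1 = c (k4m K1 K2 + k2m K4 p) / (K4 K2 (K1 + p))` and
#' `phi2 = (k2m p + k4m K3) / (K3 + p)`, with the original De Young-Keizer
#' constants.
#'
#' @param p IP3 concentration (uM).
#' @param c Cytosolic Ca2+ (uM).
#' @param params An `ash_params` object.
#' @return List with numeric components `phi1`, `phi2` (1/s).
#' @export
ipr_inactivation_rates <- function(p, c, params) {
  fx <- params$fixed
  K1 <- fx[["K1"]]; K2 <- fx[["K2"]]; K3 <- fx[["K3"]]; K4 <- fx[["K4"]]
  k2m <- fx[["k2_minus"]]; k4m <- fx[["k4_minus"]]
  phi1 <- c * (k4m * K1 * K2 + k2m * K4 * p) / (K4 * K2 * (K1 + p))
  phi2 <- (k2m * p + k4m * K3) / (K3 + p)
  list(phi1 = phi1, phi2 = phi2)
}

#' IP3 receptor Ca2+ release flux
#'
#' ER-to-cytosol release `G_IPR * O_IPR * (c_ER - c)`: positive (cytosolic
#' influx) whenever the ER holds more Ca2+ than the cytosol.
#'
#' @param c Cytosolic Ca2+ (uM).
#' @param c_ER ER Ca2+ (uM).
#' @param O_IPR Open probability in `[0, 1]`.
#' @param params An `ash_params` object (uses `G_IPR`).
#' @return Release flux in uM/s.
#' @export
ipr_flux <- function(c, c_ER, O_IPR, params) {
  params$free[["G_IPR"]] * O_IPR * (c_ER - c)
}

#' L-type VGCC steady-state activation
#'
#' `m_inf = alpha / (alpha + beta)` with the L-type voltage-dependent rates
#' `alpha(V) = 1.6 / (1 + exp(-0.072 (V - 5)))` and
#' `beta(V) = 0.02 (V - 1.31) / (exp((V - 1.31)/5.36) - 1)`; the removable
#' singularity of `beta` at V = 1.31 is evaluated by its series limit.
#'
#' @param V Membrane potential (mV).
#' @return Activation in `(0, 1)`.
#' @export
vgcc_activation <- function(V) {
  alpha <- 1.6 / (1 + exp(-0.072 * (V - 5)))
  x <- (V - 1.31) / 5.36
  beta <- 0.02 * 5.36 * expm1_ratio(x)
  alpha / (alpha + beta)
}

#' VGCC Ca2+ influx (Goldman-Hodgkin-Katz)
#'
#' Constant-field flux through L-type voltage-gated Ca2+ channels with
#' quasi-steady activation:
#' `G_VGCC * m_inf(V)^2 * V * (c_ES e^{-zFV/RT} - c) / (1 - e^{-zFV/RT})`,
#' oriented so that influx is positive at physiological negative potentials
#' with `c << c_ES`. Continuous across V = 0, where it equals
#' `G_VGCC * m_inf(0)^2 * (RT/zF) * (c_ES - c)`.
#'
#' @param V Membrane potential (mV).
#' @param c Cytosolic Ca2+ (uM).
#' @param params An `ash_params` object (uses `G_VGCC`, `c_ES`, `RT_zF`).
#' @return Influx in uM/s.
#' @export
vgcc_flux <- function(V, c, params) {
  G <- params$free[["G_VGCC"]]
  c_ES <- params$fixed[["c_ES"]]
  rtzf <- params$fixed[["RT_zF"]]
  x <- V / rtzf                               # zFV/RT, dimensionless
  m2 <- vgcc_activation(V)^2
  # J = G m^2 * rtzf * (c_ES e^-x - c) * x/(1 - e^-x);
  # x/(1 - e^-x) = 1 + x/2 + x^2/12 + O(x^4) guards the V = 0 singularity.
  small <- abs(x) < 1e-4
  out <- numeric(length(x))
  if (any(small)) {
    xs <- x[small]
    cs <- if (length(c) > 1) c[small] else c
    out[small] <- G * m2[small] * rtzf *
      (c_ES * exp(-xs) - cs) * (1 + xs / 2 + xs^2 / 12)
  }
  if (any(!small)) {
    xl <- x[!small]
    cl <- if (length(c) > 1) c[!small] else c
    out[!small] <- G * m2[!small] * rtzf * xl * (c_ES * exp(-xl) - cl) / (-expm1(-xl))
  }
  out
}

#' Stimulus-transduction cascade derivatives
#'
#' Time derivatives of the coarse-grained players P0, P1, P2 and the TRPV
#' gates O, I:
#' \describe{
#'   \item{P0}{`k_P0 S/(S + K_P0) - k_P0m P0` (stimulus-triggered G-protein stage)}
#'   \item{P1}{`k_P1 P0 - k_P1m P1` (activating branch)}
#'   \item{P2}{`k_P2 P0/(P0 + K_P2) - k_P2m P2` (inactivating, saturating branch)}
#'   \item{O}{`k_O P1 (1 - O) - k_Om O`}
#'   \item{I}{`k_I (1 - I) - k_Im P2 I`}
#' }
#'
#' @param state Named numeric with elements `P0`, `P1`, `P2`, `O`, `I`.
#' @param S Stimulus strength (dimensionless).
#' @param params An `ash_params` object.
#' @return Named numeric of the five derivatives (1/s).
#' @export
cascade_rhs <- function(state, S, params) {
  f <- params$free
  P0 <- state[["P0"]]; P1 <- state[["P1"]]; P2 <- state[["P2"]]
  O <- state[["O"]]; I <- state[["I"]]
  c(P0 = f[["k_P0"]] * S / (S + f[["K_P0"]]) - f[["k_P0_minus"]] * P0,
    P1 = f[["k_P1"]] * P0 - f[["k_P1_minus"]] * P1,
    P2 = f[["k_P2"]] * P0 / (P0 + f[["K_P2"]]) - f[["k_P2_minus"]] * P2,
    O  = f[["k_O"]] * P1 * (1 - O) - f[["k_O_minus"]] * O,
    I  = f[["k_I"]] * (1 - I) - f[["k_I_minus"]] * P2 * I)
}

#' IP3 production/decay (incoherent feed-forward motif)
#'
#' `dp/dt = k_p P1 / (1 + (K_p P2)^4) * c^2/(c^2 + K_c^2) - k_pm p`.
#' P1 promotes and P2 suppresses IP3 production; the Ca2+ Hill term encodes
#' Ca2+-induced Ca2+ release. The suppression lifts only after stimulus
#' withdrawal (P2 decays faster than P1), producing the "off" IP3 surge.
#'
#' @param P1,P2 Cascade players (dimensionless).
#' @param c Cytosolic Ca2+ (uM).
#' @param p IP3 concentration (uM).
#' @param params An `ash_params` object.
#' @return dp/dt in uM/s.
#' @export
ip3_rhs <- function(P1, P2, c, p, params) {
  f <- params$free
  f[["k_p"]] * P1 / (1 + (f[["K_p"]] * P2)^4) * c^2 / (c^2 + f[["K_c"]]^2) -
    f[["k_p_minus"]] * p
}

#' Graded membrane-potential dynamics
#'
#' `dV/dt = alpha'(c) (V_max - V) - beta'(c) (V - V_rest)` with
#' Ca2+-dependent rates `alpha'(c) = (-26 c + 4)/(e^{-26 c + 4} - 1)` and
#' `beta'(c) = (260 c - 20)/(e^{13 c - 1} - 1)` (removable singularities
#' evaluated by their limits). This is a phenomenological graded (non-spiking)
#' voltage response driven by cytosolic Ca2+.
#'
#' @param c Cytosolic Ca2+ (uM).
#' @param V Membrane potential (mV).
#' @param params An `ash_params` object (uses `V_max`, `V_rest`).
#' @return dV/dt in mV/s.
#' @export
voltage_rhs <- function(c, V, params) {
  r <- voltage_rates(c)
  r$alpha * (params$fixed[["V_max"]] - V) - r$beta * (V - params$fixed[["V_rest"]])
}

# alpha'(c), beta'(c) of the graded-voltage equation, singularity-guarded.
voltage_rates <- function(c) {
  xa <- -26 * c + 4
  alpha <- expm1_ratio(xa)            # (-26c+4)/(e^(-26c+4)-1) = xa/(e^xa - 1)
  xb <- 13 * c - 1
  beta <- 20 * expm1_ratio(xb)        # (260c-20)/(e^(13c-1)-1) = 20 * xb/(e^xb-1)
  list(alpha = alpha, beta = beta)
}

# Equilibrium membrane potential at a given cytosolic Ca2+.
voltage_fixed_point <- function(c, params) {
  r <- voltage_rates(c)
  (r$alpha * params$fixed[["V_max"]] + r$beta * params$fixed[["V_rest"]]) /
    (r$alpha + r$beta)
}
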