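# Trajectory integration over a stimulus protocol, flux decomposition,
# and extraction of the transient features used to characterise "on"/"off"
# responses.

# Parameter vector handed to the compiled RHS; order must match src/ashca_rhs.c.
ash_parms_vector <- function(params, stim_a = 0, stim_b = 0) {
  fx <- params$fixed
  c(unname(params$free[free_param_names()]),
    fx[["gamma"]], fx[["V_max"]], fx[["V_rest"]], fx[["c_ES"]], fx[["RT_zF"]],
    fx[["K1"]], fx[["K2"]], fx[["K3"]], fx[["K4"]], fx[["K5"]],
    fx[["k2_minus"]], fx[["k4_minus"]],
    params$leaks[["J_Leak"]], params$leaks[["J_Leak_ER"]],
    stim_a, stim_b)
}

# Linear coefficients (a, b) with S = a + b t on the piece containing `mid`.
segment_coeffs <- function(protocol, mid) {
  for (i in seq_len(nrow(protocol))) {
    if (mid >= protocol$start[i] && mid < protocol$end[i]) {
      slope <- (protocol$s1[i] - protocol$s0[i]) / (protocol$end[i] - protocol$start[i])
      return(c(protocol$s0[i] - slope * protocol$start[i], slope))
    }
  }
  c(0, 0)
}

#' Simulate the model over a stimulus protocol
#'
#' Integrates the 10-state system from the analytic rest state with a
#' stiff-capable adaptive integrator (deSolve's lsoda, relative tolerance
#' 1e-8, absolute 1e-10), restarting at every protocol segment boundary so
#' square edges are not smeared by adaptive stepping. The returned trace
#' carries the full state, the percent FRET series, and the per-component
#' flux decomposition at every output point.
#'
#' @param params Calibrated `ash_params`.
#' @param protocol An `ash_protocol`.
#' @param t_end End of the simulation (s).
#' @param output_dt Output grid spacing (s).
#' @param cal A `fret_calibration` used for the FRET column.
#' @return Object of class `ash_trace`: data.frame with columns `time`, the
#'   10 states, `S`, `FRET`, and the seven fluxes; attributes `params`,
#'   `protocol`, `cal`, and `diverged`. The divergence flag is set when the
#'   solver fails, when the cytosolic concentration exceeds 100 x c_ES (the
#'   trace is then truncated), or when cytosolic Ca2+ fails to return towards
#'   baseline (final c above 10 x c0) - the signature of a model whose efflux
#'   machinery cannot restore rest (e.g. a PMCA knockout).
#' @export
run_simulation <- function(params, protocol, t_end = 70, output_dt = 0.1,
                           cal = fret_calibration()) {
  stopifnot_calibrated(params)
  grid <- seq(0, t_end, by = output_dt)
  breaks <- protocol_breaks(protocol)
  breaks <- breaks[breaks > 0 & breaks < t_end]
  pieces <- cbind(c(0, breaks), c(breaks, t_end))
  y <- rest_state(params)
  rows <- list()
  diverged <- FALSE
  for (k in seq_len(nrow(pieces))) {
    t0 <- pieces[k, 1]; t1 <- pieces[k, 2]
    gpts <- grid[grid > t0 + 1e-12 & grid <= t1 + 1e-12]
    times <- unique(c(t0, gpts, t1))
    if (length(times) < 2) times <- c(t0, t1)
    ab <- segment_coeffs(protocol, (t0 + t1) / 2)
    pv <- ash_parms_vector(params, ab[1], ab[2])
    sol <- tryCatch(
      deSolve::ode(y = unname(y), times = times, func = "derivs",
                   parms = pv, dllname = "ashca", initfunc = "initmod",
                   method = "lsoda", rtol = 1e-8, atol = 1e-10),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(sol) || anyNA(sol)) { diverged <- TRUE; break }
    m <- unclass(sol)
    bad <- which(!is.finite(m[, 2]) | m[, 2] > 100 * params$fixed[["c_ES"]])
    if (length(bad)) {
      m <- m[seq_len(min(bad) - 1), , drop = FALSE]
      diverged <- TRUE
    }
    keep <- m[, 1] %in% gpts | (k == 1 & m[, 1] == 0)
    rows[[k]] <- m[keep, , drop = FALSE]
    if (diverged) break
    y <- m[nrow(m), -1]
    names(y) <- state_names()
  }
  out <- do.call(rbind, rows)
  df <- as.data.frame(out)
  names(df) <- c("time", state_names())
  if (!diverged && nrow(df) &&
      df$c[nrow(df)] > 10 * params$fixed[["c0"]]) {
    diverged <- TRUE  # no recovery towards the rest state
  }
  df$S <- eval_stimulus(protocol, df$time)
  df$FRET <- c_to_fret(pmax(df$c, 0), cal)
  fl <- trace_fluxes(df, params)
  df <- cbind(df, fl)
  structure(df, class = c("ash_trace", "data.frame"),
            params = params, protocol = protocol, cal = cal, diverged = diverged)
}

# Vectorized flux decomposition over the rows of a state data.frame.
trace_fluxes <- function(df, params) {
  f <- params$free
  O_IPR <- ipr_open_probability(df$p, df$c, df$y, params)
  data.frame(
    J_PMCA = hill2_pump_flux(df$c, f[["G_PMCA"]], f[["K_PMCA"]]),
    J_SERCA = hill2_pump_flux(df$c, f[["G_SERCA"]], f[["K_SERCA"]]),
    J_TRPV = trpv_flux(df$O, df$I, df$c, params),
    J_IPR = ipr_flux(df$c, df$c_ER, O_IPR, params),
    J_VGCC = vgcc_flux(df$V, df$c, params),
    J_Leak = rep(params$leaks[["J_Leak"]], nrow(df)),
    J_Leak_ER = rep(params$leaks[["J_Leak_ER"]], nrow(df)))
}

#' @export
print.ash_trace <- function(x, ...) {
  cat(sprintf("ASH Ca2+ trace: %d points over %.6g s%s\n", nrow(x),
              max(x$time), if (isTRUE(attr(x, "diverged"))) " [DIVERGED]" else ""))
  cat(sprintf("  peak FRET %.3g %%, peak c %.4g uM\n", max(x$FRET), max(x$c)))
  invisible(x)
}

#' @export
plot.ash_trace <- function(x, which = c("fret", "states", "fluxes"), ...) {
  which <- match.arg(which)
  if (which == "fret") {
    graphics::plot(x$time, x$FRET, type = "l", xlab = "time (s)",
                   ylab = "FRET ratio change (%)", ...)
    smax <- max(x$S)
    if (smax > 0) graphics::lines(x$time, x$S / smax * max(x$FRET) * 0.2,
                                  col = "red", lty = 2)
  } else if (which == "states") {
    graphics::par(mfrow = c(2, 2))
    for (v in c("c", "c_ER", "p", "V")) {
      graphics::plot(x$time, x[[v]], type = "l", xlab = "time (s)", ylab = v)
    }
    graphics::par(mfrow = c(1, 1))
  } else {
    cols <- c("J_TRPV", "J_IPR", "J_VGCC", "J_PMCA", "J_SERCA")
    graphics::matplot(x$time, as.matrix(x[cols]), type = "l", lty = 1,
                      xlab = "time (s)", ylab = "flux (uM/s)")
    graphics::legend("topright", legend = cols, col = seq_along(cols), lty = 1)
  }
  invisible(x)
}

#' Extract "on"/"off" transient features from a trace
#'
#' Computes the eight summary features of a stimulus-evoked FRET transient:
#' the "on" peak and its time, the plateau level (mean FRET between 30 and
#' 40 s of the response clock for a >= 40 s stimulus, else over the final
#' third of the pulse), the decaying slope of the "on" response
#' `(on_max - A_plateau)/(T_minplateau - T_max)`, the "off" peak and its
#' time, the rising slope of the "off" response
#' `(off_max - A_plateau)/(T_offmax - T_stim_end)`, and the decaying slope of
#' the "off" response `off_max / |T_offmax - T_min|` with `T_min` the time of
#' the post-peak minimum. `T_minplateau` is the first time after the "on"
#' peak at which the trace enters within 2 % of the plateau level.
#'
#' @param trace An `ash_trace` (or data.frame with `time` and `FRET`).
#' @param stim_start,stim_end Stimulus onset/offset (s).
#' @return Object of class `ash_features`: named list with `on_max`,
#'   `t_on_max`, `A_plateau`, `on_decay_slope`, `off_max`, `t_off_max`,
#'   `off_rise_slope`, `off_decay_slope`.
#' @export
extract_features <- function(trace, stim_start, stim_end) {
  t <- trace$time; fr <- trace$FRET
  if (max(t) < stim_end + 20) stop("trace must extend >= 20 s past stimulus offset")
  on_idx <- which(t >= stim_start & t <= stim_end)
  i_on <- on_idx[which.max(fr[on_idx])]
  on_max <- fr[i_on]; t_on_max <- t[i_on]
  dur <- stim_end - stim_start
  if (dur >= 40) {
    p_lo <- stim_start + 30; p_hi <- stim_start + 40
  } else {
    p_lo <- stim_start + 2 * dur / 3; p_hi <- stim_end
  }
  pl_idx <- which(t >= p_lo & t <= p_hi)
  A_plateau <- mean(fr[pl_idx])
  # first entry into the 2% band around the plateau after the on-peak
  tol <- max(0.02 * abs(A_plateau), 1e-9)
  after <- which(t > t_on_max & t <= stim_end)
  hit <- after[abs(fr[after] - A_plateau) <= tol]
  T_minplateau <- if (length(hit)) t[hit[1]] else stim_end
  on_decay_slope <- safe_slope(on_max - A_plateau, T_minplateau - t_on_max)
  off_idx <- which(t > stim_end)
  i_off <- off_idx[which.max(fr[off_idx])]
  off_max <- fr[i_off]; t_off_max <- t[i_off]
  off_rise_slope <- safe_slope(off_max - A_plateau, t_off_max - stim_end)
  post <- which(t >= t_off_max)
  T_min <- t[post[which.min(fr[post])]]
  off_decay_slope <- safe_slope(off_max, abs(T_min - t_off_max))
  structure(list(on_max = on_max, t_on_max = t_on_max, A_plateau = A_plateau,
                 on_decay_slope = on_decay_slope, off_max = off_max,
                 t_off_max = t_off_max, off_rise_slope = off_rise_slope,
                 off_decay_slope = off_decay_slope),
            class = "ash_features")
}

safe_slope <- function(num, den) {
  if (abs(num) < 1e-12) return(0)
  if (abs(den) < 1e-12) return(0)
  num / den
}

#' @export
print.ash_features <- function(x, ...) {
  cat("Transient features:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Knockout matrix: simulate all five in-silico knockouts
#'
#' Simulates the reference model and each single-component knockout
#' ("original"-parameter mode) under the same protocol and summarises the
#' qualitative outcome of each.
#'
#' @param params Calibrated reference `ash_params`.
#' @param protocol Stimulus protocol (default 30 s square pulse at t = 10 s).
#' @param t_end Simulation horizon (s).
#' @param cal FRET calibration.
#' @return data.frame with one row per model (reference + 5 knockouts):
#'   `component`, `diverged`, `on_max` (peak percent FRET during the pulse),
#'   `off_max` (peak after withdrawal), and `off_rise` (the rise of the "off"
#'   peak above the FRET level at stimulus offset - the magnitude of the
#'   "off" response proper, which is zero for a trace that merely decays
#'   from its plateau).
#' @export
knockout_matrix <- function(params, protocol = stim_square(10, 30, 1),
                            t_end = 80, cal = fret_calibration()) {
  stim_start <- protocol$start[1]
  stim_end <- max(protocol$end)
  one <- function(label, pp) {
    tr <- run_simulation(pp, protocol, t_end = t_end, cal = cal)
    div <- isTRUE(attr(tr, "diverged"))
    if (max(tr$time) < stim_end + 20) {
      return(data.frame(component = label, diverged = div,
                        on_max = NA_real_, off_max = NA_real_,
                        off_rise = NA_real_))
    }
    fe <- extract_features(tr, stim_start, stim_end)
    f_end <- tr$FRET[which.min(abs(tr$time - stim_end))]
    data.frame(component = label, diverged = div,
               on_max = fe$on_max, off_max = fe$off_max,
               off_rise = fe$off_max - f_end)
  }
  out <- one("reference", params)
  for (comp in c("PMCA", "SERCA", "TRPV", "IPR", "VGCC")) {
    out <- rbind(out, one(comp, apply_knockout(params, comp)))
  }
  rownames(out) <- NULL
  out
}
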