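# Conversion between cytosolic Ca2+ and percent FRET ratio change of the
# TN-XL sensor. The ratio follows a Hill saturation
#   R(c) = R_min + (R_max - R_min) * c^n / (c^n + Kd^n)
# and the reported signal is FRET% = 100 (R(c) - R_0)/R_0 with R_0 the ratio
# at baseline Ca2+.

hill_frac <- function(c, n, Kd) c^n / (c^n + Kd^n)

#' Two-point FRET calibration
#'
#' Solves for `R_min` and `R_max` from two anchor conditions: the ratio takes
#' a known value at the baseline Ca2+ concentration, and the percent ratio
#' change takes a known value at a reference concentration. With the defaults
#' this encodes R = 5 at 100 nM and +10 % at 500 nM for the TN-XL sensor
#' (Hill coefficient 1.7, apparent affinity 2.5 uM).
#'
#' @param c_baseline Baseline Ca2+ (uM).
#' @param R_baseline Ratio at baseline (sets `R_0`).
#' @param c_ref Reference Ca2+ (uM), different from `c_baseline`.
#' @param fret_ref Percent FRET change at `c_ref`.
#' @param n Hill coefficient.
#' @param Kd Apparent affinity (uM).
#' @return Object of class `fret_calibration`: list with `n`, `Kd`, `R_min`,
#'   `R_max`, `R_0`.
#' @export
fret_calibration <- function(c_baseline = 0.1, R_baseline = 5,
                             c_ref = 0.5, fret_ref = 10,
                             n = 1.7, Kd = 2.5) {
  if (c_baseline <= 0 || c_ref <= 0) stop("anchor concentrations must be > 0")
  if (abs(c_baseline - c_ref) < 1e-12) {
    stop("degenerate calibration: c_baseline must differ from c_ref")
  }
  if (n <= 0 || Kd <= 0) stop("n and Kd must be > 0")
  f0 <- hill_frac(c_baseline, n, Kd)
  f1 <- hill_frac(c_ref, n, Kd)
  # R_min + dR f0 = R_baseline;  R_min + dR f1 = R_baseline (1 + fret_ref/100)
  dR <- R_baseline * fret_ref / 100 / (f1 - f0)
  R_min <- R_baseline - dR * f0
  R_max <- R_min + dR
  if (R_max <= R_min) stop("non-physical calibration: R_max <= R_min")
  structure(list(n = n, Kd = Kd, R_min = R_min, R_max = R_max, R_0 = R_baseline),
            class = "fret_calibration")
}

#' @export
print.fret_calibration <- function(x, ...) {
  cat(sprintf("FRET calibration: n=%.3g, K'd=%.3g uM, R_min=%.6g, R_max=%.6g, R_0=%.6g\n",
              x$n, x$Kd, x$R_min, x$R_max, x$R_0))
  invisible(x)
}

fret_ratio <- function(c, cal) {
  cal$R_min + (cal$R_max - cal$R_min) * hill_frac(c, cal$n, cal$Kd)
}

#' Convert Ca2+ concentration to percent FRET ratio change
#'
#' @param c Cytosolic Ca2+ (uM), >= 0.
#' @param cal A `fret_calibration`.
#' @return Percent FRET change, `100 (R(c) - R_0)/R_0`; strictly increasing
#'   in `c` with finite asymptote `100 (R_max - R_0)/R_0`.
#' @export
c_to_fret <- function(c, cal = fret_calibration()) {
  100 * (fret_ratio(c, cal) - cal$R_0) / cal$R_0
}

#' Convert percent FRET ratio change to Ca2+ concentration
#'
#' Exact algebraic inverse of [c_to_fret()].
#'
#' @param fret Percent FRET change, inside the attainable open interval.
#' @param cal A `fret_calibration`.
#' @return Ca2+ concentration (uM).
#' @export
fret_to_c <- function(fret, cal = fret_calibration()) {
  lo <- 100 * (cal$R_min - cal$R_0) / cal$R_0
  hi <- 100 * (cal$R_max - cal$R_0) / cal$R_0
  if (any(fret <= lo) || any(fret >= hi)) {
    stop(sprintf("FRET value outside the attainable interval (%.6g, %.6g) %%", lo, hi))
  }
  R <- cal$R_0 * (1 + fret / 100)
  frac <- (R - cal$R_min) / (cal$R_max - cal$R_min)
  cal$Kd * (frac / (1 - frac))^(1 / cal$n)
}
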