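# Reference parameter fixture and synthetic cohort data generation. The
# reference 23-parameter set is a packaged, versioned fixture designed so the
# standard 30 s square stimulus yields rest at 100 nM, an "on" peak near 10 %
# FRET, a plateau over the 30-40 s window, and a distinct "off" peak after
# withdrawal. It is a synthetic reference, not a published table.

reference_free_values <- function() {
  c(
    # pumps (uM/s; affinities uM^2)
    G_PMCA = 3.0, K_PMCA = 0.12, G_SERCA = 0.45, K_SERCA = 0.15,
    # channels
    G_TRPV = 0.0135,  # 1/s against the ~2000 uM extracellular gradient
    G_IPR = 8.0,      # 1/s against the ER gradient
    G_VGCC = 3e-6,    # uM/(mV s) effective GHK scale (weak, secondary route)
    # TRPV gates: O closes fast after stimulus, I recovers slowly
    k_O = 1.5, k_O_minus = 3.0, k_I = 0.03, k_I_minus = 1.2,
    # cascade: P0 fast near-linear transduction; P1 slow (activating branch),
    # P2 fast (inactivating branch) - the timescale split that confines the
    # IP3 surge to stimulus withdrawal
    k_P1 = 0.25, k_P1_minus = 0.25, k_P2 = 1.0, k_P2_minus = 2.0, K_P2 = 0.5,
    k_P0 = 400, k_P0_minus = 1.0, K_P0 = 400,
    # IP3 turnover
    k_p = 5.0, k_p_minus = 3.0, K_p = 5.2, K_c = 0.3
  )
}

#' Reference model parameters
#'
#' Returns the packaged 23-parameter reference set (the "young unstressed"
#' baseline of the synthetic cohorts), leak-calibrated and ready to simulate.
#' Repeated calls return identical values.
#'
#' @return Calibrated `ash_params`.
#' @export
make_reference_params <- function() {
  calibrate_leaks(ash_params())
}

#' Cohort specification for synthetic dataset generation
#'
#' @param label Cohort name; one of `"young_unstressed"`, `"young_stressed"`,
#'   `"aged_unstressed"`, `"aged_stressed"`, or any custom label.
#' @param factors Named numeric of multiplicative parameter modifications
#'   applied to the reference set (all > 0). Empty = reference.
#' @param n_replicates Number of replicate worms emulated (>= 1).
#' @param noise_sd Gaussian replicate noise on the percent FRET scale.
#' @param seed Integer seed making the generated dataset reproducible.
#' @return Object of class `ash_cohort_spec`.
#' @export
cohort_spec <- function(label, factors = c(), n_replicates = 30,
                        noise_sd = 2, seed = 1) {
  factors <- unlist(factors)
  if (length(factors)) {
    bad <- setdiff(names(factors), free_param_names())
    if (length(bad)) stop("unknown parameter(s) in factors: ", paste(bad, collapse = ", "))
    if (any(factors <= 0)) stop("modification factors must be > 0")
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(label = label, factors = factors,
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ash_cohort_spec")
}

#' Built-in synthetic cohort presets
#'
#' Factor maps encoding the qualitative aging / oxidative-stress phenotypes
#' (stronger "on"/"off" peaks with age, altered IP3 turnover with stress) as
#' synthetic presets. These are illustrative defaults, not fitted values.
#'
#' @param seed Base seed; each cohort uses `seed + 0..3`.
#' @return Named list of four `ash_cohort_spec`s.
#' @export
cohort_presets <- function(seed = 1) {
  list(
    young_unstressed = cohort_spec("young_unstressed", c(), seed = seed),
    young_stressed = cohort_spec("young_stressed",
                                 c(k_p = 1.4, G_IPR = 1.3), seed = seed + 1),
    aged_unstressed = cohort_spec("aged_unstressed",
                                  c(G_TRPV = 1.25, G_IPR = 1.5), seed = seed + 2),
    aged_stressed = cohort_spec("aged_stressed",
                                c(G_TRPV = 1.3, G_IPR = 1.6, k_O = 1.5,
                                  k_O_minus = 1.5), seed = seed + 3)
  )
}

#' Apply a cohort's parameter modifications to a parameter record
#'
#' @param params `ash_params` (typically the reference set).
#' @param factors Named multiplicative factors on free parameters.
#' @return Recalibrated `ash_params`.
#' @export
modify_params <- function(params, factors) {
  factors <- unlist(factors)
  f <- params$free
  if (length(factors)) f[names(factors)] <- f[names(factors)] * factors
  calibrate_leaks(ash_params(free = f, fixed = params$fixed))
}

#' Generate a synthetic cohort FRET dataset
#'
#' Applies the cohort's modification map to the reference parameters,
#' recalibrates the leaks, simulates the protocol, and draws replicate traces
#' with i.i.d. Gaussian noise on the percent-FRET scale. Returns per-time
#' mean and standard deviation across replicates, the structure the
#' estimation stage consumes.
#'
#' @param spec An `ash_cohort_spec`.
#' @param protocol Stimulus protocol (default: 30 s square pulse at t = 10 s).
#' @param params Baseline parameters before modification (default reference).
#' @param t_end,output_dt Simulation horizon and data grid spacing (s).
#' @param cal FRET calibration.
#' @return Object of class `ash_dataset`: data.frame with columns `time`,
#'   `mean`, `sd`, `cohort`; attributes `n_replicates`, `seed`, `protocol`,
#'   `true_params`.
#' @export
generate_dataset <- function(spec, protocol = stim_square(10, 30, 1),
                             params = make_reference_params(),
                             t_end = 80, output_dt = 0.5,
                             cal = fret_calibration()) {
  pp <- modify_params(params, spec$factors)
  tr <- run_simulation(pp, protocol, t_end = t_end, output_dt = output_dt, cal = cal)
  if (isTRUE(attr(tr, "diverged"))) {
    stop("model diverged under modification factors: ",
         paste(sprintf("%s=%.3g", names(spec$factors), spec$factors), collapse = ", "))
  }
  set.seed(spec$seed)
  n <- spec$n_replicates
  reps <- matrix(rep(tr$FRET, n), ncol = n) +
    matrix(stats::rnorm(length(tr$FRET) * n, sd = spec$noise_sd), ncol = n)
  mu <- rowMeans(reps)
  sdv <- apply(reps, 1, stats::sd)
  if (n == 1) sdv <- rep(max(spec$noise_sd, 1e-6), length(mu))
  sdv <- pmax(sdv, 1e-6)  # Eq-25-style weighting requires sd > 0 everywhere
  structure(data.frame(time = tr$time, mean = mu, sd = sdv,
                       cohort = spec$label),
            class = c("ash_dataset", "data.frame"),
            n_replicates = n, seed = spec$seed, protocol = protocol,
            true_params = pp)
}

#' @export
print.ash_dataset <- function(x, ...) {
  cat(sprintf("Synthetic FRET dataset '%s': %d time points, %s replicates\n",
              x$cohort[1], nrow(x),
              if (is.null(attr(x, "n_replicates"))) "?" else attr(x, "n_replicates")))
  cat(sprintf("  peak mean FRET %.3g %%, median sd %.3g %%\n",
              max(x$mean), stats::median(x$sd)))
  invisible(x)
}

#' End-to-end parameter-recovery experiment
#'
#' Harness for validating the estimation pipeline on synthetic ground truth:
#' modifies the reference parameters by `truth_mods`, generates a synthetic
#' dataset from the modified model, runs [enumerate_plausible()] over the
#' given subset, and reports whether the true combination is flagged
#' plausible and how accurately its factors were recovered.
#'
#' @param truth_mods Named numeric of multiplicative changes applied to the
#'   reference (empty = no change).
#' @param fit_subset Selectable parameters handed to the enumeration
#'   (defaults to the names in `truth_mods`, plus enough companions to make
#'   the enumeration non-trivial).
#' @param seed Integer seed driving data generation and every fit.
#' @param max_size Largest combination size enumerated.
#' @param noise_sd Replicate noise sd (percent FRET).
#' @param n_replicates Synthetic replicate count.
#' @param protocol,cal,ga_control Passed through the pipeline.
#' @return List with `scan` (the `ash_plausible` table), `true_combo` (its
#'   canonical label), `true_plausible` (flag), `recovered_factors` (fitted
#'   multiplicative change of each truly modified parameter),
#'   `relative_error` (vs the true factors), and `best_combo`.
#' @export
recovery_experiment <- function(truth_mods = c(), fit_subset = NULL, seed = 1,
                                max_size = 2, noise_sd = 0.2,
                                n_replicates = 30,
                                protocol = stim_square(10, 30, 1),
                                cal = fret_calibration(),
                                ga_control = list(pop_size = 16, generations = 8)) {
  truth_mods <- unlist(truth_mods)
  ref <- make_reference_params()
  if (is.null(fit_subset)) {
    extra <- setdiff(c("G_IPR", "K_SERCA", "G_PMCA", "k_p"), names(truth_mods))
    fit_subset <- c(names(truth_mods),
                    extra[seq_len(max(0, 4 - length(truth_mods)))])
  }
  spec <- cohort_spec("synthetic_truth", truth_mods, n_replicates = n_replicates,
                      noise_sd = noise_sd, seed = seed)
  ds <- generate_dataset(spec, protocol = protocol, cal = cal)
  scan <- enumerate_plausible(ref, ds, selected = fit_subset,
                              max_size = max_size, cal = cal,
                              protocol = protocol, ga_control = ga_control,
                              seed = seed)
  true_combo <- paste(intersect(fit_subset, names(truth_mods)), collapse = "+")
  fits <- attr(scan, "fits")
  res <- list(scan = scan, true_combo = true_combo,
              best_combo = scan$combo[which.min(scan$rss)])
  if (nzchar(true_combo)) {
    idx <- match(true_combo, scan$combo)
    res$true_plausible <- isTRUE(scan$plausible[idx])
    fit <- fits[[idx]]
    rec <- fit$params$free[names(truth_mods)] / ref$free[names(truth_mods)]
    res$recovered_factors <- rec
    res$relative_error <- abs(rec - truth_mods) / truth_mods
  } else {
    res$true_plausible <- NA
    res$recovered_factors <- numeric(0)
    res$relative_error <- numeric(0)
  }
  res
}
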