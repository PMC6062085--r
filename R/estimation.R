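# Parameter estimation: weighted residuals against cohort FRET datasets,
# a real-coded genetic algorithm in log-parameter space (single- and
# multi-objective), Levenberg-Marquardt local refinement, covariance-based
# solution selection, plausible-combination enumeration, and the
# perturbation sensitivity scan.

#' Weighted residuals of the model against a FRET dataset
#'
#' `Res(t_i) = (FRET_model(t_i) - mean(t_i)) / sd(t_i)`, the per-time-point
#' standardized residual whose squared sum is the (negative log) Gaussian
#' likelihood up to a constant. The model trace is interpolated linearly onto
#' the data grid.
#'
#' @param params Calibrated `ash_params`.
#' @param dataset An `ash_dataset` (columns `time`, `mean`, `sd`).
#' @param cal A `fret_calibration`.
#' @param protocol Stimulus protocol used to record the dataset.
#' @param output_dt Simulation output spacing (s).
#' @return Numeric residual vector, one entry per data time point. Diverged
#'   simulations return a large finite penalty residual.
#' @export
fret_residuals <- function(params, dataset, cal = fret_calibration(),
                           protocol = stim_square(10, 30, 1),
                           output_dt = 0.5) {
  if (any(dataset$sd <= 0)) stop("dataset sd must be > 0 everywhere")
  tr <- run_simulation(params, protocol, t_end = max(dataset$time),
                       output_dt = output_dt, cal = cal)
  if (isTRUE(attr(tr, "diverged")) || max(tr$time) < max(dataset$time)) {
    return(rep(1e4, nrow(dataset)))
  }
  fm <- stats::approx(tr$time, tr$FRET, xout = dataset$time, rule = 2)$y
  (fm - dataset$mean) / dataset$sd
}

# Objective (residual sum of squares) for a free-parameter subvector given in
# log space. `base` supplies frozen parameters.
make_objective <- function(datasets, free, base, cal, protocol, output_dt = 0.5) {
  force(free)
  function(logtheta) {
    f <- base$free
    f[free] <- exp(logtheta)
    pp <- suppressWarnings(calibrate_leaks(ash_params(free = f, fixed = base$fixed)))
    vapply(datasets, function(d) {
      sum(fret_residuals(pp, d, cal = cal, protocol = protocol,
                         output_dt = output_dt)^2)
    }, numeric(1))
  }
}

# ---- real-coded GA in log space -------------------------------------------

# Simulated binary crossover (SBX) of two parents, eta_c distribution index.
sbx_crossover <- function(p1, p2, eta = 10) {
  u <- runif(length(p1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(c1, c2)
}

# Polynomial mutation within box bounds.
poly_mutation <- function(x, lower, upper, pm, eta = 15) {
  do <- runif(length(x)) < pm
  if (!any(do)) return(x)
  u <- runif(sum(do))
  delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  x[do] <- pmin(pmax(x[do] + delta * (upper[do] - lower[do]), lower[do]), upper[do])
  x
}

random_pop <- function(m, lower, upper) {
  n <- length(lower)
  pop <- matrix(0, m, n)
  for (i in seq_len(m)) pop[i, ] <- runif(n, lower, upper)
  pop
}

ga_defaults <- function() {
  list(pop_size = 48, generations = 40, p_crossover = 0.9, p_mutation = NULL,
       eta_c = 10, eta_m = 15, tournament = 2, log_halfwidth = log(10))
}

# Single-objective GA minimizing fn over log-parameters in a box around init.
run_ga <- function(fn, init_log, control = list(), init_pop = NULL) {
  ctl <- utils::modifyList(ga_defaults(), control)
  n <- length(init_log)
  pm <- if (is.null(ctl$p_mutation)) 1 / n else ctl$p_mutation
  lower <- init_log - ctl$log_halfwidth
  upper <- init_log + ctl$log_halfwidth
  pop <- if (is.null(init_pop)) {
    random_pop(ctl$pop_size, lower, upper)
  } else {
    init_pop[rep_len(seq_len(nrow(init_pop)), ctl$pop_size), , drop = FALSE]
  }
  pop[1, ] <- init_log  # keep the starting point in the population
  fit <- apply(pop, 1, fn)
  n_eval <- length(fit)
  for (g in seq_len(ctl$generations)) {
    kids <- matrix(0, ctl$pop_size, n)
    for (i in seq(1, ctl$pop_size, by = 2)) {
      pick <- function() {
        cand <- sample.int(ctl$pop_size, ctl$tournament)
        cand[which.min(fit[cand])]
      }
      a <- pop[pick(), ]; b <- pop[pick(), ]
      if (runif(1) < ctl$p_crossover) {
        cx <- sbx_crossover(a, b, ctl$eta_c)
        a <- cx[[1]]; b <- cx[[2]]
      }
      kids[i, ] <- poly_mutation(pmin(pmax(a, lower), upper), lower, upper, pm, ctl$eta_m)
      if (i + 1 <= ctl$pop_size) {
        kids[i + 1, ] <- poly_mutation(pmin(pmax(b, lower), upper), lower, upper, pm, ctl$eta_m)
      }
    }
    kfit <- apply(kids, 1, fn)
    n_eval <- n_eval + length(kfit)
    # (mu + lambda) survivor selection
    all_pop <- rbind(pop, kids)
    all_fit <- c(fit, kfit)
    keep <- order(all_fit)[seq_len(ctl$pop_size)]
    pop <- all_pop[keep, , drop = FALSE]
    fit <- all_fit[keep]
  }
  best <- which.min(fit)
  list(par = pop[best, ], value = fit[best], population = pop, fitness = fit,
       n_eval = n_eval)
}

# Fast non-dominated sort (returns front index per individual).
nds_fronts <- function(objs) {
  n <- nrow(objs)
  dominated_by <- integer(n)
  dominates <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(objs[i, ] <= objs[j, ]) && any(objs[i, ] < objs[j, ])) {
        dominates[[i]] <- c(dominates[[i]], j)
      } else if (all(objs[j, ] <= objs[i, ]) && any(objs[j, ] < objs[i, ])) {
        dominated_by[i] <- dominated_by[i] + 1L
      }
    }
  }
  front <- integer(n)
  cur <- which(dominated_by == 0L)
  f <- 1L
  while (length(cur)) {
    front[cur] <- f
    nxt <- integer(0)
    for (i in cur) {
      for (j in dominates[[i]]) {
        dominated_by[j] <- dominated_by[j] - 1L
        if (dominated_by[j] == 0L) nxt <- c(nxt, j)
      }
    }
    cur <- unique(nxt)
    f <- f + 1L
  }
  front
}

crowding_distance <- function(objs) {
  n <- nrow(objs)
  d <- numeric(n)
  for (m in seq_len(ncol(objs))) {
    o <- order(objs[, m])
    rng <- objs[o[n], m] - objs[o[1], m]
    d[o[c(1, n)]] <- Inf
    if (rng > 0 && n > 2) {
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (objs[o[3:n], m] - objs[o[1:(n - 2)], m]) / rng
    }
  }
  d
}

# NSGA-II style multi-objective GA; fn returns a vector of objectives.
run_nsga2 <- function(fn, init_log, control = list()) {
  ctl <- utils::modifyList(ga_defaults(), control)
  n <- length(init_log)
  pm <- if (is.null(ctl$p_mutation)) 1 / n else ctl$p_mutation
  lower <- init_log - ctl$log_halfwidth
  upper <- init_log + ctl$log_halfwidth
  pop <- random_pop(ctl$pop_size, lower, upper)
  pop[1, ] <- init_log
  objs <- t(apply(pop, 1, fn))
  for (g in seq_len(ctl$generations)) {
    front <- nds_fronts(objs)
    crowd <- crowding_distance(objs)
    pick <- function() {
      cand <- sample.int(nrow(pop), ctl$tournament)
      # binary tournament on (front, -crowding)
      best <- cand[order(front[cand], -crowd[cand])][1]
      best
    }
    kids <- matrix(0, ctl$pop_size, n)
    for (i in seq(1, ctl$pop_size, by = 2)) {
      a <- pop[pick(), ]; b <- pop[pick(), ]
      if (runif(1) < ctl$p_crossover) {
        cx <- sbx_crossover(a, b, ctl$eta_c)
        a <- cx[[1]]; b <- cx[[2]]
      }
      kids[i, ] <- poly_mutation(pmin(pmax(a, lower), upper), lower, upper, pm, ctl$eta_m)
      if (i + 1 <= ctl$pop_size) {
        kids[i + 1, ] <- poly_mutation(pmin(pmax(b, lower), upper), lower, upper, pm, ctl$eta_m)
      }
    }
    kobjs <- t(apply(kids, 1, fn))
    all_pop <- rbind(pop, kids)
    all_objs <- rbind(objs, kobjs)
    fr <- nds_fronts(all_objs)
    cd <- crowding_distance(all_objs)
    keep <- order(fr, -cd)[seq_len(ctl$pop_size)]
    pop <- all_pop[keep, , drop = FALSE]
    objs <- all_objs[keep, , drop = FALSE]
  }
  front <- nds_fronts(objs)
  list(population = pop, objectives = objs, front = front)
}

#' Multi-objective GA seeding across all cohorts
#'
#' Runs a non-dominated-sorting GA with one objective per dataset (the
#' residual sum of squares of each cohort) and selects, from the final
#' non-dominated set, the individual whose TOTAL residual over all cohorts is
#' smallest. The final population seeds the downstream single-cohort GA.
#'
#' @param datasets List of >= 2 `ash_dataset`s.
#' @param init Starting `ash_params` (box centre of the log-space search).
#' @param free Character vector of parameters to vary (default all 23).
#' @param cal,protocol As in [fret_residuals()].
#' @param control GA control overrides (`pop_size`, `generations`, ...).
#' @param seed Integer seed.
#' @return List with `population` (log-parameter matrix), `objectives`,
#'   `best_log` (chosen seed individual), `best_total` (its residual total).
#' @export
multiobjective_seed <- function(datasets, init = make_reference_params(),
                                free = free_param_names(),
                                cal = fret_calibration(),
                                protocol = stim_square(10, 30, 1),
                                control = list(), seed = 1) {
  if (length(datasets) < 2) stop("need at least two datasets")
  set.seed(seed)
  fn <- make_objective(datasets, free, init, cal, protocol)
  res <- run_nsga2(fn, log(init$free[free]), control)
  totals <- rowSums(res$objectives)
  nd <- which(res$front == 1)
  best <- nd[which.min(totals[nd])]
  list(population = res$population, objectives = res$objectives,
       best_log = res$population[best, ], best_total = totals[best])
}

# Forward-difference Jacobian of the residual vector wrt raw parameters.
residual_jacobian <- function(params, free, dataset, cal, protocol,
                              rel_step = 1e-4, output_dt = 0.5) {
  r0 <- fret_residuals(params, dataset, cal, protocol, output_dt)
  J <- matrix(0, length(r0), length(free), dimnames = list(NULL, free))
  for (k in seq_along(free)) {
    f <- params$free
    h <- max(abs(f[[free[k]]]) * rel_step, 1e-12)
    f[[free[k]]] <- f[[free[k]]] + h
    pp <- suppressWarnings(calibrate_leaks(ash_params(free = f, fixed = params$fixed)))
    J[, k] <- (fret_residuals(pp, dataset, cal, protocol, output_dt) - r0) / h
  }
  list(J = J, r = r0)
}

#' Hybrid GA + damped least-squares parameter fit
#'
#' The estimation procedure: a real-coded genetic algorithm (log-parameter
#' genome, so positivity is structural) globally minimizes the residual sum
#' of squares; its fittest individual seeds a Levenberg-Marquardt refinement
#' of the same weighted residual vector. Both stages minimize the identical
#' functional. The returned object carries the residual vector, the
#' finite-difference Jacobian at the optimum, and the covariance diagonal
#' `s^2 diag((J'J)^-1)`.
#'
#' @param dataset Target `ash_dataset` (or a list of one).
#' @param free Character vector of parameter names allowed to vary; the rest
#'   stay frozen at `init`. Empty vector returns `init` unchanged.
#' @param init Starting `ash_params`.
#' @param cal,protocol As in [fret_residuals()].
#' @param ga_control GA control overrides; `list(generations = 0)` skips the
#'   GA stage (pure local refinement).
#' @param init_pop Optional log-parameter matrix used as the GA's initial
#'   population (e.g. from [multiobjective_seed()]).
#' @param seed Integer seed.
#' @param output_dt Simulation spacing for the objective (s).
#' @return Object of class `ash_fit`: list with `params` (fitted, calibrated),
#'   `free`, `residuals`, `rss`, `cov_diag`, `jacobian`, `converged`,
#'   `n_eval`, `seed`.
#' @export
hybrid_fit <- function(dataset, free = selectable_param_names(),
                       init = make_reference_params(),
                       cal = fret_calibration(),
                       protocol = stim_square(10, 30, 1),
                       ga_control = list(), init_pop = NULL, seed = 1,
                       output_dt = 0.5) {
  if (inherits(dataset, "ash_dataset")) dataset <- list(dataset)
  if (!length(free)) {
    r <- fret_residuals(init, dataset[[1]], cal, protocol, output_dt)
    return(structure(list(params = init, free = character(0), residuals = r,
                          rss = sum(r^2), cov_diag = numeric(0),
                          jacobian = NULL, converged = TRUE, n_eval = 1,
                          seed = seed),
                     class = "ash_fit"))
  }
  bad <- setdiff(free, free_param_names())
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  fn1 <- function(lt) make_objective(dataset, free, init, cal, protocol, output_dt)(lt)[1]
  start_log <- log(init$free[free])
  ctl <- utils::modifyList(ga_defaults(), ga_control)
  if (ctl$generations > 0) {
    ga <- run_ga(fn1, start_log, ga_control, init_pop = init_pop)
    start_log <- ga$par
    n_eval <- ga$n_eval
  } else {
    n_eval <- 0
  }
  resfun <- function(lt) {
    f <- init$free
    f[free] <- exp(lt)
    pp <- suppressWarnings(calibrate_leaks(ash_params(free = f, fixed = init$fixed)))
    fret_residuals(pp, dataset[[1]], cal, protocol, output_dt)
  }
  lm <- minpack.lm::nls.lm(par = start_log, fn = resfun,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  n_eval <- n_eval + lm$niter
  f <- init$free
  f[free] <- exp(lm$par)
  fitted <- suppressWarnings(calibrate_leaks(ash_params(free = f, fixed = init$fixed)))
  jr <- residual_jacobian(fitted, free, dataset[[1]], cal, protocol,
                          output_dt = output_dt)
  r <- jr$r
  rss <- sum(r^2)
  cov_diag <- fit_covariance_diag(jr$J, rss)
  structure(list(params = fitted, free = free, residuals = r, rss = rss,
                 cov_diag = cov_diag, jacobian = jr$J,
                 converged = lm$info %in% 1:4, n_eval = n_eval, seed = seed),
            class = "ash_fit")
}

# Covariance diagonal s^2 diag((J'J)^-1); ridge-regularized fallback flagged
# by an attribute when J'J is numerically singular.
fit_covariance_diag <- function(J, rss) {
  p <- ncol(J)
  n <- nrow(J)
  s2 <- rss / max(n - p, 1)
  JtJ <- crossprod(J)
  ok <- TRUE
  inv <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv))) {
    ok <- FALSE
    inv <- solve(JtJ + diag(1e-8 * max(diag(JtJ), 1), p))
  }
  out <- s2 * diag(inv)
  names(out) <- colnames(J)
  attr(out, "regularized") <- !ok
  out
}

#' @export
print.ash_fit <- function(x, ...) {
  cat(sprintf("Hybrid GA + least-squares fit: %d free parameter(s), RSS = %.6g\n",
              length(x$free), x$rss))
  if (length(x$free)) {
    cat("  fitted:", paste(sprintf("%s=%.4g", x$free, x$params$free[x$free]),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.ash_fit <- function(object, ...) object$params$free

#' @export
residuals.ash_fit <- function(object, ...) object$residuals

#' @export
summary.ash_fit <- function(object, ...) {
  df <- data.frame(parameter = object$free,
                   estimate = unname(object$params$free[object$free]),
                   se = sqrt(pmax(unname(object$cov_diag), 0)))
  print(df, row.names = FALSE)
  invisible(df)
}

#' Select the fit with the smallest parameter variance
#'
#' Approximates each candidate's covariance as `s^2 (J'J)^-1` from its
#' least-squares Jacobian and returns the candidate whose covariance-diagonal
#' sum is smallest - the solution least sensitive to parameter perturbation.
#' Candidates with a numerically singular `J'J` are excluded (their
#' ridge-regularized diagnostic is reported in the `excluded` attribute).
#'
#' @param candidates List of `ash_fit` objects.
#' @return The selected `ash_fit`, with attribute `excluded` naming the
#'   indices dropped for rank deficiency.
#' @export
covariance_select <- function(candidates) {
  if (!length(candidates)) stop("no candidates")
  scores <- vapply(candidates, function(f) {
    if (isTRUE(attr(f$cov_diag, "regularized"))) return(Inf)
    sum(f$cov_diag)
  }, numeric(1))
  excluded <- which(!is.finite(scores))
  if (all(!is.finite(scores))) stop("all candidates are rank-deficient")
  out <- candidates[[which.min(scores)]]
  attr(out, "excluded") <- excluded
  out
}

#' Enumerate plausible parameter-change combinations
#'
#' For each combination of the selectable parameters (by default all subsets
#' of size <= `max_size` of the 13-parameter subset), re-fits only that
#' combination against the target cohort dataset while the remaining
#' parameters stay frozen at the reference values, pools all fitted
#' combinations, and applies the two plausibility criteria: (1) the
#' combination's residual is within the best `percentile` fraction of the
#' pool; (2) every re-fitted parameter moved, relative to the reference, by
#' more than its covariance-derived sensitivity (square root of the
#' reference fit's covariance diagonal). Combinations passing both are
#' flagged plausible.
#'
#' @param reference Reference `ash_params` (the cohort all changes are
#'   measured against), or an `ash_fit` whose parameters are used.
#' @param dataset Target cohort `ash_dataset`.
#' @param selected Character vector of selectable parameters.
#' @param max_size Largest combination size enumerated (the full sweep over
#'   all 2^13 - 1 subsets is supported by setting `max_size = 13`).
#' @param combos Optional explicit list of character vectors overriding the
#'   size-based enumeration.
#' @param budget Maximum number of combinations fitted; if exceeded, a
#'   seeded deterministic subsample is used (with a warning).
#' @param percentile Residual percentile kept by criterion 1 (default 0.01,
#'   i.e. the best 1 percent, ceiling-rounded so at least one survives).
#' @param cal,protocol,ga_control,seed,output_dt Passed to [hybrid_fit()].
#' @return Object of class `ash_plausible`: data.frame with one row per
#'   combination (`combo`, `size`, `rss`, `pass_percentile`,
#'   `pass_detect`, `plausible`) and attributes `fits` (the `ash_fit` list)
#'   and `sensitivity` (the per-parameter detection thresholds).
#' @export
enumerate_plausible <- function(reference, dataset,
                                selected = selectable_param_names(),
                                max_size = 2, combos = NULL, budget = Inf,
                                percentile = 0.01,
                                cal = fret_calibration(),
                                protocol = stim_square(10, 30, 1),
                                ga_control = list(pop_size = 16, generations = 8),
                                seed = 1, output_dt = 0.5) {
  if (inherits(reference, "ash_fit")) reference <- reference$params
  stopifnot_calibrated(reference)
  if (is.null(combos)) {
    combos <- list()
    for (k in seq_len(min(max_size, length(selected)))) {
      combos <- c(combos, utils::combn(selected, k, simplify = FALSE))
    }
  }
  if (length(combos) > budget) {
    warning(sprintf("budget %d < %d combinations: fitting a seeded subsample",
                    budget, length(combos)))
    set.seed(seed)
    combos <- combos[sort(sample.int(length(combos), budget))]
  }
  # reference-fit covariance over the selected subset -> detection thresholds
  ref_jr <- residual_jacobian(reference, selected, dataset, cal, protocol,
                              output_dt = output_dt)
  ref_cov <- fit_covariance_diag(ref_jr$J, sum(ref_jr$r^2))
  sens <- sqrt(pmax(ref_cov, 0))
  fits <- vector("list", length(combos))
  rss <- numeric(length(combos))
  pass_detect <- logical(length(combos))
  for (i in seq_along(combos)) {
    fits[[i]] <- hybrid_fit(dataset, free = combos[[i]], init = reference,
                            cal = cal, protocol = protocol,
                            ga_control = ga_control, seed = seed + i,
                            output_dt = output_dt)
    rss[i] <- fits[[i]]$rss
    delta <- abs(fits[[i]]$params$free[combos[[i]]] - reference$free[combos[[i]]])
    pass_detect[i] <- all(delta > sens[combos[[i]]])
  }
  keep_n <- max(1L, ceiling(percentile * length(rss)))
  pass_percentile <- rank(rss, ties.method = "first") <= keep_n
  out <- data.frame(
    combo = vapply(combos, paste, character(1), collapse = "+"),
    size = lengths(combos), rss = rss,
    pass_percentile = pass_percentile, pass_detect = pass_detect,
    plausible = pass_percentile & pass_detect)
  structure(out, class = c("ash_plausible", "data.frame"),
            fits = fits, sensitivity = sens, seed = seed)
}

#' @export
print.ash_plausible <- function(x, ...) {
  cat(sprintf("Plausible-combination scan: %d combinations, %d plausible\n",
              nrow(x), sum(x$plausible)))
  print.data.frame(head(x[order(x$rss), ], 10), row.names = FALSE)
  invisible(x)
}

#' Perturbation sensitivity scan of on/off peaks
#'
#' For each parameter set, draws `n_samples` uniform multiplicative
#' perturbations of all 23 free parameters in
#' `[1 - amplitude, 1 + amplitude]`, recalibrates the leaks, simulates the
#' standard stimulus protocol, and records the "on" and "off" peak FRET.
#' Diverged samples are kept in the output with their flag set and excluded
#' from downstream scatters.
#'
#' @param param_sets An `ash_params` or list of them (e.g. plausible fits).
#' @param n_samples Samples per set (default 100).
#' @param amplitude Relative perturbation half-width (default 0.25).
#' @param seed Integer seed.
#' @param protocol,t_end,cal Simulation settings; `stim_start`/`stim_end`
#'   are taken from the protocol span.
#' @return data.frame with columns `set`, `sample`, `on_max`, `off_max`,
#'   `diverged`.
#' @export
sensitivity_scan <- function(param_sets, n_samples = 100, amplitude = 0.25,
                             seed = 1, protocol = stim_square(10, 30, 1),
                             t_end = 80, cal = fret_calibration()) {
  if (inherits(param_sets, "ash_params")) param_sets <- list(param_sets)
  if (amplitude < 0 || amplitude >= 1) stop("amplitude must be in [0, 1)")
  if (n_samples < 1) stop("n_samples must be >= 1")
  set.seed(seed)
  stim_start <- protocol$start[1]
  stim_end <- max(protocol$end)
  rows <- list()
  for (s in seq_along(param_sets)) {
    base <- param_sets[[s]]
    for (i in seq_len(n_samples)) {
      fac <- runif(length(base$free), 1 - amplitude, 1 + amplitude)
      f <- base$free * fac
      pp <- suppressWarnings(calibrate_leaks(ash_params(free = f, fixed = base$fixed)))
      tr <- run_simulation(pp, protocol, t_end = t_end, cal = cal)
      div <- isTRUE(attr(tr, "diverged"))
      if (!div && max(tr$time) >= stim_end + 20) {
        fe <- extract_features(tr, stim_start, stim_end)
        rows[[length(rows) + 1]] <- data.frame(set = s, sample = i,
                                               on_max = fe$on_max,
                                               off_max = fe$off_max,
                                               diverged = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(set = s, sample = i,
                                               on_max = NA_real_,
                                               off_max = NA_real_,
                                               diverged = TRUE)
      }
    }
  }
  do.call(rbind, rows)
}
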