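# Flux kernels against hand evaluation, published limits, and random-point
# transcription oracles.

test_that("Hill-squared pump flux has the stated limits and shape", {
  expect_equal(hill2_pump_flux(0, 2, 0.1), 0)
  expect_equal(hill2_pump_flux(sqrt(0.1), 7, 0.1), 7 / 2)
  expect_equal(hill2_pump_flux(1e9, 2, 0.1), 2, tolerance = 1e-12)
  cs <- seq(0, 5, by = 0.1)
  expect_true(all(diff(hill2_pump_flux(cs, 2, 0.3)) > 0))
  expect_true(all(hill2_pump_flux(cs, 2, 0.3) < 2))
  expect_error(hill2_pump_flux(1, 2, -1), "K must be > 0")
})

test_that("TRPV flux vanishes for closed gate or zero gradient", {
  p <- ref_params
  expect_equal(trpv_flux(0, 1, 0.1, p), 0)
  expect_equal(trpv_flux(1, 1, p$fixed[["c_ES"]], p), 0)
  p2 <- set_params(p, G_TRPV = 0.001)
  expect_equal(trpv_flux(1, 1, 0.1, p2), 0.001 * (2000 - 0.1))
})

test_that("IPR open probability matches the reduced De Young-Keizer form", {
  p <- ref_params
  K1 <- p$fixed[["K1"]]; K5 <- p$fixed[["K5"]]
  expect_equal(ipr_open_probability(0, 1, 0, p), 0)
  expect_equal(ipr_open_probability(K1, K5, 0, p), (1 / 4)^3)
  expect_equal(ipr_open_probability(1e7, 1e7, 0, p), 1, tolerance = 1e-5)
  expect_true(all(ipr_open_probability(runif(20, 0, 5), runif(20, 0, 5),
                                       runif(20), p) <= 1))
})

test_that("IPR inactivation rates reduce correctly at the boundaries", {
  p <- ref_params
  expect_equal(ipr_inactivation_rates(0, 0, p)$phi1, 0)
  expect_equal(ipr_inactivation_rates(0, 1, p)$phi2, p$fixed[["k4_minus"]])
  # frozen direct-substitution value at p = K3, c = 1 uM with the original
  # De Young-Keizer constants (a2 = a4 = 0.2 /uM/s makes phi1 = 0.2 c exactly)
  r <- ipr_inactivation_rates(0.9434, 1, p)
  expect_equal(r$phi1, 0.2, tolerance = 1e-12)
  expect_equal(r$phi2, (0.2098 * 0.9434 + 0.0289 * 0.9434) / (0.9434 + 0.9434),
               tolerance = 1e-10)
  # rest-state consistency: y* = phi1/(phi1+phi2) at p = 0 equals c/(c+K4)
  c0 <- 0.1
  r0 <- ipr_inactivation_rates(0, c0, p)
  expect_equal(r0$phi1 / (r0$phi1 + r0$phi2),
               c0 / (c0 + p$fixed[["K4"]]), tolerance = 1e-12)
})

test_that("IPR flux follows the ER-to-cytosol gradient", {
  p <- set_params(ref_params, G_IPR = 0.5)
  expect_equal(ipr_flux(0.1, 10, 0, p), 0)
  expect_equal(ipr_flux(5, 5, 1, p), 0)
  expect_equal(ipr_flux(0.1, 10, 1, p), 4.95)
  expect_gt(ipr_flux(0.1, 10, 0.5, p), 0)
})

test_that("L-type activation reproduces the published rate limits", {
  # alpha(5) = 1.6/2; beta's removable singularity at V = 1.31
  a <- function(V) 1.6 / (1 + exp(-0.072 * (V - 5)))
  b <- function(V) 0.02 * (V - 1.31) / (exp((V - 1.31) / 5.36) - 1)
  expect_equal(a(5), 0.8)
  expect_equal(vgcc_activation(5), a(5) / (a(5) + b(5)), tolerance = 1e-9)
  expect_equal(vgcc_activation(5), 0.9148076, tolerance = 1e-6)
  # at the singular point beta -> 0.02 * 5.36 = 0.1072
  expect_equal(vgcc_activation(1.31), a(1.31) / (a(1.31) + 0.1072),
               tolerance = 1e-7)
  V <- seq(-90, 60, by = 0.5)
  m <- vgcc_activation(V)
  expect_true(all(m > 0 & m < 1))
  expect_true(all(diff(m) > 0))
})

test_that("GHK flux is influx-positive at rest, zero at reversal, continuous at V = 0", {
  p <- set_params(ref_params, G_VGCC = 1)
  rtzf <- p$fixed[["RT_zF"]]
  # frozen direct evaluation at V = -70 mV, c = 0.1 uM
  expect_equal(vgcc_flux(-70, 0.1, p), 3.5403475, tolerance = 1e-6)
  expect_gt(vgcc_flux(-70, 0.1, p), 0)
  # reversal: c = c_ES * exp(-zFV/RT)
  V <- 10
  c_rev <- p$fixed[["c_ES"]] * exp(-V / rtzf)
  expect_equal(vgcc_flux(V, c_rev, p), 0, tolerance = 1e-9)
  # series limit at V -> 0 equals G m(0)^2 (RT/zF)(c_ES - c)
  lim <- vgcc_activation(0)^2 * rtzf * (2000 - 0.1)
  expect_equal(vgcc_flux(1e-6, 0.1, p), lim, tolerance = 1e-6)
  expect_equal(vgcc_flux(-1e-6, 0.1, p), lim, tolerance = 1e-6)
  expect_equal(vgcc_flux(1e-6, 0.1, p) / vgcc_flux(-1e-6, 0.1, p), 1,
               tolerance = 1e-6)
})

test_that("cascade derivatives have the stated fixed points", {
  p <- ref_params
  f <- p$free
  rest <- c(P0 = 0, P1 = 0, P2 = 0, O = 0, I = 1)
  expect_equal(unname(cascade_rhs(rest, 0, p)), rep(0, 5))
  # P0 saturation steady state at S -> Inf
  P0_star <- f[["k_P0"]] / f[["k_P0_minus"]]
  st <- c(P0 = P0_star, P1 = 0, P2 = 0, O = 0, I = 1)
  expect_equal(cascade_rhs(st, 1e12, p)[["P0"]], 0, tolerance = 1e-6)
  # O equilibrium at constant P1
  P1 <- 0.7
  O_star <- f[["k_O"]] * P1 / (f[["k_O"]] * P1 + f[["k_O_minus"]])
  st2 <- c(P0 = 0, P1 = P1, P2 = 0, O = O_star, I = 1)
  expect_equal(cascade_rhs(st2, 0, p)[["O"]], 0, tolerance = 1e-12)
})

test_that("IP3 production/decay matches the incoherent feed-forward form", {
  p <- ref_params
  f <- p$free
  expect_equal(ip3_rhs(0, 0.3, 1, 2, p), -2 * f[["k_p_minus"]])
  expect_equal(ip3_rhs(1, 0.5, 0, 0, p), 0)
  # (K_p P2) = 1 halves production; c >> K_c saturates the Hill term
  expect_equal(ip3_rhs(1, 1 / f[["K_p"]], 1e6, 0, p), f[["k_p"]] / 2,
               tolerance = 1e-9)
})

test_that("graded-voltage rates hit their removable-singularity limits", {
  p <- ref_params
  # alpha' -> 1 as its argument -> 0 (c = 4/26), beta' -> 20 at c = 1/13
  Vm <- p$fixed[["V_max"]]; Vr <- p$fixed[["V_rest"]]
  expect_equal(voltage_rhs(4 / 26, 0, p),
               1 * (Vm - 0) - (260 * 4 / 26 - 20) / (exp(13 * 4 / 26 - 1) - 1) * (0 - Vr),
               tolerance = 1e-7)
  b_at <- function(c) (260 * c - 20) / (exp(13 * c - 1) - 1)
  a_at <- function(c) (-26 * c + 4) / (exp(-26 * c + 4) - 1)
  expect_equal(voltage_rhs(1 / 13, -30, p),
               a_at(1 / 13) * (Vm + 30) - 20 * (-30 - Vr), tolerance = 1e-7)
  # equilibrium: V* = (a Vmax + b Vrest)/(a + b)
  c <- 0.37
  Vstar <- (a_at(c) * Vm + b_at(c) * Vr) / (a_at(c) + b_at(c))
  expect_equal(voltage_rhs(c, Vstar, p), 0, tolerance = 1e-9)
})

test_that("all flux kernels agree with literal formula transcription at random points", {
  set.seed(42)
  p <- ref_params
  fx <- p$fixed
  for (i in 1:20) {
    G <- runif(1, 0.1, 5); K <- runif(1, 0.05, 1); c <- runif(1, 0, 2)
    expect_equal(hill2_pump_flux(c, G, K), G * c^2 / (c^2 + K), tolerance = 1e-12)
    O <- runif(1); I <- runif(1)
    expect_equal(trpv_flux(O, I, c, p),
                 p$free[["G_TRPV"]] * O * I * (fx[["c_ES"]] - c), tolerance = 1e-12)
    pp <- runif(1, 0, 3); y <- runif(1)
    expect_equal(ipr_open_probability(pp, c, y, p),
                 (pp * c * (1 - y) / ((pp + fx[["K1"]]) * (c + fx[["K5"]])))^3,
                 tolerance = 1e-12)
    r <- ipr_inactivation_rates(pp, c, p)
    expect_equal(r$phi1,
                 c * (fx[["k4_minus"]] * fx[["K1"]] * fx[["K2"]] +
                        fx[["k2_minus"]] * fx[["K4"]] * pp) /
                   (fx[["K4"]] * fx[["K2"]] * (fx[["K1"]] + pp)), tolerance = 1e-12)
    expect_equal(r$phi2,
                 (fx[["k2_minus"]] * pp + fx[["k4_minus"]] * fx[["K3"]]) /
                   (fx[["K3"]] + pp), tolerance = 1e-12)
    cER <- runif(1, 0, 20)
    expect_equal(ipr_flux(c, cER, 0.3, p),
                 p$free[["G_IPR"]] * 0.3 * (cER - c), tolerance = 1e-12)
    V <- runif(1, -80, 30)
    x <- V / fx[["RT_zF"]]
    expect_equal(vgcc_flux(V, c, p),
                 p$free[["G_VGCC"]] * vgcc_activation(V)^2 * V *
                   (fx[["c_ES"]] * exp(-x) - c) / (1 - exp(-x)), tolerance = 1e-9)
  }
})
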