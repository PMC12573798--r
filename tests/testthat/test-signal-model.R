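# Closed-form two-mode signal model and the arithmetic conversions.

test_that("heterodyne intensity has the right endpoints and early-time law", {
  p <- signal_params_q(1e-3, 0.1, 0.5)
  expect_identical(heterodyne_intensity(0, p), 0)
  # steady state 1 - A0
  expect_equal(heterodyne_intensity(100 * p$tau, p), 1 - p$A0,
               tolerance = 1e-6)
  # early-time slope equals 1/tau_th within 1%
  t1 <- p$tau_th / 100
  h <- t1 / 100
  slope <- (heterodyne_intensity(t1 + h, p) -
            heterodyne_intensity(t1 - h, p)) / (2 * h)
  expect_equal(slope, 1 / p$tau_th, tolerance = 0.01)
})

test_that("closed forms agree with an independent high-accuracy ODE solver", {
  skip_if_not_installed("deSolve")
  p <- signal_params_q(1e-3, 0.1, 0.8)
  tt <- seq(0, 0.5, by = 1e-3)
  sol <- deSolve::ode(
    y = c(theta = 0, g = 0), times = tt,
    func = function(t, y, parms)
      list(c((1 - y[1]) / p$tau_th, (y[1] - y[2]) / p$tau)),
    parms = NULL, method = "lsoda", rtol = 1e-12, atol = 1e-12)
  zeta_ode <- sol[, "theta"] - p$A0 * sol[, "g"]
  expect_lt(max(abs(heterodyne_intensity(tt, p) - zeta_ode)), 1e-8)
  # spec-level spot value at t = 0.05 s
  expect_equal(heterodyne_intensity(0.05, p),
               zeta_ode[which(tt == 0.05)], tolerance = 1e-6)

  # off phase: source-free decay from (theta0, g0) = (1, 1)
  sol_off <- deSolve::ode(
    y = c(theta = 1, g = 1), times = tt,
    func = function(t, y, parms)
      list(c(-y[1] / p$tau_th, (y[1] - y[2]) / p$tau)),
    parms = NULL, method = "lsoda", rtol = 1e-12, atol = 1e-12)
  zeta_off_ode <- sol_off[, "theta"] - p$A0 * sol_off[, "g"]
  expect_lt(max(abs(heterodyne_intensity_off(tt, p) - zeta_off_ode)), 1e-8)
})

test_that("off-phase intensity starts at 1 - A0 and decays to zero", {
  p <- signal_params_q(1e-3, 0.1, 0.5)
  expect_equal(heterodyne_intensity_off(0, p), 0.5)
  expect_equal(heterodyne_intensity_off(100 * p$tau, p), 0, tolerance = 1e-12)
})

test_that("equal relaxation times are handled continuously by the limit branch", {
  tau <- 0.02
  tgrid <- seq(0, 0.2, length.out = 300)
  p_lim <- signal_params_q(tau, tau, 0.7)               # limit branch
  p_near <- signal_params_q(tau, tau * (1 + 1e-10), 0.7) # inside threshold
  expect_lt(max(abs(heterodyne_intensity(tgrid, p_lim) -
                    heterodyne_intensity(tgrid, p_near))), 1e-8)
  # generic branch just outside the threshold agrees too
  p_gen <- signal_params_q(tau, tau * (1 + 1e-7), 0.7)
  expect_lt(max(abs(heterodyne_intensity(tgrid, p_gen) -
                    heterodyne_intensity(tgrid, p_lim))), 5e-7)
  expect_lt(max(abs(heterodyne_intensity_off(tgrid, p_gen) -
                    heterodyne_intensity_off(tgrid, p_lim))), 5e-7)
})

test_that("signal stays within the monotone steady-state bounds", {
  set.seed(4)
  for (k in 1:20) {
    A0 <- stats::runif(1, -1, 1)
    p <- signal_params_q(1e-3, 10^stats::runif(1, -2, 0), A0)
    tgrid <- 10^seq(-5, 1.5, length.out = 400)
    z <- heterodyne_intensity(tgrid, p)
    expect_true(all(z >= min(0, 1 - A0) - 1e-9))
    expect_true(all(z <= max(1, 1 - A0) + 1e-9))
  }
})

test_that("amplitude <-> Soret conversion inverts and carries the right sign", {
  ctr <- std_contrast()
  expect_identical(amplitude_to_soret(0, ctr, 0.007), 0)
  set.seed(11)
  for (k in 1:100) {
    A0 <- stats::runif(1, -1, 1)
    cw <- stats::runif(1, 1e-4, 0.5)
    ctr_k <- contrast_factors(stats::runif(1, -2e-4, -1e-5),
                              stats::runif(1, 0.05, 0.3))
    round_trip <- soret_to_amplitude(amplitude_to_soret(A0, ctr_k, cw),
                                     ctr_k, cw)
    expect_equal(round_trip, A0, tolerance = 1e-12)
  }
  # negative A0, negative dn_dT, positive dn_dc => thermophobic (S_T > 0)
  expect_gt(amplitude_to_soret(-0.01,
                               contrast_factors(-1.0e-4, 0.15), 0.007), 0)
})

test_that("relaxation-diffusivity relation is exact and self-inverse", {
  g <- grating_geometry(q = 1e6)
  expect_equal(relaxation_to_diffusivity(1, g), 1e-12)
  expect_equal(relaxation_to_diffusivity(1e-3, g), 1e-9)
  D <- 7.3e-11
  expect_equal(relaxation_to_diffusivity(1 / (D * g$q^2), g), D,
               tolerance = 1e-12)
  # q from fringe spacing
  g2 <- grating_geometry(fringe_spacing = 2 * pi / 1e6)
  expect_equal(g2$q, 1e6)
})

test_that("steady-state Soret gradient follows the zero-flux balance", {
  expect_identical(soret_steady_state_gradient(0, 0.007, 1e4), 0)
  expect_identical(soret_steady_state_gradient(0.01, 0.007, 0), 0)
  expect_equal(soret_steady_state_gradient(0.01, 0.007, 1e4),
               -0.01 * 0.007 * 0.993 * 1e4)
})

test_that("D_T = S_T * D and the ratio round-trips", {
  expect_identical(thermal_diffusion_coefficient(0, 1e-10), 0)
  expect_equal(thermal_diffusion_coefficient(0.02, 1e-10), 2e-12)
  D_T <- thermal_diffusion_coefficient(0.037, 8e-11)
  expect_equal(D_T / 8e-11, 0.037, tolerance = 1e-12)
  tc <- transport_coefficients(D = 1e-10, D_th = 1.4e-7, S_T = 0.02)
  expect_equal(tc$D_T, 2e-12)
})

test_that("constructors validate their domains", {
  expect_error(signal_params(-1, 1, 0), "tau_th")
  expect_error(signal_params(1e-3, 0.1, NaN), "finite")
  expect_warning(signal_params(1e-3, 5e-3, 0.1), "poorly separated")
  expect_error(grating_geometry(), "exactly one")
  expect_error(grating_geometry(q = 1e6, fringe_spacing = 1e-5), "exactly one")
  expect_error(contrast_factors(-1e-4, 0), "nonzero")
  expect_error(sample_state(c = 1.2), "strictly in")
  expect_error(heterodyne_intensity(-1, signal_params_q(1e-3, 0.1, 0.5)),
               ">= 0")
  expect_error(heterodyne_intensity(NA_real_, signal_params_q(1e-3, 0.1, 0.5)),
               "finite")
  expect_error(amplitude_to_soret(0.1, std_contrast(), 1), "strictly in")
  expect_error(transport_coefficients(D = 1e-10, D_th = 1.4e-7,
                                      S_T = 0.02, D_T = 3e-12), "disagree")
})
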