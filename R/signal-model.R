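# Closed-form physics of the transient-grating heterodyne experiment.
#
# A holographic temperature grating (wavevector q) relaxes with the thermal
# time tau_th = 1/(D_th q^2); the Soret-driven concentration grating follows
# with the mass time tau = 1/(D q^2).  The normalized heterodyne intensity of
# the readout beam is the difference of the two modes,
#   zeta(t) = theta(t) - A0 * g(t),
# where theta is the (unit-plateau) thermal mode, g the concentration mode
# response, and A0 the steady-state concentration amplitude.

# relative |tau - tau_th| threshold below which the analytic equal-time limit
# is used; the generic closed form contains a 1/(tau - tau_th) factor
.TAU_COINCIDENCE_TOL <- 1e-9

#' Lumped relaxation parameters of one grating experiment
#'
#' Bundles the thermal relaxation time, the mass (concentration) relaxation
#' time and the steady-state concentration amplitude that determine a
#' two-mode heterodyne signal.
#'
#' @param tau_th Thermal relaxation time (s), `> 0`.
#' @param tau Mass relaxation time (s), `> 0`.
#' @param A0 Steady-state concentration amplitude (dimensionless). May be
#'   negative (thermophilic solute, or sign flip through the optical contrast
#'   factors); no sign restriction is imposed.
#'
#' @details A warning (not an error) is issued when `tau / tau_th < 10`:
#'   the separation of the thermal and concentration time scales is then
#'   degraded and the two modes become hard to distinguish in a fit.
#'
#' @return An object of class `"signal_params"`: a list with elements
#'   `tau_th`, `tau`, `A0`.
#' @examples
#' signal_params(tau_th = 1e-3, tau = 0.1, A0 = 0.5)
#' @export
signal_params <- function(tau_th, tau, A0) {
  stopifnot(is.numeric(tau_th), length(tau_th) == 1L,
            is.numeric(tau), length(tau) == 1L,
            is.numeric(A0), length(A0) == 1L)
  if (!all(is.finite(c(tau_th, tau, A0))))
    stop("signal_params: tau_th, tau and A0 must all be finite")
  if (tau_th <= 0) stop("signal_params: tau_th must be > 0")
  if (tau <= 0) stop("signal_params: tau must be > 0")
  if (tau / tau_th < 10)
    warning("signal_params: tau/tau_th < 10; thermal and concentration ",
            "time scales are poorly separated", call. = FALSE)
  structure(list(tau_th = tau_th, tau = tau, A0 = A0),
            class = "signal_params")
}

#' @export
print.signal_params <- function(x, ...) {
  cat(sprintf("Grating signal parameters: tau_th = %g s, tau = %g s, A0 = %g\n",
              x$tau_th, x$tau, x$A0))
  invisible(x)
}

#' Grating geometry
#'
#' Holds the grating (scattering) vector magnitude. Exactly one of `q` or
#' `fringe_spacing` must be given; the other is derived via
#' `q = 2 * pi / fringe_spacing`.
#'
#' @param q Grating vector magnitude (1/m), `> 0`.
#' @param fringe_spacing Fringe spacing Lambda (m), `> 0`.
#' @return An object of class `"grating_geometry"` with elements `q` and
#'   `fringe_spacing`.
#' @examples
#' grating_geometry(fringe_spacing = 1e-5)
#' @export
grating_geometry <- function(q = NULL, fringe_spacing = NULL) {
  if (is.null(q) == is.null(fringe_spacing))
    stop("grating_geometry: give exactly one of q or fringe_spacing")
  if (is.null(q)) {
    stopifnot(is.numeric(fringe_spacing), length(fringe_spacing) == 1L)
    if (!is.finite(fringe_spacing) || fringe_spacing <= 0)
      stop("grating_geometry: fringe_spacing must be finite and > 0")
    q <- 2 * pi / fringe_spacing
  } else {
    stopifnot(is.numeric(q), length(q) == 1L)
    if (!is.finite(q) || q <= 0)
      stop("grating_geometry: q must be finite and > 0")
    fringe_spacing <- 2 * pi / q
  }
  structure(list(q = q, fringe_spacing = fringe_spacing),
            class = "grating_geometry")
}

#' Optical contrast factors
#'
#' Refractive-index increments converting the concentration amplitude of the
#' index grating into a Soret coefficient. Both are measured independently of
#' the TDFRS experiment (interferometry / refractometry).
#'
#' @param dn_dT Derivative of refractive index with temperature at constant
#'   composition and pressure (1/K); negative for aqueous systems.
#' @param dn_dc Derivative of refractive index with solute weight fraction at
#'   constant temperature and pressure (dimensionless); must be nonzero.
#' @return An object of class `"contrast_factors"`.
#' @examples
#' contrast_factors(dn_dT = -1.1e-4, dn_dc = 0.183)
#' @export
contrast_factors <- function(dn_dT, dn_dc) {
  stopifnot(is.numeric(dn_dT), length(dn_dT) == 1L,
            is.numeric(dn_dc), length(dn_dc) == 1L)
  if (!all(is.finite(c(dn_dT, dn_dc))))
    stop("contrast_factors: dn_dT and dn_dc must be finite")
  if (dn_dc == 0) stop("contrast_factors: dn_dc must be nonzero")
  structure(list(dn_dT = dn_dT, dn_dc = dn_dc), class = "contrast_factors")
}

#' Thermodynamic state of one sample
#'
#' @param c Solute weight fraction, strictly inside (0, 1).
#' @param temperature Temperature (degrees C).
#' @param pH Solution pH.
#' @param buffer_label Free-text buffer identifier (e.g. `"NaP"`, `"none"`).
#' @param rho Mass density (kg/m^3), optional; it cancels in the steady-state
#'   gradient and is only used when evaluating mass fluxes.
#' @return An object of class `"sample_state"`.
#' @export
sample_state <- function(c, temperature = NA_real_, pH = NA_real_,
                         buffer_label = "none", rho = NULL) {
  stopifnot(is.numeric(c), length(c) == 1L)
  if (!is.finite(c) || c <= 0 || c >= 1)
    stop("sample_state: weight fraction c must lie strictly in (0, 1)")
  if (!is.null(rho)) {
    stopifnot(is.numeric(rho), length(rho) == 1L)
    if (!is.finite(rho) || rho <= 0) stop("sample_state: rho must be > 0")
  }
  structure(list(c = c, temperature = temperature, pH = pH,
                 buffer_label = buffer_label, rho = rho),
            class = "sample_state")
}

#' Transport coefficients at one state point
#'
#' @param D Mass diffusion coefficient (m^2/s), `> 0`.
#' @param D_th Thermal diffusivity (m^2/s), `> 0`.
#' @param S_T Soret coefficient (1/K); `S_T = D_T / D`.
#' @param D_T Thermal diffusion coefficient (m^2/(s K)). Derived as
#'   `S_T * D` when omitted; when both `D_T` and `S_T` are given they must be
#'   consistent to 1e-12 relative.
#' @return An object of class `"transport_coefficients"`.
#' @examples
#' transport_coefficients(D = 1e-10, D_th = 1.4e-7, S_T = 0.02)
#' @export
transport_coefficients <- function(D, D_th, S_T, D_T = NULL) {
  stopifnot(is.numeric(D), is.numeric(D_th), is.numeric(S_T))
  if (!is.finite(D) || D <= 0) stop("transport_coefficients: D must be > 0")
  if (!is.finite(D_th) || D_th <= 0)
    stop("transport_coefficients: D_th must be > 0")
  if (is.null(D_T)) {
    D_T <- S_T * D
  } else if (abs(S_T - D_T / D) > 1e-12 * abs(S_T)) {
    stop("transport_coefficients: S_T and D_T/D disagree beyond 1e-12 relative")
  }
  structure(list(D = D, D_th = D_th, D_T = D_T, S_T = S_T),
            class = "transport_coefficients")
}

#' @export
print.transport_coefficients <- function(x, ...) {
  cat(sprintf(
    "Transport coefficients:\n  D    = %.4g m^2/s\n  D_th = %.4g m^2/s\n  D_T  = %.4g m^2/(s K)\n  S_T  = %.4g 1/K\n",
    x$D, x$D_th, x$D_T, x$S_T))
  invisible(x)
}

# concentration-mode response g(t) during excitation (source on, g(0)=0);
# separate so the fit and the intensity share one implementation
.conc_mode_on <- function(t, tau_th, tau) {
  if (abs(tau - tau_th) < .TAU_COINCIDENCE_TOL * tau_th) {
    e <- exp(-t / tau)
    1 - e - (t / tau) * e
  } else {
    1 + (tau_th * exp(-t / tau_th) - tau * exp(-t / tau)) / (tau - tau_th)
  }
}

#' Normalized heterodyne intensity during excitation
#'
#' Closed-form two-mode response of the readout beam while the optical
#' grating is being written: a fast thermal rise `1 - exp(-t/tau_th)` minus
#' the growing concentration mode scaled by the steady-state amplitude `A0`,
#' so that `zeta(0) = 0` and `zeta(Inf) = 1 - A0`.
#'
#' When `tau` and `tau_th` coincide to within 1e-9 relative, the analytic
#' equal-time limit
#' `zeta = 1 - exp(-t/tau) - A0 * (1 - exp(-t/tau) - (t/tau) exp(-t/tau))`
#' is used instead of the generic expression (which divides by
#' `tau - tau_th`).
#'
#' @param t Time since excitation on (s), vectorized, `>= 0`.
#' @param params A [signal_params()] object.
#' @return Dimensionless intensity, same length as `t`.
#' @examples
#' p <- signal_params(1e-3, 0.1, 0.5)
#' heterodyne_intensity(c(0, 1e-3, 10), p)
#' @export
heterodyne_intensity <- function(t, params) {
  stopifnot(inherits(params, "signal_params"), is.numeric(t))
  if (!all(is.finite(t))) stop("heterodyne_intensity: t must be finite")
  if (any(t < 0)) stop("heterodyne_intensity: t must be >= 0")
  tau_th <- params$tau_th; tau <- params$tau
  if (abs(tau - tau_th) < .TAU_COINCIDENCE_TOL * tau_th) {
    theta <- 1 - exp(-t / tau)
  } else {
    theta <- 1 - exp(-t / tau_th)
  }
  theta - params$A0 * .conc_mode_on(t, tau_th, tau)
}

#' Normalized heterodyne intensity after excitation switch-off
#'
#' Source-free decay of the two-mode system from the state reached at the
#' moment the writing beams are switched off: the thermal mode decays as
#' `theta0 * exp(-t/tau_th)` and drives the concentration mode through
#' `dg/dt = (theta - g)/tau`, giving a sum of two exponentials.
#'
#' @param t_off Time since switch-off (s), vectorized, `>= 0`.
#' @param params A [signal_params()] object.
#' @param state_at_off Numeric length-2 vector `c(theta0, g0)`: the thermal
#'   and concentration mode values at switch-off. After a long excitation
#'   phase both approach 1 (the default).
#' @return Dimensionless intensity `theta(t) - A0 * g(t)`.
#' @examples
#' p <- signal_params(1e-3, 0.1, 0.5)
#' heterodyne_intensity_off(0, p)          # 1 - A0 at switch-off
#' @export
heterodyne_intensity_off <- function(t_off, params, state_at_off = c(1, 1)) {
  stopifnot(inherits(params, "signal_params"), is.numeric(t_off),
            is.numeric(state_at_off), length(state_at_off) == 2L)
  if (!all(is.finite(t_off)) || !all(is.finite(state_at_off)))
    stop("heterodyne_intensity_off: inputs must be finite")
  if (any(t_off < 0)) stop("heterodyne_intensity_off: t_off must be >= 0")
  theta0 <- state_at_off[[1]]; g0 <- state_at_off[[2]]
  if (theta0 < 0 || theta0 > 1)
    stop("heterodyne_intensity_off: theta0 must lie in [0, 1]")
  tau_th <- params$tau_th; tau <- params$tau
  if (abs(tau - tau_th) < .TAU_COINCIDENCE_TOL * tau_th) {
    e <- exp(-t_off / tau)
    theta <- theta0 * e
    g <- g0 * e + theta0 * (t_off / tau) * e
  } else {
    theta <- theta0 * exp(-t_off / tau_th)
    g <- g0 * exp(-t_off / tau) +
      theta0 * tau_th / (tau - tau_th) *
        (exp(-t_off / tau) - exp(-t_off / tau_th))
  }
  theta - params$A0 * g
}

#' Convert a steady-state amplitude to a Soret coefficient
#'
#' Inverts the optical-contrast relation
#' `A0 = (dn/dc) / (dn/dT) * S_T * c * (1 - c)`:
#' `S_T = A0 * dn_dT / (dn_dc * c * (1 - c))`.
#'
#' @param A0 Steady-state concentration amplitude (dimensionless).
#' @param contrast A [contrast_factors()] object.
#' @param c Solute weight fraction, strictly in (0, 1).
#' @return Soret coefficient `S_T` (1/K).
#' @seealso [soret_to_amplitude()] for the forward direction.
#' @export
amplitude_to_soret <- function(A0, contrast, c) {
  stopifnot(inherits(contrast, "contrast_factors"), is.numeric(A0),
            is.numeric(c), length(c) == 1L)
  if (!is.finite(c) || c <= 0 || c >= 1)
    stop("amplitude_to_soret: c must lie strictly in (0, 1)")
  A0 * contrast$dn_dT / (contrast$dn_dc * c * (1 - c))
}

#' Convert a Soret coefficient to a steady-state amplitude
#'
#' @inheritParams amplitude_to_soret
#' @param S_T Soret coefficient (1/K).
#' @return Steady-state amplitude `A0` (dimensionless).
#' @export
soret_to_amplitude <- function(S_T, contrast, c) {
  stopifnot(inherits(contrast, "contrast_factors"), is.numeric(S_T),
            is.numeric(c), length(c) == 1L)
  if (!is.finite(c) || c <= 0 || c >= 1)
    stop("soret_to_amplitude: c must lie strictly in (0, 1)")
  S_T * contrast$dn_dc * c * (1 - c) / contrast$dn_dT
}

#' Relaxation time to diffusivity (and back)
#'
#' In a single-Fourier-mode grating the relaxation rate of each mode is
#' `1/tau = D q^2`: applied to the thermal time this yields the thermal
#' diffusivity `D_th`, applied to the mass time the diffusion coefficient
#' `D`. The relation is its own inverse.
#'
#' @param tau_x Relaxation time (s), `> 0`.
#' @param geometry A [grating_geometry()] object.
#' @return Diffusivity `1 / (tau_x * q^2)` (m^2/s).
#' @export
relaxation_to_diffusivity <- function(tau_x, geometry) {
  stopifnot(inherits(geometry, "grating_geometry"), is.numeric(tau_x))
  if (any(!is.finite(tau_x)) || any(tau_x <= 0))
    stop("relaxation_to_diffusivity: tau_x must be finite and > 0")
  1 / (tau_x * geometry$q^2)
}

#' Steady-state Soret concentration gradient
#'
#' Setting the mass flux to zero in the thermodiffusion flux law gives the
#' stationary concentration gradient sustained by a temperature gradient:
#' `grad_c = -S_T * c * (1 - c) * grad_T`. For `S_T > 0` the solute is
#' depleted on the warm side (thermophobic).
#'
#' @param S_T Soret coefficient (1/K).
#' @param c Solute weight fraction.
#' @param grad_T Temperature gradient (K/m).
#' @return Concentration (weight-fraction) gradient (1/m).
#' @export
soret_steady_state_gradient <- function(S_T, c, grad_T) {
  stopifnot(is.numeric(S_T), is.numeric(c), is.numeric(grad_T))
  -S_T * c * (1 - c) * grad_T
}

#' Thermal diffusion coefficient from S_T and D
#'
#' `D_T = S_T * D`; the Soret coefficient is the ratio `D_T / D`.
#'
#' @param S_T Soret coefficient (1/K).
#' @param D Mass diffusion coefficient (m^2/s).
#' @return Thermal diffusion coefficient (m^2/(s K)).
#' @export
thermal_diffusion_coefficient <- function(S_T, D) {
  stopifnot(is.numeric(S_T), is.numeric(D))
  S_T * D
}
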