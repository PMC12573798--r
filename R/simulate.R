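# Seeded synthetic-data generators: two-mode grating dynamics by fixed-step
# RK4 integration (the numerical oracle for the closed forms), Soret point
# sets from the empirical temperature law, and condition sets with a linear
# Delta S_T - helicity relation.

# evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards so generators are reproducible and side-effect-free
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration for synthetic heterodyne experiments
#'
#' @param params A [signal_params()] object: the true (tau_th, tau, A0).
#' @param t_on Duration of the excitation (grating-writing) phase (s).
#' @param t_off Duration of the relaxation phase after switch-off (s).
#' @param dt Sampling interval of the recorded trace (s); must not exceed
#'   `tau_th / 10` so the thermal rise is resolved.
#' @param noise_sd Additive Gaussian noise per sample per shot
#'   (dimensionless), `>= 0`.
#' @param n_shots Number of shots, `>= 1`.
#' @param seed Integer seed; all randomness of the simulation flows from it.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(params, t_on = 1, t_off = 1, dt = 1e-4,
                              noise_sd = 0.01, n_shots = 3000, seed = 0L) {
  stopifnot(inherits(params, "signal_params"))
  if (dt <= 0 || t_on <= 0 || t_off <= 0)
    stop("simulation_config: dt, t_on and t_off must be > 0")
  if (dt > params$tau_th / 10)
    stop("simulation_config: sampling dt must be <= tau_th / 10 to resolve ",
         "the thermal rise (dt = ", format(dt), ", tau_th = ",
         format(params$tau_th), ")")
  if (noise_sd < 0) stop("simulation_config: noise_sd must be >= 0")
  if (n_shots < 1) stop("simulation_config: n_shots must be >= 1")
  structure(list(params = params, t_on = t_on, t_off = t_off, dt = dt,
                 noise_sd = noise_sd, n_shots = as.integer(n_shots),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Fixed-step RK4 integration of the two-mode grating system
#'
#' Integrates the driven two-mode system
#' `dtheta/dt = (s(t) - theta) / tau_th`, `dg/dt = (theta - g) / tau`,
#' with unit source `s = 1` during the excitation phase and `s = 0` after
#' switch-off, recording `zeta = theta - A0 * g` on the sampling grid.
#' Classical Runge-Kutta 4 with a fixed step no larger than `tau_th / 50`
#' (an integer divisor of `dt`), chosen for bit-reproducible trajectories.
#'
#' This integrator is deliberately independent of the closed-form
#' expressions in [heterodyne_intensity()]; it serves as the numerical
#' oracle against which the closed forms are validated.
#'
#' @param params A [signal_params()] object.
#' @param t_on,t_off Phase durations (s); `t_off = 0` simulates only the
#'   excitation phase.
#' @param dt Recording interval (s).
#' @return A list with `times` (from 0 to `t_on + t_off` inclusive, step
#'   `dt`), `zeta`, `theta`, `g`, and `state_at_off` (`c(theta, g)` at the
#'   switch-off instant).
#' @export
two_mode_response <- function(params, t_on, t_off = 0, dt) {
  stopifnot(inherits(params, "signal_params"))
  tau_th <- params$tau_th; tau <- params$tau; A0 <- params$A0
  # the source switches on the recording grid: snap the requested durations
  # to whole samples and report the actual switch-off time
  n_rec_on <- max(1L, round(t_on / dt))
  n_rec_off <- round(t_off / dt)
  # substeps: RK4 step <= tau_th / 50 and an integer divisor of dt
  m <- max(1L, as.integer(ceiling(dt / (tau_th / 50))))
  h <- dt / m
  n_rec <- n_rec_on + n_rec_off
  theta_rec <- numeric(n_rec + 1L)
  g_rec <- numeric(n_rec + 1L)
  theta <- 0; g <- 0
  state_at_off <- c(0, 0)
  deriv <- function(th, gg, s) c((s - th) / tau_th, (th - gg) / tau)
  for (i in seq_len(n_rec)) {
    s <- if (i <= n_rec_on) 1 else 0
    for (j in seq_len(m)) {
      k1 <- deriv(theta, g, s)
      k2 <- deriv(theta + h / 2 * k1[1], g + h / 2 * k1[2], s)
      k3 <- deriv(theta + h / 2 * k2[1], g + h / 2 * k2[2], s)
      k4 <- deriv(theta + h * k3[1], g + h * k3[2], s)
      theta <- theta + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      g <- g + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    }
    theta_rec[i + 1L] <- theta
    g_rec[i + 1L] <- g
    if (i == n_rec_on) state_at_off <- c(theta, g)
  }
  times <- dt * (0:n_rec)
  list(times = times, zeta = theta_rec - A0 * g_rec,
       theta = theta_rec, g = g_rec, state_at_off = state_at_off,
       t_on = n_rec_on * dt)
}

#' Simulate a set of heterodyne shots
#'
#' Integrates the two-mode system once ([two_mode_response()]) and adds
#' i.i.d. Gaussian noise per sample to each shot. Deterministic for a fixed
#' seed.
#'
#' @param config A [simulation_config()].
#' @return List of `n_shots` [heterodyne_trace()] objects on a common time
#'   grid; each carries `t_excitation_off_s` and the true parameters in its
#'   metadata.
#' @export
simulate_shot_set <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  base <- two_mode_response(config$params, config$t_on, config$t_off,
                            config$dt)
  meta <- list(t_excitation_off_s = base$t_on,
               true_params = config$params, noise_sd = config$noise_sd)
  .with_seed(config$seed, {
    lapply(seq_len(config$n_shots), function(k) {
      noise <- if (config$noise_sd > 0)
        stats::rnorm(length(base$times), 0, config$noise_sd) else 0
      heterodyne_trace(base$times, base$zeta + noise, meta = meta)
    })
  })
}

#' Simulate a shot-averaged heterodyne trace
#'
#' Draws the average of `n_shots` noisy shots directly from the exact
#' sampling distribution of the shot mean and its standard error, without
#' materializing the individual shots: the mean at each sample is
#' `zeta + Normal(0, noise_sd / sqrt(n))` and the per-point standard error
#' is `noise_sd * sqrt(chi2_{n-1} / (n - 1)) / sqrt(n)` (0 when
#' `n_shots = 1` or `noise_sd = 0`). Statistically identical to
#' `average_shots(simulate_shot_set(config))`, at a fraction of the memory
#' and time for 3000-shot studies.
#'
#' @param config A [simulation_config()].
#' @return A [heterodyne_trace()] with `per_point_sd` set.
#' @export
simulate_averaged_trace <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  base <- two_mode_response(config$params, config$t_on, config$t_off,
                            config$dt)
  n <- config$n_shots
  npt <- length(base$times)
  meta <- list(t_excitation_off_s = base$t_on,
               true_params = config$params, noise_sd = config$noise_sd,
               n_shots = n)
  .with_seed(config$seed, {
    if (config$noise_sd == 0) {
      vals <- base$zeta
      sem <- rep(0, npt)
    } else {
      vals <- base$zeta + stats::rnorm(npt, 0, config$noise_sd / sqrt(n))
      sem <- if (n == 1L) rep(0, npt) else
        config$noise_sd * sqrt(stats::rchisq(npt, n - 1) / (n - 1)) / sqrt(n)
    }
    heterodyne_trace(base$times, vals, per_point_sd = sem, meta = meta)
  })
}

#' Generate a synthetic Soret temperature dataset
#'
#' Samples the empirical S_T temperature law on a temperature grid
#' (default: 15 to 45 degrees C in steps of 5, the measured range) and adds
#' Gaussian noise.
#'
#' @param true_params A [soret_params()] object. The default
#'   (`S_T_inf = 0.025` 1/K, `A = -0.132` 1/K, `T0 = 12` degC) describes a
#'   protein-like aqueous solute: Soret coefficients of order 1e-2 1/K,
#'   thermophilic below the sign-change temperature T* ~ 20 degC and
#'   thermophobic above it, with a clear bend inside the measured window.
#' @param temperatures Temperature grid (degrees C).
#' @param noise_sd Gaussian noise on S_T (1/K), `>= 0`.
#' @param seed Integer seed.
#' @return Data frame with columns `temperature`, `S_T`, `sigma_S_T`
#'   (constant `noise_sd`, omitted as a weight source when 0).
#' @export
generate_soret_dataset <- function(true_params = soret_params(0.025, -0.132, 12),
                                   temperatures = seq(15, 45, 5),
                                   noise_sd = 0.001, seed = 0L) {
  stopifnot(inherits(true_params, "soret_params"), noise_sd >= 0)
  mu <- soret_model(temperatures, true_params)
  .with_seed(seed, {
    y <- mu + if (noise_sd > 0) stats::rnorm(length(mu), 0, noise_sd) else 0
    data.frame(temperature = temperatures, S_T = y,
               sigma_S_T = if (noise_sd > 0) noise_sd else NA_real_)
  })
}

#' Configuration for synthetic condition sets
#'
#' Emulates a series of protein folding states: alpha-helical contents with
#' measurement scatter and a linear dependence of Delta S_T on helicity.
#' The default helix values (51, 50, 43, 34, 33, 4 percent) mirror the
#' folded (pH 6, with/without phosphate), molten-globule (pH 4,
#' with/without acetate) and acid-unfolded (pH 2) states; the default slope
#' and intercept place Delta S_T in the few-1e-2 1/K range typical of
#' protein Soret coefficients.
#'
#' @param slope Delta S_T change per percent helix (1/K per %).
#' @param intercept Delta S_T at zero helicity (1/K).
#' @param helix_pct True helix contents (%).
#' @param labels Condition labels, same length as `helix_pct`.
#' @param pH,buffer_label,buffer_conc_mM Per-condition annotations.
#' @param helix_sd Gaussian sd of the reported helix content (%).
#' @param delta_sd Gaussian sd of Delta S_T (1/K).
#' @param seed Integer seed.
#' @return An object of class `"condition_generator_config"`.
#' @export
condition_generator_config <- function(
    slope = 4e-4, intercept = 2e-3,
    helix_pct = c(51, 50, 43, 34, 33, 4),
    labels = c("pH 6", "pH 6 NaP 20mM", "pH 4", "pH 4 NaAc 20mM",
               "pH 4 NaAc 10mM", "pH 2"),
    pH = c(6, 6, 4, 4, 4, 2),
    buffer_label = c("none", "NaP", "none", "NaAc", "NaAc", "none"),
    buffer_conc_mM = c(0, 20, 0, 20, 10, 0),
    helix_sd = c(1.6, 0.5, 2.1, 3.2, 2.2, 0.3),
    delta_sd = 1e-3, seed = 0L) {
  n <- length(helix_pct)
  stopifnot(length(labels) == n, length(pH) == n,
            length(buffer_label) == n, length(buffer_conc_mM) == n)
  if (length(helix_sd) == 1L) helix_sd <- rep(helix_sd, n)
  if (length(delta_sd) == 1L) delta_sd <- rep(delta_sd, n)
  stopifnot(length(helix_sd) == n, length(delta_sd) == n)
  if (any(helix_sd < 0) || any(delta_sd < 0))
    stop("condition_generator_config: sds must be >= 0")
  structure(list(slope = slope, intercept = intercept,
                 helix_pct = helix_pct, labels = labels, pH = pH,
                 buffer_label = buffer_label,
                 buffer_conc_mM = buffer_conc_mM, helix_sd = helix_sd,
                 delta_sd = delta_sd, seed = as.integer(seed)),
            class = "condition_generator_config")
}

#' Generate a synthetic condition set
#'
#' Draws per-condition records with `delta_ST = slope * helix + intercept +
#' noise` and helix contents jittered by their reported sd, labelled by a
#' pH/buffer scheme mirroring the measured folding states.
#'
#' @param config A [condition_generator_config()].
#' @return Conditions data frame (columns `label`, `pH`, `buffer_label`,
#'   `buffer_conc_mM`, `helix_pct`, `helix_sd`, `delta_ST`, `delta_ST_sd`)
#'   suitable for [correlate_conditions()].
#' @export
generate_condition_set <- function(config = condition_generator_config()) {
  stopifnot(inherits(config, "condition_generator_config"))
  n <- length(config$helix_pct)
  .with_seed(config$seed, {
    helix_obs <- config$helix_pct +
      stats::rnorm(n, 0, 1) * config$helix_sd
    helix_obs <- pmin(pmax(helix_obs, 0), 100)
    delta <- config$slope * config$helix_pct + config$intercept +
      stats::rnorm(n, 0, 1) * config$delta_sd
    data.frame(label = config$labels, pH = config$pH,
               buffer_label = config$buffer_label,
               buffer_conc_mM = config$buffer_conc_mM,
               helix_pct = helix_obs, helix_sd = config$helix_sd,
               delta_ST = delta, delta_ST_sd = config$delta_sd)
  })
}
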