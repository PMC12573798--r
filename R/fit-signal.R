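# Nonlinear least-squares extraction of (tau_th, tau, A0) from heterodyne
# traces, and conversion of a fit into transport coefficients.

# covariance from a (possibly ill-conditioned) least-squares Jacobian.
# Columns are rescaled to comparable magnitude and the information matrix
# inverted through its SVD with singular values floored at 1e-10 of the
# largest: directions the data do not constrain (e.g. the mass time when
# A0 ~ 0) then carry a very large -- not a spuriously small -- variance.
.ls_covariance <- function(J, w, res, weighted, par) {
  n <- nrow(J); npar <- ncol(J)
  d <- pmax(abs(par), 1e-8 * max(abs(par), 1))
  Js <- sweep(J, 2, d, `*`)
  if (weighted) Js <- Js * w
  sv <- svd(Js, nu = 0)
  if (!all(is.finite(sv$d)) || max(sv$d) == 0)
    return(matrix(NA_real_, npar, npar))
  s_floor <- pmax(sv$d, max(sv$d) * 1e-10)
  v <- sv$v %*% (t(sv$v) / s_floor^2)
  if (!weighted) v <- v * sum(res^2) / max(n - npar, 1)
  v * tcrossprod(d)
}

# numeric central-difference Jacobian of the phase model wrt natural params
.signal_jacobian <- function(times, par, phase) {
  model <- function(p) {
    sp <- signal_params_quiet(p[1], p[2], p[3])
    if (phase == "on") heterodyne_intensity(times, sp)
    else heterodyne_intensity_off(times, sp)
  }
  J <- matrix(0, length(times), 3L)
  for (k in 1:3) {
    h <- max(abs(par[k]), 1e-12) * 1e-6
    pp <- par; pm <- par
    pp[k] <- pp[k] + h; pm[k] <- pm[k] - h
    J[, k] <- (model(pp) - model(pm)) / (2 * h)
  }
  J
}

# Robust starting point: coarse log-grid over (tau_th, tau) with A0
# profiled out by a linear solve (the model is linear in A0 at fixed
# relaxation times). Guards against mode-swapped local minima that the
# crossing heuristics can seed, especially for negative A0.
.grid_start <- function(tt, v, phase, dt, span, heuristic) {
  theta_fn <- function(tau_th) {
    if (phase == "on") 1 - exp(-tt / tau_th) else exp(-tt / tau_th)
  }
  conc_fn <- function(tau_th, tau) {
    if (phase == "on") .conc_mode_on(tt, tau_th, tau)
    else {
      if (abs(tau - tau_th) < .TAU_COINCIDENCE_TOL * tau_th) {
        e <- exp(-tt / tau)
        e + (tt / tau) * e
      } else {
        exp(-tt / tau) + tau_th / (tau - tau_th) *
          (exp(-tt / tau) - exp(-tt / tau_th))
      }
    }
  }
  eval_rss <- function(tau_th, tau) {
    th <- theta_fn(tau_th)
    g <- conc_fn(tau_th, tau)
    denom <- sum(g * g)
    A0 <- if (denom > 0) sum(g * (th - v)) / denom else 0
    A0 <- min(max(A0, -2), 2)
    list(rss = sum((th - A0 * g - v)^2), A0 = A0)
  }
  cand <- list()
  for (tau_th in exp(seq(log(max(2 * dt, span / 3000)), log(span / 20),
                         length.out = 8))) {
    for (ratio in c(5, 20, 100, 500, 2500)) {
      tau <- min(ratio * tau_th, 100 * span)
      cand[[length(cand) + 1L]] <- c(tau_th, tau)
    }
  }
  if (is.finite(heuristic$tau_th) && is.finite(heuristic$tau))
    cand[[length(cand) + 1L]] <- c(heuristic$tau_th, heuristic$tau)
  best <- NULL; best_rss <- Inf
  for (p in cand) {
    r <- eval_rss(p[1], p[2])
    if (r$rss < best_rss) {
      best_rss <- r$rss
      best <- list(tau_th = p[1], tau = p[2], A0 = r$A0)
    }
  }
  best
}

# off-phase starting values; assumes decay from the steady state 1 - A0
.off_phase_start <- function(times, values) {
  n <- length(times)
  span <- times[n] - times[1]
  A00 <- 1 - values[1]
  # after the fast thermal decay the signal sits near -A0 and relaxes slowly
  target_fast <- exp(-1) - A00
  idx <- which(values <= target_fast)
  tau_th0 <- if (length(idx)) max(times[idx[1]], span / 1e4) else span / 100
  tau0 <- span / 3
  if (abs(A00) > 1e-12) {
    late <- times > 10 * tau_th0
    idx2 <- which(late & abs(values) <= abs(A00) * exp(-1))
    if (length(idx2)) tau0 <- max(times[idx2[1]], 2 * tau_th0)
  }
  list(tau_th = tau_th0, tau = max(tau0, 1.5 * tau_th0), A0 = A00)
}

#' Fit the two-mode signal model to a heterodyne trace
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt,
#' [minpack.lm::nls.lm()]) of the closed-form two-mode heterodyne model to a
#' normalized trace. The on-phase model is [heterodyne_intensity()]; the
#' off-phase model is [heterodyne_intensity_off()] from the steady state
#' (`theta0 = g0 = 1`), appropriate when the excitation was held for several
#' mass relaxation times.
#'
#' Weights are `1 / per_point_sd^2` when the trace carries strictly positive
#' per-point standard deviations (the parameter covariance is then absolute,
#' suitable for confidence intervals); otherwise ordinary least squares with
#' the residual variance estimating the noise.
#'
#' The search is bounded: `tau_th` in `[dt, span]`, `tau` in
#' `[tau_th, 1e8 * tau_th]` (via a log-ratio parameterization that enforces
#' `tau >= tau_th`), `A0` in `[-2, 2]`. Starting values come from the
#' `1 - 1/e` crossing of the initial rise (first crossing on ties), the
#' plateau departure for `A0`, and the `1/e` relaxation of the late slow
#' component for `tau`.
#'
#' @param trace A [heterodyne_trace()], normalized to unit thermal plateau;
#'   at least 30 samples.
#' @param phase `"on"` or `"off"`; which phase model to fit.
#' @return An object of class `"tdfrs_fit"` with components `params`
#'   ([signal_params()]), `covariance` (3x3, order `tau_th, tau, A0`),
#'   `residual_rms`, `phase`, `converged` (logical; non-convergence is
#'   flagged, never silent), `data`, `fitted`.
#' @seealso [derive_transport()], [normalize_trace()], [split_phases()]
#' @export
fit_signal <- function(trace, phase = c("on", "off")) {
  stopifnot(inherits(trace, "heterodyne_trace"))
  phase <- match.arg(phase)
  tt <- trace$times
  if (phase == "off") tt <- tt - tt[1]
  v <- trace$values
  n <- length(tt)
  if (n < 30L)
    stop("fit_signal: need at least 30 samples, got ", n)
  dt <- min(diff(tt))
  span <- tt[n] - tt[1]

  st <- if (phase == "on") .on_phase_start(tt, v) else .off_phase_start(tt, v)
  st <- .grid_start(tt, v, phase, dt, span, st)
  if (span < 3 * st$tau)
    warning("fit_signal: time span < 3 * initial tau estimate; ",
            "the slow mode may be poorly constrained", call. = FALSE)

  w <- NULL
  weighted <- !is.null(trace$per_point_sd) && all(trace$per_point_sd > 0)
  if (weighted) w <- 1 / trace$per_point_sd

  model <- function(sp) {
    if (phase == "on") heterodyne_intensity(tt, sp)
    else heterodyne_intensity_off(tt, sp)
  }
  resid_fn <- function(p) {
    sp <- signal_params_quiet(exp(p[1]), exp(p[2]), p[3])
    r <- model(sp) - v
    if (weighted) r * w else r
  }
  tau_th0 <- min(max(st$tau_th, dt), span)
  start <- c(log(tau_th0),
             log(min(max(st$tau, 1.5 * tau_th0), 100 * span)),
             min(max(st$A0, -2), 2))
  lm_fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    lower = c(log(dt), log(dt), -2),
    upper = c(log(span), log(100 * span), 2),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  converged <- lm_fit$info %in% c(1L, 2L, 3L)
  par_nat <- c(tau_th = exp(lm_fit$par[1]),
               tau = exp(lm_fit$par[2]),
               A0 = lm_fit$par[3])
  sp_hat <- signal_params_quiet(par_nat[[1]], par_nat[[2]], par_nat[[3]])
  fitted <- model(sp_hat)
  res <- v - fitted
  rms <- sqrt(mean(res^2))

  J <- .signal_jacobian(tt, par_nat, phase)
  covariance <- matrix(NA_real_, 3, 3)
  cov_try <- tryCatch(.ls_covariance(J, w, res, weighted, par_nat),
                      error = function(e) NULL)
  if (!is.null(cov_try)) covariance <- cov_try
  dimnames(covariance) <- list(names(par_nat), names(par_nat))

  if (!converged)
    warning("fit_signal: Levenberg-Marquardt did not converge (info = ",
            lm_fit$info, "); fit flagged with converged = FALSE",
            call. = FALSE)

  structure(list(params = sp_hat, covariance = covariance,
                 residual_rms = rms, phase = phase, converged = converged,
                 data = trace, times_fit = tt, fitted = fitted,
                 weighted = weighted, nobs = n, deviance = lm_fit$deviance),
            class = "tdfrs_fit")
}

#' @export
coef.tdfrs_fit <- function(object, ...) {
  c(tau_th = object$params$tau_th, tau = object$params$tau,
    A0 = object$params$A0)
}

#' @export
vcov.tdfrs_fit <- function(object, ...) object$covariance

#' @export
residuals.tdfrs_fit <- function(object, ...) {
  object$data$values - object$fitted
}

#' @export
fitted.tdfrs_fit <- function(object, ...) object$fitted

#' @export
nobs.tdfrs_fit <- function(object, ...) object$nobs

#' @rdname fit_signal
#' @param object,x A `"tdfrs_fit"` object.
#' @param times Times (s) at which to evaluate the fitted model; defaults to
#'   the times of the fitted trace.
#' @param ... Unused.
#' @export
predict.tdfrs_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$times_fit
  if (object$phase == "on") heterodyne_intensity(times, object$params)
  else heterodyne_intensity_off(times, object$params)
}

#' @export
print.tdfrs_fit <- function(x, ...) {
  cat(sprintf("Two-mode heterodyne signal fit (%s phase)\n", x$phase))
  est <- coef(x)
  se <- sqrt(diag(x$covariance))
  for (k in seq_along(est))
    cat(sprintf("  %-6s = %.6g (se %.2g)\n", names(est)[k], est[k], se[k]))
  cat(sprintf("  residual rms = %.3g over %d points; converged: %s\n",
              x$residual_rms, x$nobs, x$converged))
  invisible(x)
}

#' @export
summary.tdfrs_fit <- function(object, ...) {
  est <- coef(object)
  se <- sqrt(diag(object$covariance))
  tab <- cbind(Estimate = est, `Std. Error` = se)
  out <- list(phase = object$phase, coefficients = tab,
              residual_rms = object$residual_rms,
              converged = object$converged, nobs = object$nobs,
              weighted = object$weighted)
  class(out) <- "summary.tdfrs_fit"
  out
}

#' @export
print.summary.tdfrs_fit <- function(x, ...) {
  cat(sprintf("Two-mode heterodyne signal fit (%s phase, %s least squares)\n",
              x$phase, if (x$weighted) "weighted" else "ordinary"))
  print(x$coefficients)
  cat(sprintf("residual rms %.3g on %d points; converged: %s\n",
              x$residual_rms, x$nobs, x$converged))
  invisible(x)
}

#' @export
plot.tdfrs_fit <- function(x, ...) {
  graphics::plot(x$times_fit, x$data$values, pch = ".", col = "grey40",
                 xlab = "time (s)", ylab = "heterodyne intensity", ...)
  graphics::lines(x$times_fit, x$fitted, col = "red3", lwd = 1.5)
  graphics::legend("bottomright", legend = c("data", "fit"),
                   col = c("grey40", "red3"), lty = c(NA, 1),
                   pch = c(20, NA), bty = "n")
  invisible(x)
}

#' Transport coefficients from a signal fit
#'
#' Converts fitted relaxation parameters into transport coefficients:
#' `D_th = 1/(tau_th q^2)`, `D = 1/(tau q^2)`,
#' `S_T` from the steady-state amplitude via [amplitude_to_soret()], and
#' `D_T = S_T * D`.
#'
#' @param fit A `"tdfrs_fit"` from [fit_signal()].
#' @param geometry A [grating_geometry()]; taken from the trace metadata
#'   when omitted.
#' @param contrast A [contrast_factors()]; taken from the trace metadata
#'   when omitted.
#' @param c Solute weight fraction; taken from the trace metadata when
#'   omitted.
#' @return A [transport_coefficients()] object.
#' @export
derive_transport <- function(fit, geometry = NULL, contrast = NULL, c = NULL) {
  stopifnot(inherits(fit, "tdfrs_fit"))
  meta <- fit$data$meta
  if (is.null(geometry)) geometry <- meta$geometry
  if (is.null(contrast)) contrast <- meta$contrast
  if (is.null(c)) c <- meta$c
  if (is.null(geometry) || is.null(contrast) || is.null(c))
    stop("derive_transport: geometry, contrast and c must be supplied or ",
         "present in the trace metadata")
  est <- coef(fit)
  D_th <- relaxation_to_diffusivity(est[["tau_th"]], geometry)
  D <- relaxation_to_diffusivity(est[["tau"]], geometry)
  S_T <- amplitude_to_soret(est[["A0"]], contrast, c)
  transport_coefficients(D = D, D_th = D_th, S_T = S_T)
}

#' Pool repeated estimates
#'
#' Mean and standard error of the mean over repeated per-measurement values
#' (e.g. S_T from on- and off-phase fits of repeated experiments at one
#' temperature). The standard error is `sd / sqrt(n)`, and 0 when `n = 1`.
#'
#' @param values Numeric vector of per-measurement values, `n >= 1`.
#' @return An object of class `"pooled_estimate"`: list with `mean`, `sem`,
#'   `n`.
#' @export
pool_estimates <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (!all(is.finite(values))) stop("pool_estimates: values must be finite")
  n <- length(values)
  sem <- if (n == 1L) 0 else stats::sd(values) / sqrt(n)
  structure(list(mean = mean(values), sem = sem, n = n),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate: %.6g +/- %.2g (sem, n = %d)\n",
              x$mean, x$sem, x$n))
  invisible(x)
}
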