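# Empirical temperature law for the Soret coefficient:
#   S_T(T) = S_T_inf + A * exp(-T / T0)
# with the sign-change temperature T* = T0 * log(-A / S_T_inf) (when the
# ratio is positive), and the temperature-sensitivity statistic
#   Delta S_T = S_T(T_high) - S_T(T_low).
# Temperatures are in degrees Celsius throughout (so T0 and T* are also in
# degrees C); the law is reparameterization-equivalent under a unit change.

#' Parameters of the empirical S_T temperature law
#'
#' @param S_T_inf Asymptotic Soret coefficient at high temperature (1/K).
#' @param A Amplitude of the exponential term (1/K); measures the
#'   temperature sensitivity of S_T. Equal to `-S_T_inf * exp(T_star / T0)`
#'   when a sign change exists.
#' @param T0 Bending scale of the curve (degrees C), `> 0`.
#' @return An object of class `"soret_params"` with elements `S_T_inf`,
#'   `A`, `T0` and the derived `T_star` (sign-change temperature, degrees C;
#'   `NA` when `-A / S_T_inf <= 0`, i.e. no sign change).
#' @examples
#' soret_params(S_T_inf = 0.02, A = -0.05, T0 = 30)
#' @export
soret_params <- function(S_T_inf, A, T0) {
  stopifnot(is.numeric(S_T_inf), is.numeric(A), is.numeric(T0))
  if (!all(is.finite(c(S_T_inf, A, T0))))
    stop("soret_params: parameters must be finite")
  if (T0 <= 0) stop("soret_params: T0 must be > 0")
  obj <- structure(list(S_T_inf = S_T_inf, A = A, T0 = T0,
                        T_star = NA_real_),
                   class = "soret_params")
  obj$T_star <- sign_change_temperature(obj)
  obj
}

#' @export
print.soret_params <- function(x, ...) {
  cat(sprintf("Soret temperature law: S_T_inf = %g 1/K, A = %g 1/K, T0 = %g degC\n",
              x$S_T_inf, x$A, x$T0))
  if (is.finite(x$T_star))
    cat(sprintf("  sign-change temperature T* = %.4g degC\n", x$T_star))
  else
    cat("  no sign change (A and S_T_inf have the same sign)\n")
  invisible(x)
}

#' Evaluate the empirical S_T temperature law
#'
#' @param temperature Temperature (degrees C), vectorized.
#' @param params A [soret_params()] object (or the `params` element of a
#'   [fit_soret_curve()] result).
#' @return S_T (1/K), same length as `temperature`.
#' @export
soret_model <- function(temperature, params) {
  stopifnot(is.numeric(temperature))
  if (inherits(params, "soret_fit")) params <- params$params
  stopifnot(inherits(params, "soret_params"))
  params$S_T_inf + params$A * exp(-temperature / params$T0)
}

#' Sign-change temperature of the S_T law
#'
#' Temperature at which `S_T(T) = 0`: `T* = T0 * log(-A / S_T_inf)`.
#' Only defined when `A` and `S_T_inf` have opposite signs; otherwise the
#' law never crosses zero and `NA` is returned.
#'
#' @param params A [soret_params()] object.
#' @return T* in degrees C, or `NA_real_` when no sign change exists.
#' @export
sign_change_temperature <- function(params) {
  if (inherits(params, "soret_fit")) params <- params$params
  stopifnot(inherits(params, "soret_params"))
  ratio <- -params$A / params$S_T_inf
  if (!is.finite(ratio) || ratio <= 0) return(NA_real_)
  params$T0 * log(ratio)
}

#' Fit the empirical S_T temperature law
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) of
#' `S_T_inf + A * exp(-T / T0)` to measured Soret coefficients as a function
#' of temperature. Weights are `1 / sigma_S_T^2` when uncertainties are
#' given (absolute parameter covariance), else ordinary least squares.
#'
#' Starting values: `S_T_inf` from the highest-temperature point, `T0` as
#' half the temperature span, `A` from the lowest-temperature residual.
#'
#' @param points Data frame with columns `temperature` (degrees C), `S_T`
#'   (1/K) and optionally `sigma_S_T` (1/K, `>= 0`); at least 4 points
#'   spanning at least 15 degrees C.
#' @return An object of class `"soret_fit"`: list with `params`
#'   ([soret_params()], including the derived `T_star`), `covariance`
#'   (3x3, order `S_T_inf, A, T0`), `residual_rms`, `converged`, `data`,
#'   `fitted`.
#' @examples
#' truth <- soret_params(0.02, -0.05, 30)
#' pts <- data.frame(temperature = seq(15, 45, 5),
#'                   S_T = soret_model(seq(15, 45, 5), truth))
#' fit_soret_curve(pts)
#' @export
fit_soret_curve <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("temperature", "S_T") %in% names(points)))
  Tc <- points$temperature
  y <- points$S_T
  if (!all(is.finite(Tc)) || !all(is.finite(y)))
    stop("fit_soret_curve: temperature and S_T must be finite")
  if (nrow(points) < 4L)
    stop("fit_soret_curve: need at least 4 points, got ", nrow(points))
  span <- diff(range(Tc))
  if (span < 15)
    stop("fit_soret_curve: points must span at least 15 degrees C (span = ",
         format(span), ")")
  sy <- points$sigma_S_T
  weighted <- !is.null(sy) && all(is.finite(sy)) && all(sy > 0)
  w <- if (weighted) 1 / sy else rep(1, length(y))

  # the three parameters are strongly correlated over a 30 degC window, so
  # a single naive start is fragile. Profile the nonlinear bending scale:
  # for fixed T0 the model is linear in (S_T_inf, A) and solved exactly;
  # the best grid T0 then seeds a Levenberg-Marquardt polish.
  profile_rss <- function(T0) {
    X <- cbind(1, exp(-Tc / T0)) * w
    b <- tryCatch(qr.solve(X, y * w), error = function(e) c(NA, NA))
    if (anyNA(b)) return(list(rss = Inf))
    list(rss = sum((X %*% b - y * w)^2), S_inf = b[1], A = b[2])
  }
  T0_grid <- span * 2^seq(-3, 4, by = 0.25)
  profs <- lapply(T0_grid, profile_rss)
  best <- which.min(vapply(profs, `[[`, 1, "rss"))
  T00 <- T0_grid[best]
  S_inf0 <- profs[[best]]$S_inf
  A0 <- profs[[best]]$A
  # fall back to the plain heuristic if the profile degenerated
  if (!is.finite(S_inf0) || !is.finite(A0)) {
    S_inf0 <- y[which.max(Tc)]
    T00 <- span / 2
    A0 <- (y[which.min(Tc)] - S_inf0) / exp(-Tc[which.min(Tc)] / T00)
  }

  resid_fn <- function(p) {
    (p[1] + p[2] * exp(-Tc / exp(p[3])) - y) * w
  }
  fit <- minpack.lm::nls.lm(
    par = c(S_inf0, A0, log(T00)), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))
  converged <- fit$info %in% c(1L, 2L, 3L)
  if (!converged)
    warning("fit_soret_curve: Levenberg-Marquardt did not converge (info = ",
            fit$info, ")", call. = FALSE)
  est <- c(S_T_inf = fit$par[1], A = fit$par[2], T0 = exp(fit$par[3]))
  params <- soret_params(est[[1]], est[[2]], est[[3]])
  fitted <- soret_model(Tc, params)
  res <- y - fitted
  # Jacobian in natural parameters (analytic)
  e <- exp(-Tc / est[["T0"]])
  J <- cbind(S_T_inf = rep(1, length(Tc)),
             A = e,
             T0 = est[["A"]] * e * Tc / est[["T0"]]^2)
  covariance <- matrix(NA_real_, 3, 3,
                       dimnames = list(names(est), names(est)))
  cov_try <- tryCatch(.ls_covariance(J, w, res, weighted, est),
                      error = function(e) NULL)
  if (!is.null(cov_try)) covariance <- cov_try
  dimnames(covariance) <- list(names(est), names(est))

  structure(list(params = params, covariance = covariance,
                 residual_rms = sqrt(mean(res^2)), converged = converged,
                 data = points, fitted = fitted, weighted = weighted),
            class = "soret_fit")
}

#' @export
coef.soret_fit <- function(object, ...) {
  c(S_T_inf = object$params$S_T_inf, A = object$params$A,
    T0 = object$params$T0)
}

#' @export
vcov.soret_fit <- function(object, ...) object$covariance

#' @export
residuals.soret_fit <- function(object, ...) object$data$S_T - object$fitted

#' @export
fitted.soret_fit <- function(object, ...) object$fitted

#' @export
nobs.soret_fit <- function(object, ...) nrow(object$data)

#' @rdname fit_soret_curve
#' @param object,x A `"soret_fit"` object.
#' @param temperature Temperatures (degrees C) at which to evaluate the
#'   fitted law; defaults to the fitted data temperatures.
#' @param ... Unused.
#' @export
predict.soret_fit <- function(object, temperature = NULL, ...) {
  if (is.null(temperature)) temperature <- object$data$temperature
  soret_model(temperature, object$params)
}

#' @export
print.soret_fit <- function(x, ...) {
  cat("Empirical Soret temperature-law fit\n")
  est <- coef(x)
  se <- sqrt(diag(x$covariance))
  for (k in seq_along(est))
    cat(sprintf("  %-8s = %.6g (se %.2g)\n", names(est)[k], est[k], se[k]))
  if (is.finite(x$params$T_star))
    cat(sprintf("  T* = %.4g degC (S_T changes sign)\n", x$params$T_star))
  else cat("  no sign change in the fitted range of the law\n")
  cat(sprintf("  residual rms = %.3g on %d points; converged: %s\n",
              x$residual_rms, nrow(x$data), x$converged))
  invisible(x)
}

#' @export
summary.soret_fit <- function(object, ...) {
  est <- coef(object)
  se <- sqrt(diag(object$covariance))
  out <- list(coefficients = cbind(Estimate = est, `Std. Error` = se),
              T_star = object$params$T_star,
              residual_rms = object$residual_rms,
              converged = object$converged, n = nrow(object$data),
              weighted = object$weighted)
  class(out) <- "summary.soret_fit"
  out
}

#' @export
print.summary.soret_fit <- function(x, ...) {
  cat(sprintf("Empirical Soret temperature-law fit (%s least squares, n = %d)\n",
              if (x$weighted) "weighted" else "ordinary", x$n))
  print(x$coefficients)
  if (is.finite(x$T_star)) cat(sprintf("T* = %.4g degC\n", x$T_star))
  cat(sprintf("residual rms %.3g; converged: %s\n",
              x$residual_rms, x$converged))
  invisible(x)
}

#' @export
plot.soret_fit <- function(x, ...) {
  Tc <- x$data$temperature
  graphics::plot(Tc, x$data$S_T, pch = 19,
                 xlab = "temperature (degC)", ylab = "S_T (1/K)", ...)
  if (!is.null(x$data$sigma_S_T))
    graphics::arrows(Tc, x$data$S_T - x$data$sigma_S_T,
                     Tc, x$data$S_T + x$data$sigma_S_T,
                     angle = 90, code = 3, length = 0.03)
  Tg <- seq(min(Tc), max(Tc), length.out = 200)
  graphics::lines(Tg, soret_model(Tg, x$params), col = "red3")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' @rdname fit_soret_curve
#' @param nsim Number of synthetic point sets to draw.
#' @param seed Integer seed.
#' @param noise_sd Gaussian noise added to the model values (1/K); defaults
#'   to the fit's residual rms.
#' @export
simulate.soret_fit <- function(object, nsim = 1, seed = NULL,
                               noise_sd = NULL, ...) {
  if (is.null(noise_sd)) noise_sd <- object$residual_rms
  if (is.null(seed)) seed <- 0L
  lapply(seq_len(nsim), function(i)
    generate_soret_dataset(object$params,
                           temperatures = object$data$temperature,
                           noise_sd = noise_sd, seed = seed + i - 1L))
}

#' Temperature sensitivity of the Soret coefficient
#'
#' `Delta S_T = S_T(T_high) - S_T(T_low)`, the change of the Soret
#' coefficient between a low and a high reference temperature (defaults 15
#' and 40 degrees C). Used as a hydrophilicity proxy: hydrophilic solutes
#' show a stronger temperature dependence of S_T.
#'
#' Two modes:
#' * `"from_points"`: difference of measured values; each endpoint is the
#'   mean of the measurements within 0.5 degrees C of it, and the
#'   uncertainty is combined in quadrature from their `sigma_S_T`. Errors if
#'   an endpoint has no measurement.
#' * `"from_fit"`: difference of the fitted law,
#'   `A * (exp(-T_high/T0) - exp(-T_low/T0))`, with uncertainty by the delta
#'   method on the fit covariance.
#'
#' The default mode is `"from_points"` when `x` carries measured points
#' covering both endpoints, else `"from_fit"`; the mode used is always
#' recorded in the result.
#'
#' @param x A `"soret_fit"`, a [soret_params()] object (fit mode only), or a
#'   data frame of points as in [fit_soret_curve()] (points mode only).
#' @param T_low,T_high Endpoint temperatures (degrees C).
#' @param mode `"auto"`, `"from_points"` or `"from_fit"`.
#' @return An object of class `"delta_ST"`: list with `estimate` (1/K),
#'   `sd` (1/K, `NA` when no uncertainty is available), `mode`, `T_low`,
#'   `T_high`.
#' @export
delta_ST <- function(x, T_low = 15, T_high = 40,
                     mode = c("auto", "from_points", "from_fit")) {
  mode <- match.arg(mode)
  pts <- NULL; fit <- NULL; params <- NULL
  if (inherits(x, "soret_fit")) {
    pts <- x$data; fit <- x; params <- x$params
  } else if (inherits(x, "soret_params")) {
    params <- x
  } else if (is.data.frame(x)) {
    pts <- x
  } else stop("delta_ST: x must be a soret_fit, soret_params or data frame")

  has_endpoints <- function() {
    !is.null(pts) &&
      any(abs(pts$temperature - T_low) <= 0.5) &&
      any(abs(pts$temperature - T_high) <= 0.5)
  }
  if (mode == "auto")
    mode <- if (has_endpoints()) "from_points" else "from_fit"

  if (mode == "from_points") {
    if (is.null(pts))
      stop("delta_ST: from_points mode needs measured points")
    lo <- abs(pts$temperature - T_low) <= 0.5
    hi <- abs(pts$temperature - T_high) <= 0.5
    if (!any(lo) || !any(hi))
      stop("delta_ST: no measurement within 0.5 degC of an endpoint (",
           if (!any(lo)) T_low else T_high, " degC)")
    est <- mean(pts$S_T[hi]) - mean(pts$S_T[lo])
    sdv <- NA_real_
    if (!is.null(pts$sigma_S_T) && all(is.finite(pts$sigma_S_T[lo | hi])))
      sdv <- sqrt(sum(pts$sigma_S_T[hi]^2) / sum(hi)^2 +
                  sum(pts$sigma_S_T[lo]^2) / sum(lo)^2)
  } else {
    if (is.null(params))
      stop("delta_ST: from_fit mode needs fitted parameters")
    ehi <- exp(-T_high / params$T0); elo <- exp(-T_low / params$T0)
    est <- params$A * (ehi - elo)
    sdv <- NA_real_
    if (!is.null(fit) && all(is.finite(fit$covariance))) {
      g <- c(0, ehi - elo,
             params$A * (T_high * ehi - T_low * elo) / params$T0^2)
      sdv <- sqrt(drop(t(g) %*% fit$covariance %*% g))
    }
  }
  structure(list(estimate = est, sd = sdv, mode = mode,
                 T_low = T_low, T_high = T_high),
            class = "delta_ST")
}

#' @export
print.delta_ST <- function(x, ...) {
  cat(sprintf("Delta S_T(%g -> %g degC) = %.6g 1/K%s  [%s]\n",
              x$T_low, x$T_high, x$estimate,
              if (is.finite(x$sd)) sprintf(" +/- %.2g", x$sd) else "",
              x$mode))
  invisible(x)
}
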