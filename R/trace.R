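# Heterodyne traces: container, shot averaging, normalization, phase split.

#' Heterodyne trace
#'
#' Time-resolved normalized heterodyne intensity with optional per-point
#' standard deviations and experiment metadata.
#'
#' @param times Sample times (s), strictly increasing.
#' @param values Normalized intensity (dimensionless), same length.
#' @param per_point_sd Optional per-point standard deviation of `values`
#'   (e.g. the standard error of a shot average), same length, `>= 0`.
#' @param meta Named list of metadata: typically `temperature_C`, `pH`,
#'   `buffer_label`, `geometry` ([grating_geometry()]), `contrast`
#'   ([contrast_factors()]), `c` (weight fraction), `t_excitation_off_s`.
#' @return An object of class `"heterodyne_trace"`.
#' @export
heterodyne_trace <- function(times, values, per_point_sd = NULL, meta = list()) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values), is.list(meta))
  if (length(times) < 1L) stop("heterodyne_trace: empty trace")
  if (!all(is.finite(times)) || !all(is.finite(values)))
    stop("heterodyne_trace: times and values must be finite")
  if (any(diff(times) <= 0))
    stop("heterodyne_trace: times must be strictly increasing")
  if (!is.null(per_point_sd)) {
    stopifnot(is.numeric(per_point_sd), length(per_point_sd) == length(times))
    if (any(!is.finite(per_point_sd)) || any(per_point_sd < 0))
      stop("heterodyne_trace: per_point_sd must be finite and >= 0")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 per_point_sd = per_point_sd, meta = meta),
            class = "heterodyne_trace")
}

#' @export
print.heterodyne_trace <- function(x, ...) {
  cat(sprintf("Heterodyne trace: %d samples, t = [%g, %g] s%s\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              if (is.null(x$per_point_sd)) "" else ", with per-point sd"))
  if (length(x$meta)) {
    keep <- vapply(x$meta, function(v) is.numeric(v) || is.character(v), TRUE)
    if (any(keep))
      cat("  meta:", paste(names(x$meta)[keep],
                           vapply(x$meta[keep], function(v) paste(format(v), collapse = ","), ""),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.heterodyne_trace <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l",
                 xlab = "time (s)", ylab = "heterodyne intensity", ...)
  invisible(x)
}

#' Average a set of equally-timed shots
#'
#' Pointwise mean over repeated single-shot traces on an identical time
#' grid; the per-point standard deviation of the result is the standard
#' error of the mean, `sd / sqrt(n_shots)` (0 for a single shot).
#'
#' @param shots List of [heterodyne_trace()] objects with identical `times`.
#' @return A [heterodyne_trace()] with the metadata of the first shot.
#' @export
average_shots <- function(shots) {
  stopifnot(is.list(shots), length(shots) >= 1L)
  if (!all(vapply(shots, inherits, TRUE, "heterodyne_trace")))
    stop("average_shots: shots must be heterodyne_trace objects")
  times <- shots[[1]]$times
  for (s in shots)
    if (length(s$times) != length(times) || any(s$times != times))
      stop("average_shots: shots must share an identical time grid")
  n <- length(shots)
  vals <- vapply(shots, function(s) s$values, numeric(length(times)))
  vals <- matrix(vals, nrow = length(times))
  m <- rowMeans(vals)
  if (n == 1L) {
    sem <- rep(0, length(times))
  } else {
    sem <- sqrt(rowSums((vals - m)^2) / (n - 1)) / sqrt(n)
  }
  meta <- shots[[1]]$meta
  meta$n_shots <- n
  heterodyne_trace(times, m, per_point_sd = sem, meta = meta)
}

# Heuristic tau_th estimate: first crossing of (1 - 1/e) * plateau_guess on
# the initial rise, linearly interpolated; first crossing wins on ties.
.tau_th_crossing <- function(times, values, plateau_guess) {
  target <- (1 - exp(-1)) * plateau_guess
  sgn <- sign(plateau_guess)
  idx <- which(sgn * values >= sgn * target)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1]
  if (i == 1L) return(times[1])
  # linear interpolation between the bracketing samples
  t0 <- times[i - 1]; t1 <- times[i]
  v0 <- values[i - 1]; v1 <- values[i]
  if (v1 == v0) return(t1)
  t0 + (target - v0) / (v1 - v0) * (t1 - t0)
}

# Heuristic starting values (scale, tau_th, tau, A0) for an on-phase trace
# whose thermal plateau is approximately `scale`.
.on_phase_start <- function(times, values) {
  n <- length(times)
  span <- times[n] - times[1]
  # crude plateau: median of the top decile keeps the estimate near the
  # thermal plateau even when the slow mode pulls the tail up or down
  scale0 <- stats::median(values[ceiling(0.05 * n):ceiling(0.25 * n)])
  if (!is.finite(scale0) || scale0 == 0) scale0 <- stats::median(values)
  if (!is.finite(scale0) || scale0 == 0)
    return(list(scale = 0, tau_th = NA_real_, tau = NA_real_, A0 = NA_real_))
  tau_th0 <- .tau_th_crossing(times, values, scale0)
  if (!is.finite(tau_th0) || tau_th0 <= 0) tau_th0 <- span / 100
  A00 <- (scale0 - values[n]) / scale0
  # slow mode: time at which the departure from the plateau reaches
  # (1 - 1/e) of its final size
  late <- times > 10 * tau_th0
  tau0 <- span / 3
  if (any(late) && abs(A00) > 1e-12) {
    dep <- (scale0 - values) / scale0 / A00      # ~ concentration mode in [0,1]
    idx <- which(late & dep >= (1 - exp(-1)))
    if (length(idx)) tau0 <- max(times[idx[1]] - tau_th0, 2 * tau_th0)
  }
  list(scale = scale0, tau_th = tau_th0, tau = max(tau0, 1.5 * tau_th0),
       A0 = A00)
}

#' Normalize a trace to unit thermal plateau
#'
#' The two-mode signal model is written for a heterodyne intensity whose
#' fast thermal rise saturates at 1. Experimental traces carry an arbitrary
#' detector scale; this rescales the trace so the thermal plateau equals 1.
#'
#' The plateau is estimated by fitting `scale * zeta(t; tau_th, tau, A0)`
#' (the full closed-form on-phase model) to the trace, seeded by the
#' `1 - 1/e` crossing of the initial rise. On a trace that already conforms
#' to the model the estimated scale is exact, so normalization is idempotent
#' to machine precision and invariant under rescaling.
#'
#' @param trace A [heterodyne_trace()] covering at least ~5 thermal rise
#'   times.
#' @return The rescaled trace; `per_point_sd` is rescaled too, and the
#'   estimated scale and thermal time are stored in
#'   `meta$normalization_scale` / `meta$tau_th_estimate`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "heterodyne_trace"))
  tt <- trace$times - trace$times[1]
  v <- trace$values
  # the plateau model describes the excitation-on phase only; restrict the
  # scale fit to it when the switch-off time is known
  t_off <- trace$meta$t_excitation_off_s
  if (!is.null(t_off) && is.finite(t_off)) {
    keep <- tt < (t_off - trace$times[1])
    if (sum(keep) >= 30L) {
      tt <- tt[keep]
      v <- v[keep]
    }
  }
  st <- .on_phase_start(tt, v)
  if (!is.finite(st$scale) || st$scale == 0 ||
      !is.finite(st$tau_th) || tt[length(tt)] < 5 * st$tau_th)
    stop("normalize_trace: degenerate signal; cannot estimate a positive ",
         "thermal plateau (trace must cover >= 5 thermal rise times)")
  # 4-parameter refinement: scale and shape fitted jointly
  resid_fn <- function(p) {
    pars <- signal_params_quiet(exp(p[1]), exp(p[1]) * exp(p[2]), p[3])
    p[4] * heterodyne_intensity(tt, pars) - v
  }
  start <- c(log(st$tau_th), log(st$tau / st$tau_th), st$A0, st$scale)
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    lower = c(log(tt[2] - tt[1]) - 1, 0, -2, -Inf),
    upper = c(log(tt[length(tt)]), log(1e8), 2, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  scale <- fit$par[4]
  if (!is.finite(scale) || scale == 0)
    stop("normalize_trace: degenerate signal; plateau estimate is not positive")
  out <- trace
  out$values <- trace$values / scale
  if (!is.null(trace$per_point_sd)) out$per_point_sd <- trace$per_point_sd / abs(scale)
  out$meta$normalization_scale <- scale
  out$meta$tau_th_estimate <- exp(fit$par[1])
  out
}

# signal_params without the time-scale-separation warning (internal use in
# optimizer loops, where trial parameters may transiently violate it)
signal_params_quiet <- function(tau_th, tau, A0) {
  structure(list(tau_th = tau_th, tau = tau, A0 = A0),
            class = "signal_params")
}

#' Split a trace into excitation-on and excitation-off phases
#'
#' Samples strictly before `t_excitation_off` form the on-phase trace
#' (original time origin); samples at or after it form the off-phase trace,
#' re-zeroed so the switch-off instant is `t = 0`. No sample is lost or
#' duplicated.
#'
#' @param trace A [heterodyne_trace()].
#' @param t_excitation_off Switch-off time (s), strictly inside the time
#'   span of the trace.
#' @return A list with elements `on` and `off`, both [heterodyne_trace()]s.
#' @export
split_phases <- function(trace, t_excitation_off) {
  stopifnot(inherits(trace, "heterodyne_trace"),
            is.numeric(t_excitation_off), length(t_excitation_off) == 1L)
  tt <- trace$times
  if (!is.finite(t_excitation_off) ||
      t_excitation_off <= tt[1] || t_excitation_off >= tt[length(tt)])
    stop("split_phases: t_excitation_off must lie strictly inside the time span")
  on_idx <- tt < t_excitation_off
  off_idx <- !on_idx
  meta_on <- trace$meta; meta_on$phase <- "on"
  meta_off <- trace$meta; meta_off$phase <- "off"
  list(
    on = heterodyne_trace(tt[on_idx], trace$values[on_idx],
                          per_point_sd = trace$per_point_sd[on_idx],
                          meta = meta_on),
    off = heterodyne_trace(tt[off_idx] - t_excitation_off,
                           trace$values[off_idx],
                           per_point_sd = trace$per_point_sd[off_idx],
                           meta = meta_off)
  )
}
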