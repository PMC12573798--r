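# Per-condition records (pH, buffer, alpha-helical content, Delta S_T) and
# the correlation between Delta S_T and helicity across folding states.

# validate a conditions data frame; delta columns may be absent/NA when the
# table only carries structural data
.validate_conditions <- function(records, need_delta = TRUE) {
  stopifnot(is.data.frame(records))
  req <- c("label", "helix_pct")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("conditions table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(records$helix_pct)) ||
      any(records$helix_pct < 0 | records$helix_pct > 100))
    stop("helix_pct must be finite and within [0, 100]")
  if (!is.null(records$helix_sd) &&
      any(is.finite(records$helix_sd) & records$helix_sd < 0))
    stop("helix_sd must be >= 0")
  if (need_delta) {
    if (is.null(records$delta_ST) || any(!is.finite(records$delta_ST)))
      stop("conditions table needs finite delta_ST values")
    if (!is.null(records$delta_ST_sd) &&
        any(is.finite(records$delta_ST_sd) & records$delta_ST_sd < 0))
      stop("delta_ST_sd must be >= 0")
  }
  invisible(records)
}

#' Weighted linear fit (closed-form least squares)
#'
#' Straight-line fit `y = intercept + slope * x` with weights `1 / sy^2`
#' (unit weights when `sy` is omitted), via [stats::lm()]. Uncertainties in
#' `x` are not folded in (no errors-in-variables): the line is descriptive,
#' as in a trend plot.
#'
#' @param x Predictor (here: alpha-helical content, %).
#' @param y Response (here: Delta S_T, 1/K).
#' @param sy Optional standard deviation of `y`, same length, `> 0`.
#' @return List with `slope`, `intercept`, `covariance` (2x2, order
#'   intercept then slope, as from [stats::vcov()]) and the underlying `lm`
#'   fit.
#' @export
weighted_linear_fit <- function(x, y, sy = NULL) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("weighted_linear_fit: need at least 3 points")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("weighted_linear_fit: x and y must be finite")
  if (diff(range(x)) == 0)
    stop("weighted_linear_fit: degenerate design; all x identical")
  w <- NULL
  if (!is.null(sy)) {
    stopifnot(length(sy) == length(y))
    if (any(!is.finite(sy)) || any(sy <= 0))
      stop("weighted_linear_fit: sy must be finite and > 0")
    w <- 1 / sy^2
  }
  fit <- stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  # suppressWarnings: vcov emits a "perfect fit" warning on exact lines
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       covariance = suppressWarnings(stats::vcov(fit)), fit = fit)
}

#' Correlate Delta S_T with alpha-helical content across conditions
#'
#' Fits a weighted straight line of `delta_ST` against `helix_pct` (weights
#' from `delta_ST_sd` when present), reports the Pearson correlation, and
#' runs a leave-one-out sensitivity analysis: any record whose removal
#' changes the slope by more than `outlier_threshold` (default 50%) is
#' flagged. With only a handful of folding states the report is
#' descriptive; no p-value is attached.
#'
#' @param records Conditions data frame with columns `label`, `helix_pct`,
#'   `delta_ST` and optionally `helix_sd`, `delta_ST_sd`, `pH`,
#'   `buffer_label`, `buffer_conc_mM`; at least 3 rows.
#' @param outlier_threshold Relative slope change that flags a record.
#' @return An object of class `"condition_correlation"`: list with `slope`
#'   (1/K per %), `intercept` (1/K), `pearson_r`, `n`, `covariance`,
#'   `leave_one_out_slopes` (named by label), `flagged_outliers` (labels),
#'   `records`.
#' @export
correlate_conditions <- function(records, outlier_threshold = 0.5) {
  .validate_conditions(records, need_delta = TRUE)
  if (nrow(records) < 3L)
    stop("correlate_conditions: need at least 3 condition records")
  # stable order: the report must not depend on input row order
  ord <- order(records$label)
  rec <- records[ord, , drop = FALSE]
  x <- rec$helix_pct; y <- rec$delta_ST
  sy <- rec$delta_ST_sd
  if (!is.null(sy) && (any(!is.finite(sy)) || any(sy <= 0))) sy <- NULL
  wf <- weighted_linear_fit(x, y, sy)
  r <- stats::cor(x, y)
  loo <- vapply(seq_len(nrow(rec)), function(i) {
    xi <- x[-i]; yi <- y[-i]; syi <- if (is.null(sy)) NULL else sy[-i]
    if (length(unique(xi)) < 2L) return(NA_real_)
    weighted_linear_fit(xi, yi, syi)$slope
  }, numeric(1))
  names(loo) <- rec$label
  rel_change <- abs(loo - wf$slope) / abs(wf$slope)
  flagged <- rec$label[is.finite(rel_change) & rel_change > outlier_threshold]
  structure(list(slope = wf$slope, intercept = wf$intercept,
                 pearson_r = r, n = nrow(rec), covariance = wf$covariance,
                 leave_one_out_slopes = loo,
                 flagged_outliers = flagged, records = rec,
                 outlier_threshold = outlier_threshold),
            class = "condition_correlation")
}

#' @export
coef.condition_correlation <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
print.condition_correlation <- function(x, ...) {
  cat(sprintf(
    "Delta S_T vs alpha-helical content over %d conditions\n", x$n))
  cat(sprintf("  slope     = %.4g 1/K per %% helix\n", x$slope))
  cat(sprintf("  intercept = %.4g 1/K\n", x$intercept))
  cat(sprintf("  Pearson r = %.4f\n", x$pearson_r))
  if (length(x$flagged_outliers))
    cat("  leave-one-out flags:", paste(x$flagged_outliers, collapse = ", "),
        sprintf("(slope change > %.0f%%)\n", 100 * x$outlier_threshold))
  else cat("  leave-one-out: no influential condition flagged\n")
  invisible(x)
}

#' @export
summary.condition_correlation <- function(object, ...) {
  print(object, ...)
  cat("  leave-one-out slopes:\n")
  print(object$leave_one_out_slopes)
  invisible(object)
}

#' @export
plot.condition_correlation <- function(x, ...) {
  rec <- x$records
  graphics::plot(rec$helix_pct, rec$delta_ST, pch = 19,
                 xlab = "alpha-helical content (%)",
                 ylab = "Delta S_T (1/K)", ...)
  if (!is.null(rec$delta_ST_sd))
    graphics::arrows(rec$helix_pct, rec$delta_ST - rec$delta_ST_sd,
                     rec$helix_pct, rec$delta_ST + rec$delta_ST_sd,
                     angle = 90, code = 3, length = 0.03)
  graphics::abline(x$intercept, x$slope, col = "red3")
  graphics::text(rec$helix_pct, rec$delta_ST, rec$label, pos = 3, cex = 0.7)
  invisible(x)
}

#' Rank conditions by temperature sensitivity
#'
#' Orders condition records by `delta_ST` descending (most
#' temperature-sensitive, i.e. most hydrophilic, first); ties are broken by
#' label in lexicographic order.
#'
#' @param records Conditions data frame with `label` and `delta_ST`.
#' @return Character vector of labels in rank order.
#' @export
rank_by_sensitivity <- function(records) {
  .validate_conditions(records, need_delta = TRUE)
  ord <- order(-records$delta_ST, records$label)
  as.character(records$label[ord])
}
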