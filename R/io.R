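# File formats and the end-to-end pipeline: trace CSV dialect with
# '#'-prefixed key=value headers, conditions CSV, JSON reports.

.TRACE_KEYS <- c("temperature_C", "pH", "buffer_label", "q_per_m",
                 "fringe_spacing_m", "dn_dT", "dn_dc", "c_weight_fraction",
                 "t_excitation_off_s")
# keys that must be present (in file or defaults); geometry needs one of
# q_per_m / fringe_spacing_m
.TRACE_REQUIRED <- c("temperature_C", "dn_dT", "dn_dc", "c_weight_fraction",
                     "t_excitation_off_s")

#' Write a heterodyne trace file
#'
#' CSV dialect: '#'-prefixed `key=value` header lines carrying the
#' experiment metadata, a column header `time_s,zeta[,zeta_sd]`, then the
#' samples. Hand-inspectable and diff-able.
#'
#' @param trace A [heterodyne_trace()]. Metadata entries `temperature_C`,
#'   `pH`, `buffer_label`, `geometry`, `contrast`, `c`,
#'   `t_excitation_off_s` are written when present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "heterodyne_trace"))
  m <- trace$meta
  hdr <- character(0)
  put <- function(key, val) {
    if (!is.null(val) && !(is.numeric(val) && !is.finite(val)))
      hdr <<- c(hdr, sprintf("# %s=%s", key,
                             if (is.numeric(val)) format(val, digits = 17)
                             else as.character(val)))
  }
  put("temperature_C", m$temperature_C)
  put("pH", m$pH)
  put("buffer_label", m$buffer_label)
  if (!is.null(m$geometry)) put("q_per_m", m$geometry$q)
  if (!is.null(m$contrast)) {
    put("dn_dT", m$contrast$dn_dT)
    put("dn_dc", m$contrast$dn_dc)
  }
  put("c_weight_fraction", m$c)
  put("t_excitation_off_s", m$t_excitation_off_s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (is.null(trace$per_point_sd)) {
    writeLines("time_s,zeta", con)
    utils::write.table(
      data.frame(format(trace$times, digits = 17),
                 format(trace$values, digits = 17)),
      con, sep = ",", row.names = FALSE, col.names = FALSE,
      quote = FALSE)
  } else {
    writeLines("time_s,zeta,zeta_sd", con)
    utils::write.table(
      data.frame(format(trace$times, digits = 17),
                 format(trace$values, digits = 17),
                 format(trace$per_point_sd, digits = 17)),
      con, sep = ",", row.names = FALSE, col.names = FALSE,
      quote = FALSE)
  }
  invisible(path)
}

#' Read a heterodyne trace file
#'
#' Parses the dialect written by [write_trace()]. Header keys absent from
#' the file are filled from `defaults`; a required key available from
#' neither raises a format error naming the key. Times must be strictly
#' increasing.
#'
#' @param path Input path.
#' @param defaults Named list of fallback header values (same keys as the
#'   file header).
#' @return A [heterodyne_trace()] with metadata including `geometry`
#'   ([grating_geometry()]) and `contrast` ([contrast_factors()]).
#' @export
read_trace <- function(path, defaults = list()) {
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  kv <- list()
  for (ln in lines[is_hdr]) {
    ln2 <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", ln2, fixed = TRUE)
    if (eq < 0)
      stop("read_trace: malformed header line (expected key=value): ", ln)
    key <- trimws(substr(ln2, 1, eq - 1))
    val <- trimws(substr(ln2, eq + 1, nchar(ln2)))
    if (!(key %in% .TRACE_KEYS))
      stop("read_trace: unknown header key: ", key)
    kv[[key]] <- val
  }
  for (key in names(defaults))
    if (is.null(kv[[key]])) kv[[key]] <- defaults[[key]]
  for (key in .TRACE_REQUIRED)
    if (is.null(kv[[key]]))
      stop("read_trace: missing mandatory header key: ", key)
  if (is.null(kv$q_per_m) && is.null(kv$fringe_spacing_m))
    stop("read_trace: missing mandatory header key: q_per_m ",
         "(or fringe_spacing_m)")

  body <- lines[!is_hdr]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L)
    stop("read_trace: no data rows")
  cols <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (!(length(cols) %in% 2:3) || cols[1] != "time_s" || cols[2] != "zeta")
    stop("read_trace: expected column header time_s,zeta[,zeta_sd]")
  dat <- utils::read.csv(text = body[-1], header = FALSE,
                         col.names = cols, colClasses = "numeric")
  if (any(diff(dat$time_s) <= 0))
    stop("read_trace: times are not strictly increasing")
  num <- function(key) as.numeric(kv[[key]])
  geometry <- if (!is.null(kv$q_per_m)) grating_geometry(q = num("q_per_m"))
              else grating_geometry(fringe_spacing = num("fringe_spacing_m"))
  meta <- list(
    temperature_C = num("temperature_C"),
    pH = if (is.null(kv$pH)) NA_real_ else num("pH"),
    buffer_label = if (is.null(kv$buffer_label)) "none" else kv$buffer_label,
    geometry = geometry,
    contrast = contrast_factors(num("dn_dT"), num("dn_dc")),
    c = num("c_weight_fraction"),
    t_excitation_off_s = num("t_excitation_off_s"))
  heterodyne_trace(dat$time_s, dat$zeta,
                   per_point_sd = if ("zeta_sd" %in% names(dat)) dat$zeta_sd,
                   meta = meta)
}

#' Read / write a conditions table
#'
#' Plain CSV with columns `label`, `pH`, `buffer_label`, `buffer_conc_mM`,
#' `helix_pct`, `helix_sd`, `delta_ST`, `delta_ST_sd` (the last two may be
#' empty when the table carries only structural data).
#'
#' @param path CSV path.
#' @return A data frame (for [read_conditions()]); `path` invisibly for
#'   [write_conditions()].
#' @export
read_conditions <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_conditions(dat, need_delta = FALSE)
  dat
}

#' @rdname read_conditions
#' @param records Conditions data frame.
#' @export
write_conditions <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration for the analysis pipeline
#'
#' @param trace_paths Character vector of trace-file paths.
#' @param conditions_path Optional conditions CSV (helicity table).
#' @param out_dir Optional output directory for the JSON report and CSV
#'   tables.
#' @param T_low,T_high Delta S_T endpoint temperatures (degrees C).
#' @param delta_mode Delta S_T mode passed to [delta_ST()].
#' @param trace_defaults Header defaults passed to [read_trace()].
#' @param seed Integer seed (recorded in the report; the analysis itself is
#'   deterministic).
#' @param verbose Log stage counts via [message()].
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(trace_paths = character(0), conditions_path = NULL,
                       out_dir = NULL, T_low = 15, T_high = 40,
                       delta_mode = "auto", trace_defaults = list(),
                       seed = 0L, verbose = TRUE) {
  structure(list(trace_paths = trace_paths,
                 conditions_path = conditions_path, out_dir = out_dir,
                 T_low = T_low, T_high = T_high, delta_mode = delta_mode,
                 trace_defaults = trace_defaults, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Run the full TDFRS analysis pipeline
#'
#' For each trace: normalize to unit thermal plateau, split into excitation
#' on/off phases, fit the two-mode model to both phases, and derive
#' transport coefficients. Per-temperature values are pooled over phases
#' and repeats within each solution condition (identified by
#' `buffer_label` + `pH`); the Soret temperature law is fitted per
#' condition, Delta S_T computed, and (when a conditions table is supplied)
#' Delta S_T is correlated against alpha-helical content and the conditions
#' ranked by temperature sensitivity.
#'
#' Failures are logged with the trace identity and the pipeline continues
#' over the remaining inputs, reporting a nonzero failure count; an empty
#' input set yields an empty report with a warning.
#'
#' @param config A [run_config()].
#' @return A report list (class `"tdfrs_report"`) with elements `counts`,
#'   `fits`, `pooled`, `curves`, `delta_ST`, `correlation`, `ranking`,
#'   `failures`, `seed`. Written as `report.json` (plus `fits.csv`,
#'   `pooled.csv`) under `out_dir` when given.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(...) if (config$verbose) message(sprintf(...))
  failures <- list()
  fit_rows <- list()

  for (path in config$trace_paths) {
    res <- tryCatch({
      trace <- read_trace(path, defaults = config$trace_defaults)
      trace <- normalize_trace(trace)
      ph <- split_phases(trace, trace$meta$t_excitation_off_s)
      rows <- lapply(c("on", "off"), function(phase) {
        fit <- fit_signal(ph[[phase]], phase = phase)
        tr <- derive_transport(fit)
        data.frame(file = basename(path),
                   buffer_label = trace$meta$buffer_label,
                   pH = trace$meta$pH,
                   temperature_C = trace$meta$temperature_C,
                   phase = phase,
                   tau_th = coef(fit)[["tau_th"]],
                   tau = coef(fit)[["tau"]],
                   A0 = coef(fit)[["A0"]],
                   D = tr$D, D_th = tr$D_th, D_T = tr$D_T, S_T = tr$S_T,
                   converged = fit$converged,
                   residual_rms = fit$residual_rms)
      })
      do.call(rbind, rows)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log_msg("pipeline: trace %s failed: %s", basename(path),
              conditionMessage(res))
      failures[[basename(path)]] <- conditionMessage(res)
    } else {
      fit_rows[[path]] <- res
    }
  }

  fits <- if (length(fit_rows)) do.call(rbind, fit_rows) else
    data.frame(file = character(0), buffer_label = character(0),
               pH = numeric(0), temperature_C = numeric(0),
               phase = character(0), tau_th = numeric(0), tau = numeric(0),
               A0 = numeric(0), D = numeric(0), D_th = numeric(0),
               D_T = numeric(0), S_T = numeric(0), converged = logical(0),
               residual_rms = numeric(0))
  rownames(fits) <- NULL
  n_flagged <- sum(!fits$converged)
  log_msg("pipeline: %d trace(s) read, %d failed, %d fit(s), %d converged, %d flagged",
          length(config$trace_paths), length(failures), nrow(fits),
          sum(fits$converged), n_flagged)

  # pool per condition x temperature over phases and repeats
  pooled <- NULL
  curves <- list()
  deltas <- list()
  if (nrow(fits)) {
    key <- interaction(fits$buffer_label, fits$pH, fits$temperature_C,
                       drop = TRUE)
    pooled <- do.call(rbind, lapply(split(fits, key), function(gr) {
      ps <- pool_estimates(gr$S_T)
      data.frame(buffer_label = gr$buffer_label[1], pH = gr$pH[1],
                 temperature_C = gr$temperature_C[1],
                 S_T = ps$mean, S_T_sem = ps$sem,
                 D = mean(gr$D), D_th = mean(gr$D_th), D_T = mean(gr$D_T),
                 n = ps$n)
    }))
    rownames(pooled) <- NULL
    pooled <- pooled[order(pooled$buffer_label, pooled$pH,
                           pooled$temperature_C), ]

    ckey <- interaction(pooled$buffer_label, pooled$pH, drop = TRUE)
    for (gr in split(pooled, ckey)) {
      cond <- sprintf("%s pH %g", gr$buffer_label[1], gr$pH[1])
      if (nrow(gr) < 4L || diff(range(gr$temperature_C)) < 15) {
        log_msg("pipeline: condition %s: too few temperatures for a Soret curve",
                cond)
        next
      }
      pts <- data.frame(temperature = gr$temperature_C, S_T = gr$S_T,
                        sigma_S_T = ifelse(gr$S_T_sem > 0, gr$S_T_sem,
                                           NA_real_))
      if (any(is.na(pts$sigma_S_T))) pts$sigma_S_T <- NULL
      cf <- tryCatch(fit_soret_curve(pts), error = function(e) e)
      if (inherits(cf, "error")) {
        failures[[cond]] <- conditionMessage(cf)
        next
      }
      d <- delta_ST(cf, T_low = config$T_low, T_high = config$T_high,
                    mode = config$delta_mode)
      curves[[cond]] <- list(S_T_inf = cf$params$S_T_inf, A = cf$params$A,
                             T0 = cf$params$T0, T_star = cf$params$T_star,
                             converged = cf$converged)
      deltas[[cond]] <- list(buffer_label = gr$buffer_label[1],
                             pH = gr$pH[1], delta_ST = d$estimate,
                             delta_ST_sd = d$sd, mode = d$mode)
    }
    log_msg("pipeline: %d condition curve(s) fitted", length(curves))
  }

  correlation <- NULL
  ranking <- NULL
  if (!is.null(config$conditions_path)) {
    conds <- read_conditions(config$conditions_path)
    if ((is.null(conds$delta_ST) || anyNA(conds$delta_ST)) &&
        length(deltas)) {
      # fill measured Delta S_T by condition (buffer label + pH)
      for (i in seq_len(nrow(conds))) {
        hit <- Filter(function(d) d$buffer_label == conds$buffer_label[i] &&
                        isTRUE(d$pH == conds$pH[i]), deltas)
        if (length(hit) == 1L) {
          conds$delta_ST[i] <- hit[[1]]$delta_ST
          conds$delta_ST_sd[i] <- hit[[1]]$delta_ST_sd
        }
      }
    }
    if (!is.null(conds$delta_ST) && !anyNA(conds$delta_ST) &&
        nrow(conds) >= 3L) {
      corr <- correlate_conditions(conds)
      correlation <- list(slope = corr$slope, intercept = corr$intercept,
                          pearson_r = corr$pearson_r, n = corr$n,
                          leave_one_out_slopes =
                            as.list(corr$leave_one_out_slopes),
                          flagged_outliers = corr$flagged_outliers)
      ranking <- rank_by_sensitivity(conds)
      log_msg("pipeline: %d condition record(s) correlated, r = %.3f",
              corr$n, corr$pearson_r)
    } else {
      log_msg("pipeline: conditions table lacks complete delta_ST; correlation skipped")
    }
  }

  report <- structure(list(
    counts = list(traces_read = length(config$trace_paths) - length(failures),
                  traces_failed = length(failures),
                  fits = nrow(fits), fits_converged = sum(fits$converged),
                  fits_flagged = n_flagged,
                  conditions_correlated =
                    if (is.null(correlation)) 0L else correlation$n),
    fits = fits, pooled = pooled, curves = curves, delta_ST = deltas,
    correlation = correlation, ranking = ranking,
    failures = failures, seed = config$seed), class = "tdfrs_report")

  if (length(config$trace_paths) == 0L)
    warning("run_pipeline: empty input set; empty report", call. = FALSE)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    utils::write.csv(fits, file.path(config$out_dir, "fits.csv"),
                     row.names = FALSE)
    if (!is.null(pooled))
      utils::write.csv(pooled, file.path(config$out_dir, "pooled.csv"),
                       row.names = FALSE)
  }
  report
}

#' @export
print.tdfrs_report <- function(x, ...) {
  cat("TDFRS pipeline report\n")
  cat(sprintf("  traces: %d read, %d failed; fits: %d (%d converged, %d flagged)\n",
              x$counts$traces_read, x$counts$traces_failed, x$counts$fits,
              x$counts$fits_converged, x$counts$fits_flagged))
  for (cond in names(x$delta_ST))
    cat(sprintf("  %s: Delta S_T = %.4g 1/K [%s]\n", cond,
                x$delta_ST[[cond]]$delta_ST, x$delta_ST[[cond]]$mode))
  if (!is.null(x$correlation))
    cat(sprintf("  correlation: slope %.4g 1/K per %%, r = %.3f over %d conditions\n",
                x$correlation$slope, x$correlation$pearson_r,
                x$correlation$n))
  if (!is.null(x$ranking))
    cat("  sensitivity ranking:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}
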