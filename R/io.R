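#' Read a hyperpolarized intensity series from tabular text
#'
#' Accepts the two dialects used throughout: wide
#' (`time_s, pyruvate, lactate`) and long (`time_s, species, intensity` with
#' species labels `pyruvate`/`lactate`). Field separator (comma, tab or
#' whitespace) is sniffed from the header line. Times must be strictly
#' increasing; violations and malformed cells are reported with line numbers.
#'
#' @param path File path.
#' @param dialect `"auto"` (default), `"wide"` or `"long"`.
#' @return An [hp_series()].
#' @export
read_series <- function(path, dialect = c("auto", "wide", "long")) {
  dialect <- match.arg(dialect)
  header <- readLines(path, n = 1L)
  sep <- if (grepl(",", header)) "," else if (grepl("\t", header)) "\t" else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  cols <- tolower(names(df))
  names(df) <- cols
  if (dialect == "auto") {
    dialect <- if ("species" %in% cols) "long" else "wide"
  }
  if (dialect == "long") {
    need <- c("time_s", "species", "intensity")
    if (!all(need %in% cols)) {
      stop("parse-error: long dialect needs columns time_s, species, intensity",
           call. = FALSE)
    }
    known <- c("pyruvate", "lactate")
    badsp <- which(!df$species %in% known)
    if (length(badsp)) {
      stop(sprintf("parse-error: unknown species %s at line(s) %s",
                   paste(unique(df$species[badsp]), collapse = ", "),
                   paste(badsp + 1L, collapse = ", ")), call. = FALSE)
    }
    check_numeric(df$time_s, "time_s")
    check_numeric(df$intensity, "intensity")
    p <- df[df$species == "pyruvate", c("time_s", "intensity")]
    l <- df[df$species == "lactate", c("time_s", "intensity")]
    p <- p[order(p$time_s), ]
    l <- l[order(l$time_s), ]
    if (nrow(p) != nrow(l) || any(abs(p$time_s - l$time_s) > 1e-9)) {
      stop("parse-error: pyruvate and lactate timestamps do not match",
           call. = FALSE)
    }
    times <- p$time_s
    prec <- p$intensity
    prod <- l$intensity
  } else {
    need <- c("time_s", "pyruvate", "lactate")
    if (!all(need %in% cols)) {
      stop("parse-error: wide dialect needs columns time_s, pyruvate, lactate",
           call. = FALSE)
    }
    check_numeric(df$time_s, "time_s")
    check_numeric(df$pyruvate, "pyruvate")
    check_numeric(df$lactate, "lactate")
    times <- df$time_s
    prec <- df$pyruvate
    prod <- df$lactate
  }
  dup <- which(duplicated(times))
  if (length(dup)) {
    stop(sprintf("parse-error: duplicate timestamps at line(s) %s",
                 paste(dup + 1L, collapse = ", ")), call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("parse-error: times must be strictly increasing", call. = FALSE)
  }
  hp_series(as.numeric(times), as.numeric(prec), as.numeric(prod))
}

check_numeric <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(x))))
    stop(sprintf("parse-error: non-numeric %s at line(s) %s", name,
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
}

#' Write a hyperpolarized series as tabular text
#'
#' @param series An [hp_series()].
#' @param path Output path.
#' @param dialect `"wide"` (default) or `"long"`.
#' @export
write_series <- function(series, path, dialect = c("wide", "long")) {
  stopifnot(inherits(series, "hp_series"))
  dialect <- match.arg(dialect)
  fmt <- function(x) sprintf("%.17g", x)   # round-trips doubles exactly
  df <- if (dialect == "wide") {
    data.frame(time_s = fmt(series$times), pyruvate = fmt(series$precursor),
               lactate = fmt(series$product))
  } else {
    data.frame(
      time_s = fmt(rep(series$times, 2L)),
      species = rep(c("pyruvate", "lactate"), each = length(series$times)),
      intensity = fmt(c(series$precursor, series$product)))
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' @param path Path to a YAML file describing a run (see [run_pipeline()]
#'   for the recognized fields).
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

validate_config <- function(config) {
  designs <- c("arrest_nonselective", "arrest_selective", "continuous_flow")
  if (is.null(config$design) || !config$design %in% designs) {
    stop("config-error: 'design' must be one of ",
         paste(designs, collapse = ", "), call. = FALSE)
  }
  if (is.null(config$TR)) {
    stop("config-error: 'TR' (s) is required", call. = FALSE)
  }
  if (config$design == "arrest_nonselective") {
    if (is.null(config$nutation)) {
      stop("config-error: 'nutation' (deg) is required for non-selective runs",
           call. = FALSE)
    }
  } else {
    if (is.null(config$rho) && is.null(config$pulse)) {
      stop("config-error: selective designs need 'rho' (scalar) or a 'pulse' block",
           call. = FALSE)
    }
    if (is.null(config$theta_p)) {
      stop("config-error: 'theta_p' (precursor effective angle, deg) is required",
           call. = FALSE)
    }
    if (is.null(config$atp_nmole)) {
      stop("config-error: 'atp_nmole' is required for rate normalization",
           call. = FALSE)
    }
    if (config$design == "continuous_flow" && is.null(config$T1_precursor)) {
      stop("config-error: continuous_flow needs 'T1_precursor' (s) from an arrested-perfusion measurement",
           call. = FALSE)
    }
  }
  config
}

config_default <- function(config, field, default, log) {
  if (is.null(config[[field]])) {
    log(sprintf("default applied: %s = %s", field,
                paste(format(default), collapse = " ")))
    default
  } else {
    config[[field]]
  }
}

#' Run the design-appropriate analysis chain
#'
#' For `arrest_nonselective` the series is fitted with the two-pool model and
#' the rate constant is extrapolated to an amount (and per-ATP rate if
#' `atp_nmole` is given). For `arrest_selective` and `continuous_flow` the
#' chain is: precursor T1 (fitted for the arrested design via [fit_t1_eq1()],
#' supplied via `T1_precursor` for continuous flow), decay correction,
#' constant-concentration window selection, per-excitation rates and plateau
#' aggregation. Every default applied is logged in the report; all numbers
#' carry units.
#'
#' Recognized config fields: `design`, `series` (path or [hp_series()]),
#' `TR`, `nutation` (non-selective), `theta_p`, `rho` or `pulse`
#' (`kind`, `duration_s`, `calibrated_angle_deg`, `lobes`,
#' `precursor_offset_hz`), `pyr_conc_mM`, `V_medium_mL`, `atp_nmole`,
#' `T1_precursor`, `drop_first`, `t_extrapolate_s`, `window_tol`,
#' `stabilization_tol`, `quench_mask` (indices to exclude), `seed`.
#'
#' @param config A config list (see [read_run_config()]).
#' @return A list of class `"hp_report"`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)

  series <- config$series
  if (is.character(series)) series <- read_series(series)
  if (!inherits(series, "hp_series")) {
    stop("config-error: 'series' must be a path or an hp_series",
         call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  if (config$design == "arrest_nonselective") {
    scheme <- acquisition_scheme(config$TR, config$nutation,
                                 n_samples = length(series$times))
    drop_first <- config_default(config, "drop_first", TRUE, log)
    fit <- fit_two_pool(series, scheme, drop_first = drop_first)
    report <- list(design = config$design,
                   k_1st_per_s = fit$params$k_1st,
                   T1_precursor_s = fit$params$T1_precursor,
                   T1_product_s = fit$params$T1_product,
                   M0_au = fit$params$M0,
                   r2_precursor = fit$r2_precursor,
                   r2_product = fit$r2_product)
    pyr_conc <- config_default(config, "pyr_conc_mM", 14, log)
    v_med <- config_default(config, "V_medium_mL", 0.5, log)
    t_ex <- config_default(config, "t_extrapolate_s", 60, log)
    pyr_nmole <- pyr_conc * v_med * 1000
    report$lactate_amount_nmole <- extrapolate_amount(fit$params$k_1st,
                                                      pyr_nmole, t_ex)
    report$t_extrapolate_s <- t_ex
    if (!is.null(config$atp_nmole)) {
      report$rate_per_atp_nmole_min_nmoleATP <-
        report$lactate_amount_nmole / config$atp_nmole * (60 / t_ex)
    }
  } else {
    theta_p <- config$theta_p
    scheme <- acquisition_scheme(config$TR, theta_p, 90,
                                 n_samples = length(series$times))
    mask <- rep(FALSE, length(series$times))
    if (!is.null(config$quench_mask)) mask[config$quench_mask] <- TRUE
    keep <- which(!mask)
    t_keep <- series$times[keep]
    sp <- series$precursor[keep]
    sl <- series$product[keep]
    if (!is.null(config$T1_precursor)) {
      T1 <- config$T1_precursor
      log("precursor T1 supplied from arrested-perfusion measurement")
      t1fit <- NULL
    } else {
      t1fit <- fit_t1_eq1(t_keep, sp, scheme)
      T1 <- t1fit$T1
    }
    corr <- correct_precursor_eq2(t_keep, sp, T1, scheme)
    wtol <- config_default(config, "window_tol", 0.10, log)
    corr <- select_constant_window(corr, tol = wtol)
    rho <- config$rho
    if (is.null(rho)) {
      p <- config$pulse
      shape <- pulse_shape(p$kind, p$duration_s, p$calibrated_angle_deg,
                           if (is.null(p$lobes)) 3L else p$lobes)
      if (is.null(p$lobes)) log("default applied: pulse lobes = 3")
      rho <- response_ratio(0, p$precursor_offset_hz, shape)
      log(sprintf("rho simulated from pulse description: %.4g", rho))
    }
    pyr_conc <- config_default(config, "pyr_conc_mM", 14, log)
    v_med <- config_default(config, "V_medium_mL", 0.5, log)
    stol <- config_default(config, "stabilization_tol", 0.15, log)
    w <- corr$window
    rates <- rate_eq3(sl[w], sp[w], pyr_conc, rho, config$TR, v_med,
                      config$atp_nmole)
    agg <- aggregate_rates(rates, stabilization_tol = stol)
    report <- list(design = config$design,
                   T1_precursor_s = T1,
                   t1_fit = t1fit,
                   rho = rho,
                   window_indices = keep[w],
                   window_times_s = t_keep[w],
                   per_point_rates_nmole_min_nmoleATP = agg$per_point_rates,
                   mean_rate_nmole_min_nmoleATP = agg$mean_rate,
                   sd_rate_nmole_min_nmoleATP = agg$sd_rate,
                   stabilized_indices = keep[w][agg$stabilized_indices])
  }
  report$log <- log_lines
  class(report) <- "hp_report"
  report
}

#' @export
print.hp_report <- function(x, ...) {
  cat(sprintf("<hp_report> design: %s\n", x$design))
  if (x$design == "arrest_nonselective") {
    cat(sprintf("  k_1st = %.4g 1/s; T1 pyr = %.4g s; T1 lac = %.4g s\n",
                x$k_1st_per_s, x$T1_precursor_s, x$T1_product_s))
    cat(sprintf("  R2 pyr = %.4f; R2 lac = %.4f\n",
                x$r2_precursor, x$r2_product))
    cat(sprintf("  lactate in %.3g s: %.4g nmole\n",
                x$t_extrapolate_s, x$lactate_amount_nmole))
    if (!is.null(x$rate_per_atp_nmole_min_nmoleATP)) {
      cat(sprintf("  per-ATP rate: %.4g nmole/min/nmole ATP\n",
                  x$rate_per_atp_nmole_min_nmoleATP))
    }
  } else {
    cat(sprintf("  T1 pyr = %.4g s; rho = %.4g; window of %d points\n",
                x$T1_precursor_s, x$rho, length(x$window_indices)))
    cat(sprintf("  rate: %.4g +- %.4g nmole/min/nmole ATP\n",
                x$mean_rate_nmole_min_nmoleATP, x$sd_rate_nmole_min_nmoleATP))
  }
  if (length(x$log)) cat("  log:", paste(x$log, collapse = "\n       "), "\n")
  invisible(x)
}
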