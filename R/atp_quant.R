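#' A thermal-equilibrium 31P measurement
#'
#' Bundles an integrated gamma-ATP (or standard) intensity with the
#' acquisition metadata needed to compare it with another measurement:
#' flip angle, repetition time, scan count and the longitudinal relaxation
#' time of the species under the field used. T1 is mandatory — quantification
#' refuses to assume one silently.
#'
#' @param integral Integrated peak intensity, arbitrary units.
#' @param flip_angle Excitation flip angle, degrees.
#' @param TR Repetition time, seconds.
#' @param n_scans Number of averaged acquisitions (>= 1).
#' @param T1 Longitudinal relaxation time of the species, seconds.
#' @return An object of class `"p31_measurement"`.
#' @export
p31_measurement <- function(integral, flip_angle, TR, n_scans, T1) {
  if (missing(T1) || is.null(T1) || !is.finite(T1)) {
    stop("missing-metadata: T1 is required for saturation correction",
         call. = FALSE)
  }
  if (integral <= 0 || flip_angle <= 0 || TR <= 0 || T1 <= 0) {
    stop("invalid-parameter: all fields must be positive", call. = FALSE)
  }
  n_scans <- as.integer(n_scans)
  if (is.na(n_scans) || n_scans < 1L) {
    stop("invalid-parameter: n_scans must be >= 1", call. = FALSE)
  }
  structure(list(integral = integral, flip_angle = flip_angle, TR = TR,
                 n_scans = n_scans, T1 = T1),
            class = "p31_measurement")
}

#' Steady-state saturation factor of a pulsed acquisition
#'
#' Signal per scan of a pulse train at flip angle theta and repetition time
#' TR, relative to a fully relaxed 90-degree scan:
#' `sin(theta) * (1 - E) / (1 - E * cos(theta))` with `E = exp(-TR/T1)`.
#' This is the Ernst steady-state expression; it corrects 31P integrals for
#' partial saturation before amounts are compared.
#'
#' @param flip_angle Degrees.
#' @param TR Seconds.
#' @param T1 Seconds.
#' @return The unitless factor in (0, 1\].
#' @export
#' @examples
#' saturation_factor(50, 1.1, 1.0)
saturation_factor <- function(flip_angle, TR, T1) {
  if (any(flip_angle <= 0) || any(TR <= 0) || any(T1 <= 0)) {
    stop("invalid-parameter: arguments must be positive", call. = FALSE)
  }
  th <- flip_angle * pi / 180
  E <- exp(-TR / T1)
  sin(th) * (1 - E) / (1 - E * cos(th))
}

#' Quantify ATP against an external standard
#'
#' The sample amount follows from the ratio of saturation- and
#' scan-count-normalized integrals:
#' `amount = standard_amount * (I_s / n_s / f_s) / (I_std / n_std / f_std)`
#' with `f` the [saturation_factor()] of each acquisition. Deterministic;
#' invariant to rescaling both integrals by a common factor.
#'
#' @param sample A [p31_measurement()] of the tissue gamma-ATP signal.
#' @param standard A [p31_measurement()] of the external ATP standard.
#' @param standard_amount Amount of ATP in the probe-visible part of the
#'   standard, nmole (see [atp_standard_amount()]).
#' @return An object of class `"atp_quantification"` with `atp_amount`
#'   (nmole) and the inputs.
#' @export
quantify_atp <- function(sample, standard, standard_amount) {
  stopifnot(inherits(sample, "p31_measurement"),
            inherits(standard, "p31_measurement"))
  if (standard_amount <= 0) {
    stop("invalid-parameter: standard_amount must be positive", call. = FALSE)
  }
  per_scan <- function(m) {
    (m$integral / m$n_scans) / saturation_factor(m$flip_angle, m$TR, m$T1)
  }
  structure(list(atp_amount = standard_amount * per_scan(sample) / per_scan(standard),
                 standard_amount = standard_amount),
            class = "atp_quantification")
}

#' @export
print.atp_quantification <- function(x, ...) {
  cat(sprintf("<atp_quantification> %.4g nmole ATP (standard %.4g nmole)\n",
              x$atp_amount, x$standard_amount))
  invisible(x)
}

#' Probe-visible amount of an ATP standard
#'
#' @param volume_mL Probe-visible standard volume, mL (no default: it depends
#'   on the tube and coil geometry).
#' @param conc_mM Standard concentration, mM (default 111, the reference
#'   standard in D2O).
#' @return Amount in nmole.
#' @export
atp_standard_amount <- function(volume_mL, conc_mM = 111) {
  if (volume_mL <= 0 || conc_mM <= 0) {
    stop("invalid-parameter: volume and concentration must be positive",
         call. = FALSE)
  }
  conc_mM * volume_mL * 1000   # mM * mL = umole -> nmole
}

#' Convert a per-ATP rate to a per-tissue-mass rate
#'
#' Uses a literature conversion factor for tissue ATP content
#' (default 0.86 umole ATP per gram tissue):
#' nmole/min/nmole ATP x umole ATP/g = umole/g/min.
#'
#' @param per_atp_rate Rate in nmole/min per nmole ATP.
#' @param atp_per_gram Tissue ATP content, umole/g (default 0.86).
#' @return Rate in umole per gram tissue per minute.
#' @export
#' @examples
#' per_mass_rate(6.1)  # ~5.2 umole/g/min
per_mass_rate <- function(per_atp_rate, atp_per_gram = 0.86) {
  if (any(per_atp_rate < 0) || atp_per_gram < 0) {
    stop("invalid-parameter: inputs must be non-negative", call. = FALSE)
  }
  per_atp_rate * atp_per_gram
}

#' Hyperpolarized signal equivalence of a concentration
#'
#' Detectability bookkeeping: a concentration enhanced `enhancement`-fold by
#' dissolution-DNP gives the signal of `conc * enhancement` at thermal
#' equilibrium, expressed in molar.
#'
#' @param conc_mM Concentration in mM.
#' @param enhancement Signal enhancement factor (default 1e4).
#' @return Molar-equivalent signal (M).
#' @export
#' @examples
#' signal_equivalence(5.2)  # 52 M
signal_equivalence <- function(conc_mM, enhancement = 1e4) {
  if (any(conc_mM < 0) || enhancement <= 0) {
    stop("invalid-parameter: conc must be >= 0 and enhancement > 0",
         call. = FALSE)
  }
  conc_mM * enhancement / 1000
}
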