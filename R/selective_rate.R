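#' Fit precursor T1 from a pulsed decay under arrested perfusion
#'
#' With the precursor concentration constant (perfusion arrested) the pulsed
#' signal decays only through T1 and RF sampling:
#' `M(t) = M0 * exp(-t/T1) * cos(theta)^(t/TR)`. Both TR and the precursor's
#' effective nutation angle are known, so T1 and M0 are estimated by
#' nonlinear least squares.
#'
#' @param times Acquisition times, seconds (>= 5 samples).
#' @param intensities Precursor intensities, arbitrary units.
#' @param scheme An [acquisition_scheme()]; `nutation_precursor` is the
#'   effective angle the precursor experiences.
#' @param init Optional list with starting `T1` (s) and `M0`.
#' @return An object of class `"t1_estimate"`: `T1` (s), `M0`, `r2`.
#' @export
fit_t1_eq1 <- function(times, intensities, scheme, init = NULL) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  if (length(times) != length(intensities)) {
    stop("invalid-parameter: times/intensities lengths differ", call. = FALSE)
  }
  if (length(times) < 5L) {
    stop("invalid-parameter: need at least 5 samples", call. = FALSE)
  }
  th <- scheme$nutation_precursor
  if (th >= 90 && length(times) > 1L) {
    stop("degenerate-model: a 90 degree pulse nulls the signal after one excitation",
         call. = FALSE)
  }
  cth <- cos(th * pi / 180)
  if (is.null(init)) init <- list(T1 = 50, M0 = max(intensities))
  model <- function(M0, T1) {
    M0 * exp(-times / T1) * cth^(times / scheme$TR)
  }
  cf <- lm_fit(function(par) intensities - model(par[1], par[2]),
               c(init$M0, init$T1), "T1")
  structure(list(T1 = cf[2], M0 = cf[1],
                 r2 = r_squared(intensities, model(cf[1], cf[2]))),
            class = "t1_estimate")
}

#' @export
print.t1_estimate <- function(x, ...) {
  cat(sprintf("<t1_estimate> T1 = %.4g s, M0 = %.4g, R2 = %.4f\n",
              x$T1, x$M0, x$r2))
  invisible(x)
}

#' Decay-correct a precursor series
#'
#' Divides the precursor intensities by their decay envelope
#' `exp(-t/T1) * cos(theta_p)^(t/TR)` so that a series acquired at truly
#' constant precursor concentration maps to a constant. The T1 comes from
#' arrested-perfusion measurements of the same preparation. Points whose
#' correction factor exceeds `amplification_ceiling` (far into the decay,
#' where the correction mostly amplifies noise) are flagged unreliable but
#' kept.
#'
#' @param times Acquisition times, seconds.
#' @param intensities Precursor intensities.
#' @param T1 Precursor T1 in seconds (e.g. from [fit_t1_eq1()]).
#' @param scheme An [acquisition_scheme()].
#' @param include_rf Include the RF-loss term `cos(theta_p)^(t/TR)` in the
#'   envelope (default TRUE); FALSE reproduces a strictly-T1 correction.
#' @param amplification_ceiling Flag points whose correction factor exceeds
#'   this (default 20).
#' @return An object of class `"corrected_series"`: `times`, `corrected`,
#'   `reliable` (logical), and `window` (NULL until
#'   [select_constant_window()] is applied).
#' @export
correct_precursor_eq2 <- function(times, intensities, T1, scheme,
                                  include_rf = TRUE,
                                  amplification_ceiling = 20) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  if (T1 <= 0) stop("invalid-parameter: T1 must be positive", call. = FALSE)
  env <- exp(-times / T1)
  if (isTRUE(include_rf)) {
    env <- env * cos(scheme$nutation_precursor * pi / 180)^(times / scheme$TR)
  }
  structure(list(times = times,
                 corrected = intensities / env,
                 reliable = (1 / env) <= amplification_ceiling,
                 window = NULL),
            class = "corrected_series")
}

#' Select the constant-concentration window
#'
#' Implements the 10-percent-of-first-maximum rule: the first maximum of the
#' corrected precursor series is located (the first running maximum not
#' exceeded — beyond a small tie tolerance — within the next `guard` samples,
#' which tolerates noise spikes and the slow asymptotic tail of a well-mixed
#' build-up; in the arrested design this is simply the first point), and all
#' contiguous points from it whose relative difference from it is at most
#' `tol` are selected, stopping at the first violation.
#'
#' @param corrected A `"corrected_series"` from [correct_precursor_eq2()], or
#'   a numeric vector of corrected intensities.
#' @param tol Relative tolerance (default 0.10).
#' @param guard Number of subsequent samples that must not exceed a candidate
#'   first maximum (default 2).
#' @param tie_tol Relative excess below which a later sample does not
#'   disqualify a candidate maximum (default 0.02; must be < `tol`).
#' @return Integer indices of the window (1-based). When `corrected` is a
#'   `"corrected_series"` the object is returned with its `window` field set.
#' @export
#' @examples
#' select_constant_window(c(100, 99, 95, 91, 89, 60))  # 1:4
select_constant_window <- function(corrected, tol = 0.10, guard = 2L,
                                   tie_tol = 0.02) {
  v <- if (inherits(corrected, "corrected_series")) corrected$corrected
       else corrected
  n <- length(v)
  if (n < 3L) stop("invalid-parameter: need at least 3 corrected points",
                   call. = FALSE)
  if (tie_tol >= tol) stop("invalid-parameter: tie_tol must be < tol",
                           call. = FALSE)
  peak <- NA_integer_
  for (i in seq_len(n)) {
    if (v[i] < max(v[seq_len(i)]) * (1 - tie_tol)) next  # well below running max
    ahead <- v[seq(i + 1L, min(i + guard, n))]
    if (i == n || all(ahead <= v[i] * (1 + tie_tol))) { peak <- i; break }
  }
  if (is.na(peak)) stop("no-plateau: no first maximum found", call. = FALSE)
  idx <- peak
  j <- peak + 1L
  while (j <= n && abs(v[j] - v[peak]) / v[peak] <= tol) {
    idx <- c(idx, j)
    j <- j + 1L
  }
  if (inherits(corrected, "corrected_series")) {
    corrected$window <- idx
    corrected
  } else {
    idx
  }
}

#' Per-excitation lactate production rate
#'
#' The selective-excitation rate formula: each excitation reads only the
#' product accumulated over one TR, so the rate per nmole of tissue ATP is
#' \deqn{v = \frac{S_{lac}}{S_{pyr}} \cdot \rho \cdot
#'           \frac{[Pyr] \cdot V_{medium}}{TR \cdot n_{ATP}}}
#' computed per second and reported per minute. `rho` converts the observed
#' signal ratio into a concentration ratio: the precursor-to-product response
#' ratio of the selective pulse (see [response_ratio()]); 1 for a
#' non-selective pulse.
#'
#' @param S_lac Product intensity (a.u.), vectorized over windowed samples.
#' @param S_pyr Precursor intensity (a.u.), same length.
#' @param pyr_conc Hyperpolarized precursor concentration, mM.
#' @param rho Response ratio from [response_ratio()] or measured.
#' @param TR Repetition time, s.
#' @param V_medium Probe-visible medium volume, mL.
#' @param atp Tissue ATP in the probe-visible volume, nmole.
#' @param noise_floor Points with `S_pyr` at or below it become `NA` and are
#'   reported with a message (default 0).
#' @return Rates in nmole/min per nmole ATP, one per input point.
#' @export
#' @examples
#' rate_eq3(S_lac = 1.987e-3, S_pyr = 1, pyr_conc = 14, rho = 1,
#'          TR = 12, V_medium = 0.5, atp = 11.4)  # ~6.1
rate_eq3 <- function(S_lac, S_pyr, pyr_conc, rho, TR, V_medium, atp,
                     noise_floor = 0) {
  if (any(S_lac < 0)) stop("invalid-parameter: S_lac must be >= 0",
                           call. = FALSE)
  if (pyr_conc <= 0 || rho <= 0 || TR <= 0 || V_medium <= 0 || atp <= 0) {
    stop("invalid-parameter: pyr_conc, rho, TR, V_medium, atp must be positive",
         call. = FALSE)
  }
  bad <- S_pyr <= noise_floor
  if (any(bad)) {
    message(sprintf("rate_eq3: excluding %d point(s) with precursor at or below the noise floor",
                    sum(bad)))
  }
  pyr_nmole <- pyr_conc * V_medium * 1000   # mM * mL = umole -> nmole
  v <- (S_lac / S_pyr) * rho * pyr_nmole / (TR * atp) * 60
  v[bad] <- NA_real_
  v
}

#' Aggregate per-point rates over the stabilized plateau
#'
#' The per-point rates typically rise while product delivery stabilizes and
#' then plateau; the reported maximal rate is the mean over the plateau.
#' Plateau membership: the contiguous run of points around the maximum whose
#' rate is within `stabilization_tol` of the maximum rate.
#'
#' @param rates Per-point rates (NA allowed; NA points never enter the
#'   plateau).
#' @param stabilization_tol Relative tolerance defining the plateau
#'   (default 0.15).
#' @return An object of class `"rate_result"`: `per_point_rates`,
#'   `mean_rate`, `sd_rate`, `stabilized_indices`, `units`.
#' @export
aggregate_rates <- function(rates, stabilization_tol = 0.15) {
  ok <- !is.na(rates)
  if (!any(ok)) stop("no-plateau: all rates are NA", call. = FALSE)
  vmax <- max(rates[ok])
  imax <- which(ok & rates == vmax)[1]
  inset <- function(i) ok[i] && abs(rates[i] - vmax) / vmax <= stabilization_tol
  lo <- imax
  while (lo > 1L && inset(lo - 1L)) lo <- lo - 1L
  hi <- imax
  while (hi < length(rates) && inset(hi + 1L)) hi <- hi + 1L
  idx <- lo:hi
  structure(list(per_point_rates = rates,
                 mean_rate = mean(rates[idx]),
                 sd_rate = stats::sd(rates[idx]),
                 stabilized_indices = idx,
                 units = "nmole/min per nmole ATP"),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("<rate_result> mean %.3g +- %.3g %s over %d plateau points (of %d)\n",
              x$mean_rate, x$sd_rate, x$units,
              length(x$stabilized_indices), length(x$per_point_rates)))
  invisible(x)
}
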