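#' Describe an RF excitation pulse
#'
#' Constructs the description of a hard (rectangular) or shaped cardinal-sine
#' (sinc) excitation pulse. The amplitude is calibrated so that the
#' on-resonance nutation equals `calibrated_angle`; selective excitation of one
#' resonance while barely perturbing another (e.g. lactate vs. pyruvate 214 Hz
#' away) is obtained with a long sinc pulse calibrated to ~90 degrees.
#'
#' @param kind `"hard"` or `"sinc"`.
#' @param duration Pulse length in seconds (e.g. `2.5e-3` for the selective
#'   sinc pulse).
#' @param calibrated_angle On-resonance nutation angle in degrees, in
#'   (0, 180].
#' @param lobes Number of sinc side-lobe pairs (ignored for hard pulses).
#'
#' @return An object of class `"pulse_shape"`.
#' @export
#' @examples
#' pulse_shape("sinc", 2.5e-3, calibrated_angle = 90)
pulse_shape <- function(kind = c("hard", "sinc"), duration,
                        calibrated_angle, lobes = 3L) {
  kind <- match.arg(kind)
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0) {
    stop("invalid-parameter: 'duration' must be a positive finite scalar",
         call. = FALSE)
  }
  if (!is.numeric(calibrated_angle) || length(calibrated_angle) != 1L ||
      calibrated_angle <= 0 || calibrated_angle > 180) {
    stop("invalid-parameter: 'calibrated_angle' must be in (0, 180] degrees",
         call. = FALSE)
  }
  lobes <- as.integer(lobes)
  if (kind == "sinc" && (is.na(lobes) || lobes < 0L)) {
    stop("invalid-parameter: 'lobes' must be a non-negative integer",
         call. = FALSE)
  }
  structure(
    list(kind = kind, duration = duration,
         calibrated_angle = calibrated_angle, lobes = lobes),
    class = "pulse_shape"
  )
}

#' @export
print.pulse_shape <- function(x, ...) {
  cat(sprintf("<pulse_shape> %s, %.4g ms, calibrated %.3g deg%s\n",
              x$kind, x$duration * 1e3, x$calibrated_angle,
              if (x$kind == "sinc") sprintf(", %d side-lobe pairs", x$lobes)
              else ""))
  invisible(x)
}

# Discretized B1 envelope in rad/s at `steps` midpoints, scaled so the
# on-resonance rotation sum(omega1 * dt) equals the calibrated angle exactly
# at this discretization.
pulse_envelope <- function(shape, steps) {
  dt <- shape$duration / steps
  tau <- (seq_len(steps) - 0.5) * dt
  if (shape$kind == "hard") {
    env <- rep(1, steps)
  } else {
    # sinc argument spans +-(lobes + 1) * pi across the pulse
    x <- ((2 * tau / shape$duration) - 1) * (shape$lobes + 1L) * pi
    env <- ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  }
  theta <- shape$calibrated_angle * pi / 180
  omega1 <- env * theta / (sum(env) * dt)
  list(omega1 = omega1, dt = dt)
}

#' Simulate the off-resonance response of an excitation pulse
#'
#' Integrates the Bloch rotations of the piecewise-constant discretized pulse
#' envelope (no relaxation during the pulse; at 2.5 ms against T1 of tens of
#' seconds the error is below 0.02 percent) and returns, per offset, the
#' fraction of longitudinal magnetization converted to detectable transverse
#' signal.
#'
#' At each time step the magnetization is rotated about the effective field
#' `(omega1(t), 0, 2*pi*offset)`; the envelope is calibrated so the
#' on-resonance response equals `sin(calibrated_angle)` exactly.
#'
#' @param shape A [pulse_shape()].
#' @param offsets Resonance offsets in Hz (finite numeric vector).
#' @param steps Number of envelope discretization steps (default 2000; a
#'   convergence check is to double it and require the response to move by
#'   less than 1e-4).
#'
#' @return An object of class `"pulse_response"`: a list with `offsets`,
#'   `transverse_response` (in \[0, 1\]), `effective_angle` (degrees,
#'   `asin` of the response) and the generating `shape`.
#' @export
#' @examples
#' sel <- pulse_shape("sinc", 2.5e-3, 90)
#' simulate_pulse(sel, offsets = c(0, 214))
simulate_pulse <- function(shape, offsets, steps = 2000L) {
  stopifnot(inherits(shape, "pulse_shape"))
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 100L) {
    stop("invalid-parameter: 'steps' must be an integer >= 100", call. = FALSE)
  }
  if (!is.numeric(offsets) || length(offsets) == 0L || !all(is.finite(offsets))) {
    stop("invalid-parameter: 'offsets' must be finite numeric", call. = FALSE)
  }
  env <- pulse_envelope(shape, steps)
  dw <- 2 * pi * offsets            # rad/s, one per offset
  mx <- numeric(length(offsets))
  my <- numeric(length(offsets))
  mz <- rep(1, length(offsets))
  for (i in seq_len(steps)) {
    w1 <- env$omega1[i]
    wn <- sqrt(w1^2 + dw^2)
    phi <- wn * env$dt
    # rotation axis (w1, 0, dw)/wn; Rodrigues rotation of (mx, my, mz)
    ax <- ifelse(wn > 0, w1 / wn, 1)
    az <- ifelse(wn > 0, dw / wn, 0)
    cphi <- cos(phi)
    sphi <- sin(phi)
    dot <- ax * mx + az * mz
    cx <- -az * my            # axis x M  (axis y-component is zero)
    cy <- az * mx - ax * mz
    cz <- ax * my
    mx2 <- mx * cphi + cx * sphi + ax * dot * (1 - cphi)
    my2 <- my * cphi + cy * sphi
    mz2 <- mz * cphi + cz * sphi + az * dot * (1 - cphi)
    mx <- mx2; my <- my2; mz <- mz2
  }
  resp <- pmin(sqrt(mx^2 + my^2), 1)
  structure(
    list(offsets = offsets,
         transverse_response = resp,
         effective_angle = asin(resp) * 180 / pi,
         shape = shape,
         steps = steps),
    class = "pulse_response"
  )
}

#' @export
print.pulse_response <- function(x, ...) {
  cat(sprintf("<pulse_response> %s pulse, %d offsets, steps = %d\n",
              x$shape$kind, length(x$offsets), x$steps))
  print(utils::head(data.frame(offset_Hz = x$offsets,
                               response = x$transverse_response,
                               effective_angle_deg = x$effective_angle), 10))
  invisible(x)
}

#' Relative response ratio rho of a selective pulse
#'
#' Computes rho, the factor that converts the observed product/precursor
#' signal ratio into a magnetization (concentration) ratio in the
#' per-excitation rate formula. Since each observed signal is
#' `response * longitudinal magnetization`, that factor is the ratio of the
#' precursor's to the product's response to the same pulse:
#' `rho = response(precursor_offset) / response(product_offset)`. For the
#' selective lactate readout the pulse is centered on the product
#' (`product_offset = 0`, full excitation) and the precursor sits 214 Hz
#' off-resonance, so rho <= 1; for a non-selective pulse rho = 1.
#'
#' @param product_offset Offset of the product resonance from the pulse
#'   center, Hz.
#' @param precursor_offset Offset of the precursor resonance, Hz.
#' @param shape A [pulse_shape()]; both responses are simulated with the same
#'   shape and step count.
#' @param steps Discretization steps passed to [simulate_pulse()].
#' @param floor Smallest admissible precursor response; below it the ratio is
#'   considered degenerate and an error is raised.
#'
#' @return The scalar rho (> 0).
#' @export
#' @examples
#' response_ratio(0, 214, pulse_shape("sinc", 2.5e-3, 90))
response_ratio <- function(product_offset, precursor_offset, shape,
                           steps = 2000L, floor = 1e-6) {
  sim <- simulate_pulse(shape, c(product_offset, precursor_offset), steps)
  rp <- sim$transverse_response[1]
  rq <- sim$transverse_response[2]
  if (rq < floor) {
    stop(sprintf(
      "degenerate-ratio: precursor response %.3g below floor %.3g", rq, floor),
      call. = FALSE)
  }
  rq / rp
}

#' Write a pulse offset/response profile as a two-column text table
#'
#' @param response A `"pulse_response"` from [simulate_pulse()].
#' @param path Output file path.
#' @export
write_pulse_profile <- function(response, path) {
  stopifnot(inherits(response, "pulse_response"))
  utils::write.table(
    data.frame(offset_Hz = response$offsets,
               response = response$transverse_response),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
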