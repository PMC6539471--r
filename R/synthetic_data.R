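#' Probe/perfusion geometry of a slice experiment
#'
#' Default volumes follow the reference setup: 0.5 mL medium and 0.9 mL
#' tissue visible to the probe, 1.4 mL total, with 14 mM hyperpolarized
#' pyruvate in the medium.
#'
#' @param V_medium Probe-visible medium volume, mL.
#' @param V_tissue Probe-visible tissue volume, mL.
#' @param V_total Total probe-visible volume, mL; must equal
#'   `V_medium + V_tissue`.
#' @param pyr_conc Hyperpolarized pyruvate concentration, mM.
#' @return An object of class `"experiment_geometry"`.
#' @export
experiment_geometry <- function(V_medium = 0.5, V_tissue = 0.9,
                                V_total = V_medium + V_tissue,
                                pyr_conc = 14) {
  if (V_medium <= 0 || V_tissue <= 0 || pyr_conc <= 0) {
    stop("invalid-parameter: volumes and concentration must be positive",
         call. = FALSE)
  }
  if (abs(V_medium + V_tissue - V_total) > 1e-9) {
    stop("invalid-parameter: V_medium + V_tissue must equal V_total",
         call. = FALSE)
  }
  structure(list(V_medium = V_medium, V_tissue = V_tissue,
                 V_total = V_total, pyr_conc = pyr_conc),
            class = "experiment_geometry")
}

#' Delivery profile of a continuous-flow experiment
#'
#' The hyperpolarized medium arrives, builds up, holds a steady inlet
#' concentration for `steady_duration` (set by hyperpolarized volume over
#' flow rate; 12 mL at 4 mL/min gives 180 s), then is washed out. The probe
#' volume is modelled as a single well-mixed compartment with exchange rate
#' `washout_rate` (default flow/V_total = (4/60)/1.4 per second).
#'
#' @param arrival_time Arrival of the agent at the probe, s after the first
#'   excitation.
#' @param buildup_duration Linear inlet ramp duration, s.
#' @param steady_duration Constant inlet phase, s.
#' @param washout_rate Compartment exchange rate, 1/s.
#' @return An object of class `"flow_profile"`.
#' @export
flow_profile <- function(arrival_time = 10, buildup_duration = 50,
                         steady_duration = 180,
                         washout_rate = (4 / 60) / 1.4) {
  if (arrival_time < 0 || buildup_duration < 0 || steady_duration < 0) {
    stop("invalid-parameter: durations must be non-negative", call. = FALSE)
  }
  if (washout_rate <= 0) {
    stop("invalid-parameter: washout_rate must be positive", call. = FALSE)
  }
  structure(list(arrival_time = arrival_time,
                 buildup_duration = buildup_duration,
                 steady_duration = steady_duration,
                 washout_rate = washout_rate),
            class = "flow_profile")
}

#' Additive intensity noise model
#'
#' @param sigma Gaussian noise level. For time series this is an additive
#'   standard deviation in the intensity units; for 31P integral pairs it is
#'   relative (fraction of the integral).
#' @param seed Optional integer; identical seeds give identical datasets.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(sigma = 0, seed = NULL) {
  if (sigma < 0) stop("invalid-parameter: sigma must be >= 0", call. = FALSE)
  structure(list(sigma = sigma, seed = seed), class = "noise_model")
}

apply_seed <- function(noise) {
  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
  invisible(NULL)
}

#' Synthetic arrested-perfusion series, non-selective acquisition
#'
#' Emulates the bolus design with non-selective pulses: constant precursor
#' concentration (perfusion stopped), signals from the two-pool model
#' ([simulate_two_pool()]), plus additive Gaussian noise. With `sigma = 0`
#' the series equals the noiseless simulation exactly.
#'
#' @param params A [kinetic_params()] (the ground truth).
#' @param scheme An [acquisition_scheme()] (non-selective: equal angles).
#' @param geometry An [experiment_geometry()], recorded in the truth record.
#' @param noise A [noise_model()].
#' @return A list of class `"hp_synth"`: `series` (an [hp_series()]) and
#'   `truth` (all generator parameters).
#' @export
generate_arrest_nonselective <- function(params, scheme,
                                         geometry = experiment_geometry(),
                                         noise = noise_model()) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(scheme, "acquisition_scheme"),
            inherits(noise, "noise_model"))
  clean <- simulate_two_pool(params, scheme)
  apply_seed(noise)
  n <- length(clean$times)
  series <- hp_series(clean$times,
                      clean$precursor + stats::rnorm(n, 0, noise$sigma),
                      clean$product + stats::rnorm(n, 0, noise$sigma),
                      clean$precursor_z, clean$product_z)
  structure(list(series = series,
                 truth = list(design = "arrest_nonselective",
                              params = params, scheme = scheme,
                              geometry = geometry, noise = noise)),
            class = "hp_synth")
}

# Precursor longitudinal magnetization before pulse m (1-based) of a pulse
# train at times `times`, having decayed since injection at -pre_delay.
selective_precursor_z <- function(params, times, theta_p_deg, pre_delay) {
  cth <- cos(theta_p_deg * pi / 180)
  params$M0 * exp(-(times + pre_delay) / params$T1_precursor) *
    cth^(seq_along(times) - 1L)
}

#' Synthetic arrested-perfusion series, selective acquisition
#'
#' Emulates the bolus design with selective 90-degree product readout: each
#' excitation nulls the product pool, which re-accumulates from the precursor
#' over the next repetition interval, so every sample reads only newly
#' produced lactate. The precursor is depleted only by its small effective
#' angle and T1. An initial block of `quench` rapid excitations (repetition
#' time `quench_TR`) discards product accumulated since injection; with
#' `quench = 0` the first analysis sample is inflated by that pre-accumulated
#' product.
#'
#' @param params A [kinetic_params()].
#' @param scheme An [acquisition_scheme()] for the analysis block
#'   (`nutation_product` should be 90, `nutation_precursor` small, TR
#'   typically 8-16 s).
#' @param geometry An [experiment_geometry()].
#' @param noise A [noise_model()].
#' @param quench Number of initial quench excitations (default 4).
#' @param quench_TR Repetition time of the quench block, s (default 2).
#' @param pre_delay Time between injection and the first excitation, s
#'   (default 5).
#' @return A list of class `"hp_synth"`: `series` covering quench plus
#'   analysis excitations, `quench_mask` (logical, TRUE for quench samples)
#'   and `truth`.
#' @export
generate_arrest_selective <- function(params, scheme,
                                      geometry = experiment_geometry(),
                                      noise = noise_model(),
                                      quench = 4L, quench_TR = 2,
                                      pre_delay = 5) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(scheme, "acquisition_scheme"))
  quench <- as.integer(quench)
  if (quench < 0L || quench_TR <= 0 || pre_delay < 0) {
    stop("invalid-parameter: quench >= 0, quench_TR > 0, pre_delay >= 0",
         call. = FALSE)
  }
  thl <- scheme$nutation_product
  if (thl < 89 || thl > 90) {
    warning("selective design expects a ~90 degree product readout")
  }
  tq <- if (quench > 0L) (seq_len(quench) - 1L) * quench_TR else numeric(0)
  t0 <- if (quench > 0L) (quench - 1L) * quench_TR + scheme$TR else 0
  ta <- t0 + (seq_len(scheme$n_samples) - 1L) * scheme$TR
  times <- c(tq, ta)
  P <- selective_precursor_z(params, times, scheme$nutation_precursor,
                             pre_delay)
  cthp <- cos(scheme$nutation_precursor * pi / 180)
  # product re-accumulates from zero over each inter-pulse interval
  L <- numeric(length(times))
  gaps <- c(pre_delay, diff(times))
  for (m in seq_along(times)) {
    P_start <- if (m == 1L) {
      params$M0                      # at injection, before any pulse
    } else {
      P[m - 1L] * cthp               # just after the previous pulse
    }
    L[m] <- params$k_1st * P_start *
      product_kernel(gaps[m], params$T1_precursor, params$T1_product)
  }
  sin_l <- sin(thl * pi / 180)
  apply_seed(noise)
  series <- hp_series(
    times,
    precursor = sin(scheme$nutation_precursor * pi / 180) * P +
      stats::rnorm(length(times), 0, noise$sigma),
    product = sin_l * L + stats::rnorm(length(times), 0, noise$sigma),
    precursor_z = P, product_z = L)
  structure(list(series = series,
                 quench_mask = c(rep(TRUE, quench),
                                 rep(FALSE, scheme$n_samples)),
                 truth = list(design = "arrest_selective", params = params,
                              scheme = scheme, geometry = geometry,
                              noise = noise, quench = quench,
                              quench_TR = quench_TR, pre_delay = pre_delay)),
            class = "hp_synth")
}

#' Synthetic continuous-flow series, selective acquisition
#'
#' Emulates continuous delivery of hyperpolarized medium: the inlet
#' concentration ramps up, holds steady and shuts off per the
#' [flow_profile()]; the probe volume responds as a single well-mixed
#' compartment, producing the build-up / steady-state / wash-out shape of the
#' precursor. Signals include T1 decay and per-pulse RF losses; the product
#' is generated from the instantaneous precursor magnetization with a
#' selective 90-degree readout each TR. An optional `spike` reproduces the
#' small rise sometimes seen between plateau and wash-out from inflow of
#' less-depolarized material left in the line (default off).
#'
#' @param params A [kinetic_params()].
#' @param scheme An [acquisition_scheme()] (selective).
#' @param geometry An [experiment_geometry()].
#' @param flow A [flow_profile()].
#' @param noise A [noise_model()].
#' @param spike Relative amplitude of the post-plateau inflow spike
#'   (default 0 = off).
#' @param spike_duration Spike length, s.
#' @param dt Integration grid step, s.
#' @return A list of class `"hp_synth"`: `series`, `truth` (including
#'   `steady_corrected`, the decay-corrected plateau level, and
#'   `steady_onset`, the end of the build-up).
#' @export
generate_continuous_flow <- function(params, scheme,
                                     geometry = experiment_geometry(),
                                     flow = flow_profile(),
                                     noise = noise_model(),
                                     spike = 0, spike_duration = 10,
                                     dt = 0.02) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(scheme, "acquisition_scheme"),
            inherits(flow, "flow_profile"))
  n <- scheme$n_samples
  TR <- scheme$TR
  t_end <- (n - 1L) * TR
  grid <- seq(0, t_end, by = dt)
  # inlet relative concentration
  u <- numeric(length(grid))
  tb <- flow$arrival_time
  te <- tb + flow$buildup_duration
  ts <- te + flow$steady_duration
  ramp <- grid > tb & grid < te
  if (flow$buildup_duration > 0) u[ramp] <- (grid[ramp] - tb) / (te - tb)
  u[grid >= te & grid <= ts] <- 1
  if (spike > 0) u[grid > ts & grid <= ts + spike_duration] <- spike
  # well-mixed compartment, exact exponential update per step
  C <- numeric(length(grid))
  ef <- exp(-flow$washout_rate * dt)
  for (i in seq_along(grid)[-1]) {
    C[i] <- u[i - 1L] + (C[i - 1L] - u[i - 1L]) * ef
  }
  thp <- scheme$nutation_precursor * pi / 180
  npulses <- pmin(floor(grid / TR) + 1L, n)   # pulses applied at or before t
  Pz_grid <- params$M0 * C * exp(-grid / params$T1_precursor) *
    cos(thp)^(npulses)
  # magnetization read at pulse times: before the pulse acts
  ti <- round((seq_len(n) - 1L) * TR / dt) + 1L
  nprev <- seq_len(n) - 1L
  Pz <- params$M0 * C[ti] * exp(-(nprev * TR) / params$T1_precursor) *
    cos(thp)^nprev
  # product accumulated over each inter-pulse interval (reset by 90 readout)
  L <- numeric(n)
  for (m in seq_len(n)[-1]) {
    seg <- ti[m - 1L]:ti[m]
    s <- grid[seg]
    w <- exp(-(grid[ti[m]] - s) / params$T1_product)
    f <- params$k_1st * Pz_grid[seg] * w
    L[m] <- sum((f[-1] + f[-length(f)]) / 2) * dt
  }
  apply_seed(noise)
  sin_l <- sin(scheme$nutation_product * pi / 180)
  series <- hp_series(
    (seq_len(n) - 1L) * TR,
    precursor = sin(thp) * Pz + stats::rnorm(n, 0, noise$sigma),
    product = sin_l * L + stats::rnorm(n, 0, noise$sigma),
    precursor_z = Pz, product_z = L)
  structure(list(series = series,
                 truth = list(design = "continuous_flow", params = params,
                              scheme = scheme, geometry = geometry,
                              flow = flow, noise = noise, spike = spike,
                              steady_corrected = sin(thp) * params$M0,
                              inlet_steady_onset = te,
                              # probe concentration reaches within 10% of its
                              # plateau (build-up end as seen by the probe)
                              steady_onset = grid[which(C >= 0.9 * max(C))[1]],
                              washout_onset = ts)),
            class = "hp_synth")
}

#' Synthetic 31P sample/standard measurement pair
#'
#' Generates a gamma-ATP integral for a sample of known ATP amount and an
#' integral for an external standard, under their respective acquisition
#' metadata, with optional relative Gaussian noise on both integrals.
#' Round-tripping through [quantify_atp()] recovers the true amount exactly
#' at `sigma = 0`.
#'
#' @param true_amount Ground-truth sample ATP, nmole.
#' @param sample_meta List with `flip_angle`, `TR`, `n_scans`, `T1` for the
#'   sample acquisition.
#' @param standard_meta Same for the standard acquisition.
#' @param standard_amount Standard ATP amount, nmole.
#' @param noise A [noise_model()] (`sigma` is relative here).
#' @param scale Common spectrometer intensity scale (cancels in
#'   quantification).
#' @return A list of class `"p31_synth"`: `sample` and `standard`
#'   ([p31_measurement()]s), `standard_amount`, `truth`.
#' @export
generate_p31_pair <- function(true_amount, sample_meta, standard_meta,
                              standard_amount, noise = noise_model(),
                              scale = 1) {
  if (true_amount <= 0 || standard_amount <= 0 || scale <= 0) {
    stop("invalid-parameter: amounts and scale must be positive",
         call. = FALSE)
  }
  apply_seed(noise)
  mk <- function(amount, meta) {
    f <- saturation_factor(meta$flip_angle, meta$TR, meta$T1)
    integral <- scale * amount * f * meta$n_scans *
      (1 + stats::rnorm(1, 0, noise$sigma))
    p31_measurement(integral, meta$flip_angle, meta$TR, meta$n_scans, meta$T1)
  }
  structure(list(sample = mk(true_amount, sample_meta),
                 standard = mk(standard_amount, standard_meta),
                 standard_amount = standard_amount,
                 truth = list(true_amount = true_amount, noise = noise)),
            class = "p31_synth")
}
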