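# Independent brute-force oracles. These deliberately re-derive everything
# from scratch (fine-grid Euler integration, explicit rotation matrices,
# long pulse-train recursion) and share no propagation code with the package.

# Fine-grid Euler integration of the two-pool model with per-pulse cosine
# losses. Returns before-pulse signals at sample times 0, TR, ..., like
# simulate_two_pool().
oracle_euler_two_pool <- function(k, T1p, T1l, M0, TR, theta_p_deg,
                                  theta_l_deg, n_samples, dt = 1e-3) {
  thp <- theta_p_deg * pi / 180
  thl <- theta_l_deg * pi / 180
  P <- M0
  L <- 0
  sp <- numeric(n_samples)
  sl <- numeric(n_samples)
  nstep <- round(TR / dt)
  for (i in seq_len(n_samples)) {
    sp[i] <- sin(thp) * P
    sl[i] <- sin(thl) * L
    if (i == n_samples) break
    P <- P * cos(thp)
    L <- L * cos(thl)
    for (s in seq_len(nstep)) {
      dL <- k * P - L / T1l
      dP <- -P / T1p
      P <- P + dP * dt
      L <- L + dL * dt
    }
  }
  list(precursor = sp, product = sl)
}

# Explicit rotation-matrix Bloch integration of a pulse envelope at one
# offset. The envelope is re-derived here from the pulse description.
oracle_bloch_response <- function(kind, duration, calibrated_angle_deg,
                                  lobes, offset_hz, steps = 1e5) {
  dt <- duration / steps
  tau <- (seq_len(steps) - 0.5) * dt
  if (kind == "hard") {
    env <- rep(1, steps)
  } else {
    x <- ((2 * tau / duration) - 1) * (lobes + 1) * pi
    env <- ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  }
  theta <- calibrated_angle_deg * pi / 180
  w1 <- env * theta / (sum(env) * dt)
  dw <- 2 * pi * offset_hz
  rotmat <- function(axis, phi) {
    K <- matrix(c(0, -axis[3], axis[2],
                  axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    diag(3) + sin(phi) * K + (1 - cos(phi)) * (K %*% K)
  }
  M <- c(0, 0, 1)
  for (i in seq_len(steps)) {
    wn <- sqrt(w1[i]^2 + dw^2)
    if (wn == 0) next
    M <- rotmat(c(w1[i], 0, dw) / wn, wn * dt) %*% M
  }
  sqrt(M[1]^2 + M[2]^2)
}

# Magnitude of the Fourier transform of the pulse envelope at an offset,
# normalized to its on-resonance value (small-tip-angle excitation limit).
oracle_fourier_profile <- function(kind, duration, lobes, offset_hz,
                                   steps = 2e4) {
  dt <- duration / steps
  tau <- (seq_len(steps) - 0.5) * dt
  if (kind == "hard") {
    env <- rep(1, steps)
  } else {
    x <- ((2 * tau / duration) - 1) * (lobes + 1) * pi
    env <- ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  }
  ft <- sum(env * exp(-2i * pi * offset_hz * tau)) * dt
  Mod(ft) / (sum(env) * dt)
}

# Steady-state signal per scan relative to a relaxed 90-degree scan, by
# iterating the pulse train until stationary.
oracle_saturation <- function(flip_angle_deg, TR, T1, n_pulses = 1e4) {
  th <- flip_angle_deg * pi / 180
  E <- exp(-TR / T1)
  Mz <- 1
  for (i in seq_len(n_pulses)) {
    Mz <- (1 - E) + E * Mz * cos(th)
  }
  Mz * sin(th)
}

# Vectorized over a parameter grid (same recursion, all cells at once).
oracle_saturation_grid <- function(flip_angle_deg, TR_over_T1,
                                   n_pulses = 1e4) {
  th <- flip_angle_deg * pi / 180
  E <- exp(-TR_over_T1)
  Mz <- rep(1, length(th))
  for (i in seq_len(n_pulses)) {
    Mz <- (1 - E) + E * Mz * cos(th)
  }
  Mz * sin(th)
}

# Trapezoid quadrature of k * integral P(s) exp(-(t-s)/T1l) ds over one
# repetition interval, for the selective-readout product signal.
oracle_selective_accumulation <- function(k, P_start, T1p, T1l, tau,
                                          n = 2e4) {
  s <- seq(0, tau, length.out = n)
  f <- k * P_start * exp(-s / T1p) * exp(-(tau - s) / T1l)
  sum((f[-1] + f[-n]) / 2) * (tau - 0) / (n - 1)
}

# Expected per-excitation rate (nmole/min per nmole ATP) that the selective
# chain should report for windowed samples of a synthetic series: computed
# directly from the generator's magnetization columns, independent of
# rate_eq3's implementation.
oracle_expected_rate <- function(synth, window_idx, pyr_conc, V_medium, atp,
                                 TR) {
  Pz <- synth$series$precursor_z[window_idx]
  Lz <- synth$series$product_z[window_idx]
  mean(Lz / Pz) * pyr_conc * V_medium * 1000 / (TR * atp) * 60
}
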