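sel_scheme <- function(TR = 8, theta_p = 5, n = 12) {
  acquisition_scheme(TR, theta_p, 90, n_samples = n)
}

pulsed_decay <- function(M0, T1, theta_deg, TR, n) {
  t <- (seq_len(n) - 1) * TR
  list(t = t, y = M0 * exp(-t / T1) * cos(theta_deg * pi / 180)^(t / TR))
}

test_that("pulsed-decay T1 fit recovers the generating T1", {
  # pure exponential (theta = 0)
  d <- pulsed_decay(1, 53.4, 0, 8, 12)
  f <- fit_t1_eq1(d$t, d$y, sel_scheme(theta_p = 0))
  expect_equal(f$T1, 53.4, tolerance = 1e-6)
  # with RF losses included
  d <- pulsed_decay(2.5, 50, 5, 8, 10)
  f <- fit_t1_eq1(d$t, d$y, sel_scheme())
  expect_equal(f$T1, 50, tolerance = 1e-6)
  expect_equal(f$M0, 2.5, tolerance = 1e-6)
  expect_gt(f$r2, 1 - 1e-12)
})

test_that("decay attributable to RF alone yields an effectively infinite T1", {
  d <- pulsed_decay(1, 1e9, 5, 8, 12)
  f <- fit_t1_eq1(d$t, d$y, sel_scheme())
  expect_gte(f$T1, 1e6)
})

test_that("a 90-degree precursor angle is a degenerate T1 model", {
  d <- pulsed_decay(1, 50, 5, 8, 12)
  expect_error(fit_t1_eq1(d$t, d$y, sel_scheme(theta_p = 90)),
               "degenerate-model")
})

test_that("decay correction inverts the decay law exactly", {
  sc <- sel_scheme(n = 15)
  d <- pulsed_decay(3, 53.4, 5, 8, 15)
  corr <- correct_precursor_eq2(d$t, d$y, 53.4, sc)
  expect_equal(corr$corrected, rep(3, 15), tolerance = 1e-9)
  # strictly-T1 correction flag: residual cos-term decay remains
  corr2 <- correct_precursor_eq2(d$t, d$y, 53.4, sc, include_rf = FALSE)
  expect_true(all(diff(corr2$corrected) < 0))
})

test_that("a washed-out tail stays strictly decreasing after correction", {
  sc <- sel_scheme(n = 10)
  d <- pulsed_decay(1, 53.4, 5, 8, 10)
  washout <- d$y * exp(-0.05 * d$t)
  corr <- correct_precursor_eq2(d$t, washout, 53.4, sc)
  expect_true(all(diff(corr$corrected) < 0))
})

test_that("correction factors beyond the amplification ceiling are flagged", {
  sc <- sel_scheme(n = 40)
  d <- pulsed_decay(1, 53.4, 5, 8, 40)
  corr <- correct_precursor_eq2(d$t, d$y, 53.4, sc, amplification_ceiling = 20)
  expect_true(any(!corr$reliable))
  expect_true(all(which(!corr$reliable) > max(which(corr$reliable))))
})

test_that("window selection applies the 10% rule exactly", {
  expect_identical(select_constant_window(c(100, 99, 95, 91, 89, 60)), 1:4)
  # constant series: every point selected
  expect_identical(select_constant_window(rep(5, 8)), 1:8)
  expect_error(select_constant_window(c(1, 2)), "invalid-parameter")
})

test_that("window selection is idempotent", {
  set.seed(7)
  rise <- 1 - exp(-(0:24) / 4)
  v <- c(rise, rep(1, 10) + rnorm(10, 0, 0.005), exp(-(1:8) / 3))
  w <- select_constant_window(v)
  w2 <- select_constant_window(v[w])
  expect_identical(v[w][w2], v[w])
  expect_identical(w2, seq_along(w))
})

test_that("per-excitation rate formula reproduces the worked arithmetic", {
  v <- rate_eq3(S_lac = 1.987e-3, S_pyr = 1, pyr_conc = 14, rho = 1,
                TR = 12, V_medium = 0.5, atp = 11.4)
  expect_equal(v, 6.1, tolerance = 0.01)
  expect_identical(rate_eq3(0, 1, 14, 1, 12, 0.5, 11.4), 0)
})

test_that("rate is linear in its numerator terms and inverse in TR and ATP", {
  base <- rate_eq3(2e-3, 1, 14, 0.8, 12, 0.5, 11.4)
  expect_equal(rate_eq3(4e-3, 1, 14, 0.8, 12, 0.5, 11.4), 2 * base)
  expect_equal(rate_eq3(2e-3, 1, 14, 1.6, 12, 0.5, 11.4), 2 * base)
  expect_equal(rate_eq3(2e-3, 1, 28, 0.8, 12, 0.5, 11.4), 2 * base)
  expect_equal(rate_eq3(2e-3, 1, 14, 0.8, 12, 1.0, 11.4), 2 * base)
  expect_equal(rate_eq3(2e-3, 1, 14, 0.8, 24, 0.5, 11.4), base / 2)
  expect_equal(rate_eq3(2e-3, 1, 14, 0.8, 12, 0.5, 22.8), base / 2)
})

test_that("precursor points at the noise floor are excluded, not used", {
  expect_message(
    v <- rate_eq3(c(1e-3, 1e-3), c(1, 0), 14, 1, 12, 0.5, 11.4,
                  noise_floor = 0),
    "excluding")
  expect_true(is.na(v[2]) && !is.na(v[1]))
})

test_that("plateau aggregation averages only the stabilized points", {
  rates <- c(1, 2, 3, 5, 5.2, 5.1, 4.9)
  agg <- aggregate_rates(rates)
  expect_identical(agg$stabilized_indices, 4:7)
  expect_equal(agg$mean_rate, mean(rates[4:7]))
  expect_equal(agg$sd_rate, sd(rates[4:7]))
})

test_that("selective chain recovers the expected rate from noisy flow data", {
  truth <- kinetic_params(1.5e-4, 53.4, 30, 1)
  sc <- acquisition_scheme(12, 5, 90, n_samples = 30)
  atp <- 11.4
  clean <- generate_continuous_flow(truth, sc)
  # SNR 50 for the product signal inside the analysis window (the signal
  # being quantified; hyperpolarized decay makes the series maximum an
  # irrelevant reference there)
  cw <- select_constant_window(
    correct_precursor_eq2(clean$series$times, clean$series$precursor,
                          truth$T1_precursor, sc))$window
  sigma <- mean(clean$series$product[cw]) / 50
  set.seed(11)
  g <- generate_continuous_flow(truth, sc, noise = noise_model(sigma))
  corr <- correct_precursor_eq2(g$series$times, g$series$precursor,
                                truth$T1_precursor, sc)
  corr <- select_constant_window(corr)
  w <- corr$window
  rho <- sin(5 * pi / 180)   # precursor/product response in the generator
  rates <- rate_eq3(g$series$product[w], g$series$precursor[w],
                    pyr_conc = 14, rho = rho, TR = 12, V_medium = 0.5,
                    atp = atp)
  agg <- aggregate_rates(rates)
  # expectation from the clean generator magnetization over the same
  # (maximal-rate) points the aggregator selected
  expected <- oracle_expected_rate(clean, w[agg$stabilized_indices],
                                   14, 0.5, atp, 12)
  expect_lt(abs(agg$mean_rate - expected) / expected, 0.10)
})
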