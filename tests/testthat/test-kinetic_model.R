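fig4_params <- kinetic_params(1.55e-4, 64.5, 20.0, M0 = 1)
fig4_scheme <- acquisition_scheme(5, 12, n_samples = 66)

test_that("zero rate constant gives an identically zero product channel", {
  p <- kinetic_params(0, 64.5, 20.0, 1)
  s <- simulate_two_pool(p, fig4_scheme)
  expect_true(all(s$product == 0))
  expect_true(all(s$precursor > 0))
})

test_that("lossless limit reproduces the closed-form produced amount", {
  # theta = 0, effectively infinite T1s: accumulated product magnetization at
  # t = 60 s equals Pyr * (1 - exp(-k t)) (k t small enough that neglecting
  # precursor consumption costs < 1e-6 relative)
  k <- 1e-8
  p <- kinetic_params(k, 1e9, 1e9, 1)
  s <- simulate_two_pool(p, acquisition_scheme(5, 0, n_samples = 13))
  i60 <- which(s$times == 60)
  expect_equal(s$product_z[i60], extrapolate_amount(k, 1, 60),
               tolerance = 1e-6)
})

test_that("discrete simulator matches the fine-grid Euler oracle", {
  cases <- list(
    list(p = fig4_params, TR = 5, th = 12, n = 30),
    list(p = kinetic_params(5e-4, 40, 15, 2), TR = 8, th = 20, n = 20)
  )
  for (cs in cases) {
    s <- simulate_two_pool(cs$p, acquisition_scheme(cs$TR, cs$th,
                                                    n_samples = cs$n))
    o <- oracle_euler_two_pool(cs$p$k_1st, cs$p$T1_precursor,
                               cs$p$T1_product, cs$p$M0, cs$TR, cs$th, cs$th,
                               cs$n, dt = 1e-3)
    expect_equal(s$precursor, o$precursor, tolerance = 1e-4)
    # skip the first (zero) product sample for a relative comparison
    expect_equal(s$product[-1], o$product[-1], tolerance = 1e-4)
  }
})

test_that("precursor channel is unaffected by the rate constant", {
  s1 <- simulate_two_pool(kinetic_params(1e-4, 60, 20, 1), fig4_scheme)
  s2 <- simulate_two_pool(kinetic_params(9e-3, 60, 20, 1), fig4_scheme)
  expect_identical(s1$precursor, s2$precursor)
})

test_that("with theta = 0 the total magnetization drifts by exactly k*M0*t", {
  # consumption is neglected in the precursor pool, so P + L is not conserved:
  # it grows as M0 * (1 + k t) when relaxation is switched off
  p <- kinetic_params(2e-4, 1e12, 1e12, 3)
  s <- simulate_two_pool(p, acquisition_scheme(5, 0, n_samples = 25))
  expect_equal(s$precursor_z + s$product_z,
               p$M0 * (1 + p$k_1st * s$times), tolerance = 1e-9)
})

test_that("noiseless round-trip fit recovers all parameters", {
  s <- simulate_two_pool(fig4_params, fig4_scheme)
  for (method in c("sequential", "joint")) {
    f <- fit_two_pool(s, fig4_scheme, method = method)
    expect_equal(f$params$k_1st, 1.55e-4, tolerance = 1e-4)
    expect_equal(f$params$T1_precursor, 64.5, tolerance = 1e-4)
    expect_equal(f$params$T1_product, 20.0, tolerance = 1e-4)
    expect_equal(f$params$M0, 1, tolerance = 1e-4)
    expect_gt(f$r2_precursor, 1 - 1e-9)
    expect_gt(f$r2_product, 1 - 1e-9)
  }
})

test_that("an all-zero product channel drives the rate constant to its lower bound", {
  s <- simulate_two_pool(kinetic_params(0, 64.5, 20, 1), fig4_scheme)
  f <- fit_two_pool(s, fig4_scheme)
  expect_lte(f$params$k_1st, 1e-12)
})

test_that("median rate constant is recovered from noisy replicates", {
  # noise emulating the study's product-channel fit quality (R^2 ~ 0.9):
  # additive sigma at a tenth of the product signal maximum
  set.seed(42)
  truth <- fig4_params
  clean <- simulate_two_pool(truth, fig4_scheme)
  sigma <- max(clean$product) / 10
  ks <- replicate(40, {
    g <- generate_arrest_nonselective(truth, fig4_scheme,
                                      noise = noise_model(sigma))
    fit_two_pool(g$series, fig4_scheme)$params$k_1st
  })
  expect_lt(abs(stats::median(ks) - truth$k_1st) / truth$k_1st, 0.05)
})

test_that("amount extrapolation is exact arithmetic with the right limits", {
  expect_identical(extrapolate_amount(1.67e-4, 7000, 0), 0)
  expect_equal(extrapolate_amount(1.67e-4, 7000, 1e12), 7000)
  # one minute at the study-average rate constant: ~70 nmole = 0.07 umole
  a <- extrapolate_amount(1.67e-4, 7000, 60)
  expect_equal(a / 1000, 0.07, tolerance = 0.005 / 0.07)
  expect_true(all(diff(extrapolate_amount(1.67e-4, 7000, seq(0, 600, 10))) > 0))
  expect_error(extrapolate_amount(-1, 7000, 60), "invalid-parameter")
})

test_that("series and scheme constructors enforce their invariants", {
  expect_error(acquisition_scheme(0, 12), "invalid-parameter")
  expect_error(acquisition_scheme(5, 95), "invalid-parameter")
  expect_error(kinetic_params(1e-4, -1, 20, 1), "invalid-parameter")
  expect_error(hp_series(c(0, 5, 5), 1:3, 1:3), "invalid-parameter")
  expect_error(hp_series(c(0, 5), 1:3, 1:2), "invalid-parameter")
})
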