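truth_params <- kinetic_params(1.55e-4, 64.5, 20.0, 1)
ns_scheme <- acquisition_scheme(5, 12, n_samples = 40)
sel <- acquisition_scheme(12, 5, 90, n_samples = 20)

test_that("noiseless arrest generator reproduces the forward simulation exactly", {
  g <- generate_arrest_nonselective(truth_params, ns_scheme)
  s <- simulate_two_pool(truth_params, ns_scheme)
  expect_identical(g$series$precursor, s$precursor)
  expect_identical(g$series$product, s$product)
})

test_that("generators are deterministic under a fixed seed", {
  nz <- noise_model(0.01, seed = 123)
  g1 <- generate_arrest_nonselective(truth_params, ns_scheme, noise = nz)
  g2 <- generate_arrest_nonselective(truth_params, ns_scheme, noise = nz)
  expect_identical(g1$series$precursor, g2$series$precursor)
  s1 <- generate_arrest_selective(truth_params, sel, noise = nz)
  s2 <- generate_arrest_selective(truth_params, sel, noise = nz)
  expect_identical(s1$series$product, s2$series$product)
  f1 <- generate_continuous_flow(truth_params, sel, noise = nz)
  f2 <- generate_continuous_flow(truth_params, sel, noise = nz)
  expect_identical(f1$series$precursor, f2$series$precursor)
  meta <- list(flip_angle = 50, TR = 1.1, n_scans = 16, T1 = 1)
  p1 <- generate_p31_pair(11.4, meta, meta, 55500, noise = nz)
  p2 <- generate_p31_pair(11.4, meta, meta, 55500, noise = nz)
  expect_identical(p1$sample$integral, p2$sample$integral)
})

test_that("fitted rate constants center on the generator truth", {
  set.seed(5)
  sigma <- max(simulate_two_pool(truth_params, ns_scheme)$product) / 20
  ks <- replicate(30, {
    g <- generate_arrest_nonselective(truth_params, ns_scheme,
                                      noise = noise_model(sigma))
    fit_two_pool(g$series, ns_scheme)$params$k_1st
  })
  expect_lt(abs(median(ks) - truth_params$k_1st) / truth_params$k_1st, 0.05)
})

test_that("selective product accumulation matches the quadrature oracle", {
  # lossless product relaxation: signal over one TR is k * integral P dt
  p <- kinetic_params(2e-4, 53.4, 1e12, 1)
  g <- generate_arrest_selective(p, sel, quench = 0L, pre_delay = 0)
  # sample 2 accumulates from the depleted precursor after pulse 1
  P_start <- g$series$precursor_z[1] * cos(5 * pi / 180)
  want <- oracle_selective_accumulation(p$k_1st, P_start, p$T1_precursor,
                                        1e12, sel$TR)
  expect_equal(g$series$product[2], want, tolerance = 1e-6)
  # and with product relaxation on
  p2 <- kinetic_params(2e-4, 53.4, 25, 1)
  g2 <- generate_arrest_selective(p2, sel, quench = 0L, pre_delay = 0)
  want2 <- oracle_selective_accumulation(p2$k_1st, P_start, p2$T1_precursor,
                                         25, sel$TR)
  expect_equal(g2$series$product[2], want2, tolerance = 1e-6)
})

test_that("omitting the quench block inflates the first analysis sample", {
  p <- kinetic_params(2e-4, 53.4, 25, 1)
  # same elapsed time since injection at the first analysis excitation:
  # 5 s pre-delay + 3 quench intervals + one TR = 23 s
  with_q <- generate_arrest_selective(p, sel, quench = 4L, quench_TR = 2,
                                      pre_delay = 5)
  no_q <- generate_arrest_selective(p, sel, quench = 0L, pre_delay = 23)
  first_analysis <- which(!with_q$quench_mask)[1]
  expect_equal(sum(with_q$quench_mask), 4L)
  expect_equal(first_analysis, 5L)
  # quenched: product re-grew for only one TR; unquenched: for 23 s
  expect_gt(no_q$series$product[1] / with_q$series$product[first_analysis], 1.2)
})

test_that("continuous-flow steady phase is flat after decay correction", {
  p <- kinetic_params(1.5e-4, 53.4, 30, 1)
  sc <- acquisition_scheme(12, 5, 90, n_samples = 30)
  g <- generate_continuous_flow(p, sc)
  corr <- correct_precursor_eq2(g$series$times, g$series$precursor,
                                p$T1_precursor, sc)
  t <- g$series$times
  plateau <- corr$corrected[t >= g$truth$steady_onset + 40 &
                            t <= g$truth$washout_onset]
  expect_gt(length(plateau), 3)
  expect_lt(max(abs(plateau - mean(plateau))) / mean(plateau), 0.01)
  expect_equal(mean(plateau), g$truth$steady_corrected, tolerance = 0.01)
})

test_that("window selection starts near the end of the build-up", {
  p <- kinetic_params(1.5e-4, 53.4, 30, 1)
  sc <- acquisition_scheme(12, 5, 90, n_samples = 30)
  g <- generate_continuous_flow(p, sc)
  corr <- correct_precursor_eq2(g$series$times, g$series$precursor,
                                p$T1_precursor, sc)
  w <- select_constant_window(corr)$window
  start <- g$series$times[w[1]]
  expect_gte(start, g$truth$steady_onset - sc$TR)
  expect_lte(start, g$truth$steady_onset + 4 * sc$TR)
})

test_that("a steady inlet covering the acquisition degenerates to the arrest design", {
  p <- kinetic_params(1.5e-4, 53.4, 30, 1)
  sc <- acquisition_scheme(12, 5, 90, n_samples = 15)
  # instant mixing: the probe concentration is 1 from the first grid step on
  fl <- flow_profile(arrival_time = 0, buildup_duration = 0,
                     steady_duration = 1e4, washout_rate = 1e3)
  g <- generate_continuous_flow(p, sc, flow = fl)
  a <- generate_arrest_selective(p, sc, quench = 0L, pre_delay = 0)
  expect_equal(g$series$precursor[-1], a$series$precursor[2:15],
               tolerance = 1e-3)
  expect_equal(g$series$product[-1], a$series$product[2:15],
               tolerance = 1e-3)
})

test_that("the optional inflow spike produces a post-plateau bump", {
  p <- kinetic_params(1.5e-4, 53.4, 30, 1)
  sc <- acquisition_scheme(12, 5, 90, n_samples = 30)
  g0 <- generate_continuous_flow(p, sc, spike = 0)
  g1 <- generate_continuous_flow(p, sc, spike = 0.5, spike_duration = 15)
  after <- g0$series$times > g0$truth$washout_onset
  expect_true(any(g1$series$precursor[after] > g0$series$precursor[after]))
})

test_that("geometry and flow constructors enforce their invariants", {
  expect_error(experiment_geometry(V_total = 2), "invalid-parameter")
  expect_equal(experiment_geometry()$V_total, 1.4)
  expect_error(flow_profile(washout_rate = 0), "invalid-parameter")
  expect_error(noise_model(-1), "invalid-parameter")
})
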