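test_that("closed level is the amiloride-segment mean and shifts with offset", {
  fx <- level_trace(c(0, 1, 0, 2), baseline = -1)
  expect_equal(detect_closed_level(fx$trace, fx$annotation), -1)
  sh <- fx$trace; sh$current <- sh$current + 0.5
  expect_equal(detect_closed_level(sh, fx$annotation), -0.5)
  ann <- segment_annotation(0, 1, "washout")
  expect_error(detect_closed_level(ec_trace(rep(0, 5000), 2e-4), ann),
               "amiloride")
})

test_that("noiseless histograms occupy exactly one bin per level", {
  fx <- level_trace(c(0, 1), unitary = 0.38)
  h <- build_histogram(fx$trace, -1, ann = fx$annotation,
                       refilter_hz = NULL)
  expect_equal(sum(h$counts > 0), 2L)
  expect_equal(sum(h$counts), h$total_samples)
  # pure noise: a single Gaussian mode at the closed level
  set.seed(21)
  noise_tr <- ec_trace(rnorm(50000, -1, 0.05), 2e-4, "pA")
  hn <- build_histogram(noise_tr, -1, refilter_hz = NULL)
  expect_error(estimate_amplitude(hn), "no openings")
})

test_that("amplitude is the mean spacing of adjacent modes", {
  fx <- level_trace(c(0, 1, 2, 0, 1), unitary = 0.38)
  h <- build_histogram(fx$trace, -1, ann = fx$annotation,
                       refilter_hz = NULL)
  expect_equal(estimate_amplitude(h), 0.38, tolerance = 1e-6)
  fx2 <- level_trace(c(0, 1), unitary = 1)
  h2 <- build_histogram(fx2$trace, -1, ann = fx2$annotation,
                        refilter_hz = NULL)
  expect_equal(estimate_amplitude(h2), 1, tolerance = 1e-6)
  # invariant to a closed-level offset
  sh <- fx$trace; sh$current <- sh$current - 2
  hs <- build_histogram(sh, -3, ann = fx$annotation, refilter_hz = NULL)
  expect_equal(estimate_amplitude(hs), estimate_amplitude(h),
               tolerance = 1e-9)
})

test_that("histogram NPo equals the direct time average on ideal traces", {
  # oracle equivalence on a deterministic level sequence
  fx <- level_trace(c(0, 1, 2, 1, 0, 2), unitary = 0.38)
  h <- build_histogram(fx$trace, -1, ann = fx$annotation,
                       refilter_hz = NULL)
  expect_equal(estimate_npo(h), npo_time_average(fx$open_count),
               tolerance = 1e-12)
  # and on a simulated noiseless gating trace
  sim <- simulate_single_channel(gating_spec(2, 0.3, noise_sd = 0),
                                 duration = 30, amiloride_tail = 5,
                                 seed = 31)
  cl <- detect_closed_level(sim$trace, sim$annotation)
  hs <- build_histogram(sim$trace, cl, ann = sim$annotation,
                        refilter_hz = NULL)
  gated <- seq_len(round(25 / sim$trace$dt))
  expect_equal(estimate_npo(hs), npo_time_average(sim$open_count[gated]),
               tolerance = 1e-12)
})

test_that("noisy simulated patches recover amplitude and NPo", {
  sim <- simulate_single_channel(gating_spec(2, 0.3, unitary_current = 0.38,
                                             noise_sd = 0.05),
                                 duration = 60, amiloride_tail = 5,
                                 seed = 41)
  res <- analyze_patch(sim$trace, sim$annotation)
  expect_lt(abs(res$i - 0.38), 0.02)
  gated <- seq_len(round(55 / sim$trace$dt))
  expect_lt(abs(res$npo - npo_time_average(sim$open_count[gated])), 0.03)
  expect_equal(res$apparent_n, 2L)
  expect_lt(abs(res$po_app - res$npo / 2), 1e-12)
  # NPo never exceeds the apparent channel count
  expect_lte(res$npo, res$apparent_n)
})

test_that("apparent-N rules cap the Po(app) report at three channels", {
  fx <- level_trace(c(0, 1, 2, 1, 2, 0), unitary = 0.5)
  h <- build_histogram(fx$trace, -1, ann = fx$annotation,
                       refilter_hz = NULL)
  ap <- apparent_n_and_po(h, npo = 0.8)
  expect_equal(ap$apparent_n, 2L)
  expect_equal(ap$po_app, 0.4)
  fx4 <- level_trace(c(0, 1, 2, 3, 4, 0, 2), unitary = 0.5)
  h4 <- build_histogram(fx4$trace, -1, ann = fx4$annotation,
                        refilter_hz = NULL)
  ap4 <- apparent_n_and_po(h4)
  expect_equal(ap4$apparent_n, 4L)
  expect_true(is.na(ap4$po_app))
})

test_that("chord conductance scales linearly and rejects zero potential", {
  expect_equal(chord_conductance(0.38, -82), 0.38 / 82 * 1000)
  expect_equal(chord_conductance(1, -100), 10)
  expect_equal(chord_conductance(0.76, -82), 2 * chord_conductance(0.38, -82))
  expect_error(chord_conductance(1, 0), "non-zero")
})
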