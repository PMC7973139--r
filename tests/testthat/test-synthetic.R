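test_that("cohort generation is deterministic and validates its spec", {
  sp <- cohort_spec(n_oocytes = 6, n_batches = 2, seed = 5)
  a <- generate_cohort(sp, render_traces = FALSE)
  b <- generate_cohort(sp, render_traces = FALSE)
  expect_identical(a$cohort, b$cohort)
  expect_error(cohort_spec(n_oocytes = 0), "n_oocytes")
  expect_error(cohort_spec(groups = list(list(name = "g",
                                              mean_di_ami = 1,
                                              inhibition = 1.5,
                                              mean_di_camg = 0))))
})

test_that("noiseless traces give back the programmed metrics exactly", {
  sp <- cohort_spec(n_oocytes = 3, n_batches = 1, noise_sd = 0, seed = 2)
  g <- generate_cohort(sp)
  expect_equal(g$cohort$delta_i_ami, g$cohort$true_di_ami)
  expect_equal(g$cohort$delta_i_camg, g$cohort$true_di_camg)
  # the control group carries no hemichannel current at all
  expect_true(all(g$cohort$delta_i_camg[g$cohort$group == "ENaC"] == 0))
})

test_that("an inhibition factor of zero makes the groups exchangeable", {
  sp <- cohort_spec(n_oocytes = 4, n_batches = 1,
                    groups = list(
                      list(name = "a", mean_di_ami = 1000, inhibition = 0,
                           mean_di_camg = 0),
                      list(name = "b", mean_di_ami = 1000, inhibition = 0,
                           mean_di_camg = 0)),
                    seed = 3)
  g <- generate_cohort(sp, render_traces = FALSE)$cohort
  # identical generating parameters: same lognormal mean for both groups
  expect_equal(mean(g$true_di_ami[g$group == "a"]) > 0, TRUE)
  expect_equal(sp$groups[[1]]$mean_di_ami * (1 - sp$groups[[1]]$inhibition),
               sp$groups[[2]]$mean_di_ami * (1 - sp$groups[[2]]$inhibition))
})

test_that("measured relative inhibition matches the programmed 54%", {
  sp <- cohort_spec(n_oocytes = 50, n_batches = 5, noise_sd = 0, seed = 1)
  g <- generate_cohort(sp, render_traces = FALSE)
  nm <- batch_normalize(g$cohort, "ENaC")
  s <- summarize_groups(nm, "normalized")
  test <- s[s$group == "ENaC+Cx30", ]
  inhib <- relative_inhibition(test$mean, 1)
  sem_pct <- test$sem * 100
  expect_lt(abs(inhib - 54), 3 * sem_pct)
})

test_that("MTSET timecourse generator honours its degenerate settings", {
  p0 <- steady_state(trafficking_params(0, n0 = 800, po_baseline = 0.3))
  s0 <- simulate_mtset_timecourse(p0, noise_sd = 0)
  expect_equal(unname(s0$di_t), rep(800, 8))  # no retrieval: flat
  # steady state: dI(70) + dI_2nd returns exactly to dI(0)
  p <- params_for_remaining(0.46, po = 0.3)
  s <- simulate_mtset_timecourse(p, noise_sd = 0)
  expect_equal(unname(s$di_t[s$times == 70]) + s$di_second_mtset,
               unname(s$di_t[s$times == 0]), tolerance = 1e-12)
  # the stated-world ratio: f + (1 - f) Po at 70 min
  expect_equal(unname(normalized_decay(s)[["70"]]), 0.622,
               tolerance = 1e-9)
  expect_error(simulate_mtset_timecourse(p, sample_times = c(0, 20, 10)),
               "increasing")
  expect_error(simulate_mtset_timecourse(p, sample_times = c(10, 70)),
               "include 0")
})

test_that("patch simulator matches two-state stationary statistics", {
  # ergodicity: single channel at p_open 0.5
  sim1 <- simulate_single_channel(gating_spec(1, 0.5, noise_sd = 0,
                                              mean_open_ms = 50),
                                  duration = 120, amiloride_tail = 0,
                                  seed = 9)
  expect_lt(abs(mean(sim1$open_count) - 0.5), 0.05)
  # two independent channels: level occupancy is Binomial(2, p)
  sim2 <- simulate_single_channel(gating_spec(2, 0.3, noise_sd = 0,
                                              mean_open_ms = 50),
                                  duration = 240, amiloride_tail = 0,
                                  seed = 10)
  emp <- tabulate(sim2$open_count + 1L, nbins = 3L) /
    length(sim2$open_count)
  expect_lt(max(abs(emp - dbinom(0:2, 2, 0.3))), 0.05)
  # amiloride tail: every sample at the closed level
  sim3 <- simulate_single_channel(gating_spec(1, 0.5, noise_sd = 0),
                                  duration = 10, amiloride_tail = 4,
                                  seed = 11, baseline_pA = -1)
  tail_idx <- segment_indices(sim3$trace, 6, 10)
  expect_equal(unique(sim3$trace$current[tail_idx]), -1)
  expect_error(simulate_single_channel(gating_spec(1, 0.5,
                                                   mean_open_ms = 0.1),
                                       dt = 2e-4),
               "resolve")
})

test_that("generators are bit-identical under a fixed seed", {
  p <- params_for_remaining(0.5)
  expect_identical(simulate_mtset_timecourse(p, noise_sd = 5, seed = 4),
                   simulate_mtset_timecourse(p, noise_sd = 5, seed = 4))
  expect_identical(
    simulate_step_protocol(1, -20, noise_sd = 2, seed = 4),
    simulate_step_protocol(1, -20, noise_sd = 2, seed = 4))
  gs <- gating_spec(2, 0.3)
  expect_identical(
    simulate_single_channel(gs, duration = 8, seed = 4)$trace,
    simulate_single_channel(gs, duration = 8, seed = 4)$trace)
})
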