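#' Specification of a synthetic oocyte cohort
#'
#' Describes the statistical structure of a two-electrode voltage-clamp
#' cohort: per-oocyte expression heterogeneity (lognormal, CV ~0.5 to match
#' the wide scatter of individual oocytes), multiplicative donor-batch
#' factors (lognormal, CV 0.2), and Gaussian recording noise. Each group is
#' a list with elements `name`, `mean_di_ami` (group-mean amiloride-
#' sensitive current before batch/oocyte factors, in the trace units),
#' `inhibition` (fractional suppression of `mean_di_ami` relative to the
#' control scale, in [0, 1]) and `mean_di_camg` (mean hemichannel
#' divalent-removal current, 0 for groups without connexin).
#'
#' @param n_oocytes Oocytes per group per batch totals are split evenly
#'   across batches.
#' @param n_batches Number of donor batches (>= 1).
#' @param groups List of group specs (see Details above).
#' @param expression_cv CV of the per-oocyte lognormal expression factor.
#' @param batch_cv CV of the per-batch lognormal factor.
#' @param noise_sd Gaussian trace noise SD, trace units (nA).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_oocytes = 20, n_batches = 3,
                        groups = list(
                          list(name = "ENaC", mean_di_ami = 5000,
                               inhibition = 0, mean_di_camg = 0),
                          list(name = "ENaC+Cx30", mean_di_ami = 5000,
                               inhibition = 0.54, mean_di_camg = 900)),
                        expression_cv = 0.5, batch_cv = 0.2,
                        noise_sd = 5, seed = 1L) {
  stopifnot(n_oocytes >= 1, n_batches >= 1, expression_cv >= 0,
            batch_cv >= 0, noise_sd >= 0)
  for (g in groups) {
    stopifnot(!is.null(g$name), g$mean_di_ami > 0,
              g$inhibition >= 0, g$inhibition <= 1, g$mean_di_camg >= 0)
  }
  structure(list(n_oocytes = n_oocytes, n_batches = n_batches,
                 groups = groups, expression_cv = expression_cv,
                 batch_cv = batch_cv, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# lognormal factor with mean 1 and the requested CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# standard whole-cell protocol timing (seconds)
.protocol_times <- list(
  ami1 = c(0, 60), wash = c(60, 150), ami2 = c(150, 210),
  divfree = c(210, 310), post = c(310, 360))

# render one oocyte's annotated whole-cell trace; exponential solution-
# exchange relaxations (tau 2 s) are cosmetic, metrics read plateaus
render_wc_trace <- function(di_ami, di_camg, noise_sd, dt = 0.1,
                            baseline = -50, tau = 2, label = "") {
  p <- .protocol_times
  tt <- seq(0, p$post[2] - dt, by = dt)
  relax <- function(t_on, from, to) {
    ifelse(tt < t_on, from, to + (from - to) * exp(-(tt - t_on) / tau))
  }
  i <- rep(baseline, length(tt))                      # amiloride on
  i <- relax(p$wash[1], i, baseline - di_ami)         # washout reveals ENaC
  i <- relax(p$ami2[1], i, baseline)                  # re-block
  i <- relax(p$divfree[1], i, baseline - di_camg)     # hemichannel current
  i <- relax(p$post[1], i, baseline)                  # divalents back
  i <- i + stats::rnorm(length(tt), 0, noise_sd)
  ann <- segment_annotation(
    start = c(p$ami1[1], p$wash[1], p$ami2[1], p$divfree[1], p$post[1]),
    end = c(p$ami1[2], p$wash[2], p$ami2[2], p$divfree[2], p$post[2]),
    condition = c("amiloride", "washout", "amiloride", "divalent_free",
                  "baseline"),
    solution = c("ND96+Ami", "ND96", "ND96+Ami", "divalent-free+Ami",
                 "ND96+Ami"))
  list(trace = ec_trace(i, dt, units = "nA", label = label), annotation = ann)
}

#' Generate a synthetic whole-cell cohort with known ground truth
#'
#' Each oocyte receives a true amiloride-sensitive current
#' `group_mean * (1 - inhibition) * batch_factor * oocyte_factor` and a
#' matching annotated trace (amiloride -> washout -> amiloride ->
#' divalent-removal -> recovery). The returned cohort table carries the
#' true values alongside, so analysis operations can be validated exactly.
#'
#' @param spec A [cohort_spec()].
#' @param render_traces If `FALSE`, skip trace rendering (cohort table
#'   only; much faster for large Monte-Carlo checks).
#' @return List with `cohort` (a [cohort_table()] with `true_di_ami`,
#'   `true_di_camg` columns; `delta_i_ami` filled from rendered traces or
#'   from truth when traces are skipped) and `recordings` (per-oocyte
#'   lists of `trace`, `annotation`, `truth`).
#' @export
generate_cohort <- function(spec, render_traces = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  batch_fac <- rlnorm_cv(spec$n_batches, spec$batch_cv)
  rows <- list(); recs <- list(); k <- 0L
  per_batch <- rep(spec$n_oocytes %/% spec$n_batches, spec$n_batches)
  extra <- spec$n_oocytes %% spec$n_batches
  if (extra > 0) per_batch[seq_len(extra)] <- per_batch[seq_len(extra)] + 1L
  for (b in seq_len(spec$n_batches)) {
    for (g in spec$groups) {
      ooc_fac <- rlnorm_cv(per_batch[b], spec$expression_cv)
      for (j in seq_len(per_batch[b])) {
        k <- k + 1L
        true_ami <- g$mean_di_ami * (1 - g$inhibition) *
          batch_fac[b] * ooc_fac[j]
        true_camg <- g$mean_di_camg * batch_fac[b] * ooc_fac[j]
        id <- sprintf("ooc%03d", k)
        if (render_traces) {
          rec <- render_wc_trace(true_ami, true_camg, spec$noise_sd,
                                 label = id)
          meas_ami <- as.numeric(measure_delta_ami(rec$trace,
                                                   rec$annotation))
          meas_camg <- measure_divalent_removal(rec$trace, rec$annotation)
          rec$truth <- list(di_ami = true_ami, di_camg = true_camg)
          recs[[id]] <- rec
        } else {
          meas_ami <- true_ami
          meas_camg <- true_camg
        }
        row <- oocyte_measurement(id, sprintf("batch%02d", b), g$name,
                                  meas_ami, meas_camg)
        row$true_di_ami <- true_ami
        row$true_di_camg <- true_camg
        rows[[k]] <- row
      }
    }
  }
  list(cohort = cohort_table(do.call(rbind, rows)), recordings = recs)
}

#' Simulate a noisy MTSET timecourse from the trafficking model
#'
#' Forward counterpart of the retrieval protocol: measure Delta-I_Ami,
#' expose to MTSET (all surface channels modified, open probability ->
#' `po_modified`), follow the decaying current at the sample times, then
#' apply MTSET a second time at the final sample time and record the
#' increment. Dynamics are delegated to [simulate_trafficking()]; Gaussian
#' noise of SD `noise_sd` (in the same current units) is added to every
#' measurement.
#'
#' @param params A [trafficking_params()] (use [steady_state()] for the
#'   balanced-membrane protocol).
#' @param sample_times Increasing times (minutes) after the first MTSET
#'   application; must include 0 and a final time (default 0..70 by 10).
#' @param noise_sd Measurement noise SD.
#' @param seed Integer seed.
#' @return An [mtset_series()] with attribute `"truth"` holding the params
#'   and the true modified-pool remaining fraction at the final time.
#' @export
simulate_mtset_timecourse <- function(params,
                                      sample_times = seq(0, 70, by = 10),
                                      noise_sd = 0, seed = 1L) {
  stopifnot(inherits(params, "trafficking_params"))
  if (is.unsorted(sample_times, strictly = TRUE))
    stop("sample_times must be strictly increasing")
  if (!any(sample_times == 0)) stop("sample_times must include 0")
  set.seed(as.integer(seed))
  tmax <- max(sample_times)
  states <- simulate_trafficking(params, mtset_times = 0,
                                 t_grid = sample_times)
  di <- predicted_delta_ami(states, params)
  di_before <- params$unitary * params$n0 * params$po_baseline
  final <- states[nrow(states), ]
  di_second <- params$unitary * final$n_unmodified *
    (params$po_modified - params$po_baseline)
  noise <- stats::rnorm(length(di) + 2L, 0, noise_sd)
  series <- mtset_series(
    di_before = max(di_before + noise[1L], 0),
    di_t = stats::setNames(pmax(di + noise[seq_along(di) + 1L], 0),
                           sample_times),
    di_second_mtset = max(di_second + noise[length(noise)], 0))
  attr(series, "truth") <- list(
    params = params,
    remaining_modified_fraction = final$n_modified / params$n0)
  series
}

#' Simulate an ohmic voltage-step recording
#'
#' Per-step current = conductance * (V - E_rev) + Gaussian noise, steady
#' within each step (capacitive transients are not modeled). Conductance in
#' microsiemens and potentials in mV give currents in nA.
#'
#' @param conductance Linear conductance in uS (>= 0).
#' @param true_erev True reversal potential in mV.
#' @param protocol A [step_protocol()].
#' @param noise_sd Noise SD in nA.
#' @param seed Integer seed.
#' @param dt Sampling interval in seconds.
#' @return List of [ec_trace()]s, one per step, in protocol order.
#' @export
simulate_step_protocol <- function(conductance, true_erev,
                                   protocol = step_protocol(),
                                   noise_sd = 0, seed = 1L, dt = 0.01) {
  stopifnot(conductance >= 0)
  set.seed(as.integer(seed))
  n <- round(protocol$step_duration / dt)
  lapply(protocol_potentials(protocol), function(v) {
    i <- conductance * (v - true_erev) + stats::rnorm(n, 0, noise_sd)
    ec_trace(i, dt, units = "nA", label = sprintf("step %+d mV", v))
  })
}

#' Gating specification for single-channel simulation
#'
#' Independent identical two-state (closed/open) channels. Open probability
#' and dwell means are kept consistent at construction:
#' p_open = mean_open / (mean_open + mean_closed), so only `p_open` and
#' `mean_open_ms` are free.
#'
#' @param n_channels Number of channels in the patch (>= 1).
#' @param p_open Stationary open probability in (0, 1).
#' @param unitary_current Unitary current magnitude in pA (inward openings
#'   are rendered negative).
#' @param mean_open_ms Mean open dwell in ms; the mean closed dwell is
#'   derived as `mean_open_ms * (1 - p_open) / p_open`.
#' @param noise_sd Gaussian noise SD in pA.
#' @param filter_hz Effective recording bandwidth (metadata; the analysis
#'   side refilters).
#' @return An object of class `gating_spec`.
#' @export
gating_spec <- function(n_channels = 2, p_open = 0.3,
                        unitary_current = 0.38, mean_open_ms = 150,
                        noise_sd = 0.05, filter_hz = 250) {
  stopifnot(n_channels >= 1, p_open > 0, p_open < 1, unitary_current > 0,
            mean_open_ms > 0, noise_sd >= 0, filter_hz > 0)
  structure(list(n_channels = n_channels, p_open = p_open,
                 unitary_current = unitary_current,
                 mean_open_ms = mean_open_ms,
                 mean_closed_ms = mean_open_ms * (1 - p_open) / p_open,
                 noise_sd = noise_sd, filter_hz = filter_hz),
            class = "gating_spec")
}

# one channel's open/closed indicator over n samples: alternating
# exponential dwells, stationary initial state
sim_two_state <- function(n, dt_ms, mean_open_ms, mean_closed_ms, p_open) {
  open <- logical(n)
  state <- stats::runif(1) < p_open
  i <- 1L
  while (i <= n) {
    dwell <- stats::rexp(1, 1 / if (state) mean_open_ms else mean_closed_ms)
    len <- max(1L, round(dwell / dt_ms))
    j <- min(n, i + len - 1L)
    if (state) open[i:j] <- TRUE
    i <- j + 1L
    state <- !state
  }
  open
}

#' Simulate an outside-out patch recording
#'
#' Sums independent two-state Markov channels (inward-negative unitary
#' steps) on a baseline, adds Gaussian noise, and appends an amiloride tail
#' during which all channels are blocked shut — the segment from which the
#' all-closed current level is read.
#'
#' @param spec A [gating_spec()].
#' @param duration Total recording length in seconds.
#' @param dt Sampling interval in seconds (must resolve the dwell times:
#'   `dt` < both mean dwells).
#' @param amiloride_tail Seconds of amiloride application at the end
#'   (`0 <= amiloride_tail < duration`).
#' @param seed Integer seed.
#' @param baseline_pA Closed-level current in pA.
#' @return List with `trace` (an [ec_trace()] in pA), `annotation` (a
#'   [segment_annotation()] with washout then amiloride segments), and
#'   `open_count` (true per-sample number of open channels — simulation
#'   ground truth).
#' @export
simulate_single_channel <- function(spec, duration = 60, dt = 2e-4,
                                    amiloride_tail = 5, seed = 1L,
                                    baseline_pA = -1) {
  stopifnot(inherits(spec, "gating_spec"), duration > amiloride_tail,
            amiloride_tail >= 0)
  dt_ms <- dt * 1000
  if (dt_ms >= min(spec$mean_open_ms, spec$mean_closed_ms))
    stop("dt does not resolve the channel kinetics (dt >= mean dwell)")
  set.seed(as.integer(seed))
  n <- round(duration / dt)
  n_gate <- round((duration - amiloride_tail) / dt)
  open_count <- integer(n)
  for (ch in seq_len(spec$n_channels)) {
    open_count[seq_len(n_gate)] <- open_count[seq_len(n_gate)] +
      sim_two_state(n_gate, dt_ms, spec$mean_open_ms, spec$mean_closed_ms,
                    spec$p_open)
  }
  i <- baseline_pA - spec$unitary_current * open_count +
    stats::rnorm(n, 0, spec$noise_sd)
  ann <- if (amiloride_tail > 0) {
    segment_annotation(start = c(0, duration - amiloride_tail),
                       end = c(duration - amiloride_tail, duration),
                       condition = c("washout", "amiloride"),
                       solution = c("modified ND96", "modified ND96+Ami"))
  } else {
    segment_annotation(0, duration, "washout", "modified ND96")
  }
  list(trace = ec_trace(i, dt, units = "pA", label = "outside-out patch"),
       annotation = ann, open_count = open_count)
}
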