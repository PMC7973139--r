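# shared fixtures, built in code

# a piecewise-constant annotated whole-cell trace (nA, inward negative):
# amiloride -> washout -> amiloride -> divalent_free -> baseline
flat_wc_trace <- function(ami = -100, washout = -600, divfree = ami,
                          dt = 0.1) {
  seg_len <- 20  # seconds per segment
  lv <- c(ami, washout, ami, divfree, ami)
  cur <- rep(lv, each = seg_len / dt)
  ann <- segment_annotation(
    start = seg_len * (0:4), end = seg_len * (1:5),
    condition = c("amiloride", "washout", "amiloride", "divalent_free",
                  "baseline"))
  list(trace = ec_trace(cur, dt, "nA"), annotation = ann)
}

# noiseless patch trace stepping through given open levels (pA)
level_trace <- function(levels, unitary = 0.38, baseline = -1,
                        dt = 2e-4, seg_s = 2, amiloride_s = 2) {
  cur <- rep(baseline - unitary * levels, each = seg_s / dt)
  cur <- c(cur, rep(baseline, amiloride_s / dt))
  dur <- seg_s * length(levels)
  ann <- segment_annotation(
    start = c(0, dur), end = c(dur, dur + amiloride_s),
    condition = c("washout", "amiloride"))
  list(trace = ec_trace(cur, dt, "pA"), annotation = ann,
       open_count = rep(levels, each = seg_s / dt))
}

# steady-state trafficking params for a target remaining fraction at t_end
params_for_remaining <- function(remaining, t_end = 70, po = 0.3,
                                 n0 = 1000, unitary = 1) {
  steady_state(trafficking_params(log(1 / remaining) / t_end, n0 = n0,
                                  po_baseline = po, unitary = unitary))
}
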