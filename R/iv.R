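#' Voltage-step protocol description
#'
#' The standard protocol: nine consecutive 2-s steps in 20-mV increments
#' starting from a hyperpolarizing pulse to -120 mV, with currents averaged
#' over the final 100 ms of each step.
#'
#' @param start First step potential in mV.
#' @param increment Step increment in mV.
#' @param n_steps Number of steps (>= 2).
#' @param step_duration Step length in seconds.
#' @param analysis_window Tail window averaged per step, in seconds
#'   (<= `step_duration`).
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(start = -120, increment = 20, n_steps = 9,
                          step_duration = 2, analysis_window = 0.1) {
  stopifnot(n_steps >= 2, analysis_window > 0,
            analysis_window <= step_duration, step_duration > 0)
  structure(list(start = start, increment = increment, n_steps = n_steps,
                 step_duration = step_duration,
                 analysis_window = analysis_window),
            class = "step_protocol")
}

protocol_potentials <- function(protocol) {
  protocol$start + protocol$increment * (seq_len(protocol$n_steps) - 1L)
}

#' Current-voltage relation
#'
#' @param potentials Strictly increasing potentials in mV.
#' @param currents Mean current per potential.
#' @param sem Optional per-potential SEM.
#' @param n Number of cells averaged.
#' @return An object of class `iv_curve` (a data.frame).
#' @export
iv_curve <- function(potentials, currents, sem = NULL, n = 1L) {
  stopifnot(length(potentials) == length(currents))
  if (is.unsorted(potentials, strictly = TRUE))
    stop("potentials must be strictly increasing")
  df <- data.frame(potential = potentials, current = currents,
                   sem = if (is.null(sem)) NA_real_ else sem)
  attr(df, "n") <- n
  class(df) <- c("iv_curve", "data.frame")
  df
}

#' Build an I/V curve from step-protocol traces
#'
#' Averages each step trace over the protocol's tail analysis window
#' (final 100 ms by default) and pairs the result with the step potential.
#'
#' @param step_traces List of [ec_trace()] objects, one per step, in
#'   protocol order; each must span the step duration.
#' @param protocol A [step_protocol()].
#' @return An [iv_curve()].
#' @export
build_iv <- function(step_traces, protocol = step_protocol()) {
  if (length(step_traces) != protocol$n_steps)
    stop("need exactly ", protocol$n_steps, " step traces, got ",
         length(step_traces))
  currents <- vapply(step_traces, function(tr) {
    dur <- trace_duration(tr)
    if (dur + 1e-9 < protocol$step_duration)
      stop("step trace shorter than the protocol step duration")
    mean(tr$current[segment_indices(tr, dur - protocol$analysis_window, dur)])
  }, numeric(1))
  iv_curve(protocol_potentials(protocol), currents)
}

#' Reversal potential of an I/V curve
#'
#' Linear interpolation between the pair of adjacent points bracketing zero
#' current; when the curve crosses zero more than once the crossing nearest
#' 0 mV is used. A local linear fit over the three points nearest the
#' crossing is available as an alternative.
#'
#' @param iv An [iv_curve()].
#' @param method `"interpolate"` (default) or `"local_fit"`.
#' @return Reversal potential in mV.
#' @export
estimate_reversal <- function(iv, method = c("interpolate", "local_fit")) {
  method <- match.arg(method)
  v <- iv$potential; i <- iv$current
  # zero current at a grid point counts as a crossing
  roots <- c()
  for (k in seq_len(length(v) - 1L)) {
    if (i[k] == 0) roots <- c(roots, v[k])
    else if (i[k] * i[k + 1L] < 0) {
      roots <- c(roots,
                 v[k] - i[k] * (v[k + 1L] - v[k]) / (i[k + 1L] - i[k]))
    }
  }
  if (i[length(i)] == 0) roots <- c(roots, v[length(v)])
  if (!length(roots)) stop("reversal outside protocol range: no sign change")
  root <- roots[which.min(abs(roots))]
  if (method == "local_fit") {
    nearest <- order(abs(v - root))[1:3]
    fit <- stats::lm(i[nearest] ~ v[nearest])
    root <- -stats::coef(fit)[1L] / stats::coef(fit)[2L]
  }
  unname(root)
}

#' Subtract a control-mean background from a test I/V curve
#'
#' Pointwise subtraction of the batch-matched control average from an
#' individual test curve, correcting for endogenous oocyte conductances.
#' The control mean is treated as fixed, so the SEM of the result carries
#' the test curve's variability only.
#'
#' @param test,control_mean [iv_curve()]s on identical potential grids.
#' @return An [iv_curve()] of the difference currents.
#' @export
subtract_background <- function(test, control_mean) {
  if (!isTRUE(all.equal(test$potential, control_mean$potential)))
    stop("potential grids differ between test and control curves")
  iv_curve(test$potential, test$current - control_mean$current,
           sem = test$sem, n = attr(test, "n"))
}

#' Cation permeability ratio from a reversal-potential shift
#'
#' P_X / P_Na = exp(dE_rev / (RT/F)), where dE_rev is the reversal shift
#' observed on fully substituting bath Na+ with the test cation X
#' (residual millimolar Na+ in the substituted bath is ignored, matching
#' the simple exponential form).
#'
#' @param delta_erev Reversal-potential shift in mV (substituted minus
#'   control).
#' @param constants A [phys_constants()].
#' @return Dimensionless permeability ratio.
#' @examples
#' permeability_ratio(-33.1)  # ~0.27
#' @export
permeability_ratio <- function(delta_erev, constants = phys_constants()) {
  exp(delta_erev / constants$rt_over_f)
}
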