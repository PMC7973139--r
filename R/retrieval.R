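#' Per-oocyte MTSET timecourse
#'
#' The measurements the retrieval calculus consumes: the amiloride-sensitive
#' current before the first MTSET exposure (`di_before`), the timecourse of
#' Delta-I_Ami after the first exposure (`di_t`, a named vector keyed by
#' time in minutes that must include 0 and a final time, conventionally 70),
#' and the current increase elicited by a second MTSET exposure at the end
#' of the protocol (`di_second_mtset`).
#'
#' @param di_before Delta-I_Ami before the first MTSET application (>= 0).
#' @param di_t Named numeric vector: names are times in minutes, values
#'   Delta-I_Ami. Must contain time 0.
#' @param di_second_mtset Current increase on the second MTSET application
#'   (>= 0).
#' @return An object of class `mtset_series`.
#' @export
mtset_series <- function(di_before, di_t, di_second_mtset) {
  if (is.null(names(di_t))) stop("di_t must be named by time in minutes")
  times <- as.numeric(names(di_t))
  if (anyNA(times)) stop("di_t names must be numeric times")
  o <- order(times)
  times <- times[o]; di_t <- as.numeric(di_t)[o]
  if (!any(times == 0)) stop("di_t must include time 0")
  if (any(di_t < 0) || di_before < 0 || di_second_mtset < 0)
    stop("currents stored as magnitudes, must be >= 0")
  structure(list(di_before = di_before, times = times, di_t = di_t,
                 di_second_mtset = di_second_mtset),
            class = "mtset_series")
}

di_at <- function(series, t) {
  i <- which(series$times == t)
  if (!length(i)) stop("series has no measurement at t = ", t, " min")
  series$di_t[i]
}

t_final <- function(series) max(series$times)

#' Baseline open probability estimated from the MTSET stimulation
#'
#' Po(initial) = Delta-I_Ami(before 1st MTSET) / Delta-I_Ami(0 min), on the
#' assumption that MTSET drives open probability to ~1 without changing the
#' number of surface channels. Values outside [0, 1] (possible on noisy
#' series) are clipped and flagged via the `"clipped"` attribute.
#'
#' @param series An [mtset_series()].
#' @return Estimated open probability in [0, 1].
#' @export
estimate_po_initial <- function(series) {
  di0 <- di_at(series, 0)
  if (di0 <= 0) stop("Delta-I_Ami(0 min) must be > 0")
  po <- series$di_before / di0
  clipped <- po < 0 || po > 1
  if (clipped) {
    warning("Po(initial) outside [0, 1]; clipped")
    po <- min(max(po, 0), 1)
  }
  structure(po, clipped = clipped)
}

#' Insertion correction from the second MTSET response
#'
#' The second MTSET application stimulates only channels inserted since the
#' first one. The current those channels already contributed at baseline
#' open probability is Delta-I_Insertion = Delta-I_2ndMTSET * Po / (1 - Po),
#' with Po = Po(initial).
#'
#' @param series An [mtset_series()].
#' @param po_initial Optional override; defaults to
#'   [estimate_po_initial()] of the series.
#' @return Delta-I_Insertion (same units as the series currents).
#' @export
insertion_correction <- function(series, po_initial = NULL) {
  po <- if (is.null(po_initial)) as.numeric(estimate_po_initial(series))
        else po_initial
  if (po >= 1) stop("insertion correction undefined at Po(initial) = 1")
  series$di_second_mtset * po / (1 - po)
}

#' Retrieval current and corrected remaining fraction
#'
#' Implements the full insertion-corrected retrieval calculus:
#' Delta-I_Retrieval = Delta-I_Ami(0) - (Delta-I_Ami(t_end) -
#' Delta-I_Insertion). The normalized retrieval is Delta-I_Retrieval /
#' Delta-I_Ami(0), and the corrected remaining fraction (the fraction of the
#' originally modified channel pool still at the surface at t_end) is its
#' complement.
#'
#' @param series An [mtset_series()].
#' @param t_end Time of the final measurement used (default: last time in
#'   the series, conventionally 70 min).
#' @return A list of class `retrieval_estimate` with components
#'   `po_initial`, `di_insertion`, `di_retrieval`, `normalized_retrieval`,
#'   `remaining_fraction_corrected`.
#' @export
retrieval_current <- function(series, t_end = t_final(series)) {
  po <- estimate_po_initial(series)
  di0 <- di_at(series, 0)
  di_end <- di_at(series, t_end)
  di_ins <- insertion_correction(series, as.numeric(po))
  di_ret <- di0 - (di_end - di_ins)
  structure(list(po_initial = as.numeric(po),
                 di_insertion = di_ins,
                 di_retrieval = di_ret,
                 normalized_retrieval = di_ret / di0,
                 remaining_fraction_corrected = 1 - di_ret / di0,
                 clipped = isTRUE(attr(po, "clipped"))),
            class = "retrieval_estimate")
}

#' @export
print.retrieval_estimate <- function(x, ...) {
  cat(sprintf(paste0("Retrieval estimate: Po(initial) = %.3f, ",
                     "dI_Insertion = %.4g, dI_Retrieval = %.4g\n",
                     "  normalized retrieval = %.3f, ",
                     "corrected remaining fraction = %.3f\n"),
              x$po_initial, x$di_insertion, x$di_retrieval,
              x$normalized_retrieval, x$remaining_fraction_corrected))
  invisible(x)
}

#' Insertion-corrected remaining fraction from summary ratios
#'
#' Closed-form identity of the retrieval calculus under an exact
#' steady-state insertion/retrieval balance: if the raw remaining fraction
#' is r = Delta-I_Ami(t)/Delta-I_Ami(0) and the baseline open probability is
#' Po, the fraction of the originally modified pool still at the surface is
#' (r - Po) / (1 - Po). This is the summary-statistic form of
#' [retrieval_current()]; it lets printed cohort ratios be corrected without
#' per-oocyte currents.
#'
#' @param raw_remaining Raw remaining fraction, must be >= `po_initial`
#'   (values below are inconsistent with the steady-state model).
#' @param po_initial Baseline open probability, < 1.
#' @return Corrected remaining fraction in [0, 1].
#' @examples
#' corrected_remaining_fraction(0.62, 0.3)  # 0.457
#' @export
corrected_remaining_fraction <- function(raw_remaining, po_initial) {
  if (po_initial >= 1) stop("po_initial must be < 1")
  if (raw_remaining < po_initial)
    stop("raw_remaining < po_initial is inconsistent with steady state")
  (raw_remaining - po_initial) / (1 - po_initial)
}

#' Normalized current decay
#'
#' Ratio of Delta-I_Ami at each time point to its value at time 0.
#'
#' @param series An [mtset_series()].
#' @return Named numeric vector of ratios keyed by time (minutes).
#' @export
normalized_decay <- function(series) {
  di0 <- di_at(series, 0)
  if (di0 <= 0) stop("Delta-I_Ami(0 min) must be > 0")
  stats::setNames(series$di_t / di0, series$times)
}

#' Proportional (through-origin) regression of retrieval on initial current
#'
#' Least-squares fit of y = k x with no intercept, as used for cohort-level
#' retrieval-vs-expression regressions: if retrieval is first order and the
#' endocytic machinery is not saturated, Delta-I_Retrieval is proportional
#' to Delta-I_Ami(0 min) and k estimates the retrieved fraction.
#'
#' @param x Predictor (e.g. Delta-I_Ami at 0 min); not all zero, length >= 2.
#' @param y Response (e.g. Delta-I_Retrieval), same length.
#' @param intercept If `TRUE`, fit a free intercept instead (diagnostic
#'   variant).
#' @return List with `k`, `se`, `fit` (the underlying `lm`).
#' @export
proportional_fit <- function(x, y, intercept = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (all(x == 0)) stop("degenerate predictor: all x are zero")
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ 0 + x)
  # summary.lm warns on exact fits; SE = 0 is the correct answer there
  co <- suppressWarnings(summary(fit))$coefficients
  row <- if (intercept) "x" else "x"
  list(k = unname(co[row, "Estimate"]), se = unname(co[row, "Std. Error"]),
       fit = fit)
}
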