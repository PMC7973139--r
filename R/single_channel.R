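#' Gaussian digital refilter
#'
#' Low-pass filters a trace to an effective bandwidth `fc` with a Gaussian
#' FIR kernel, the standard smoothing used before amplitude-histogram
#' analysis of patch-clamp data. The kernel standard deviation follows the
#' usual Gaussian-filter relation sigma_t = 0.1325 / fc; edges are padded
#' by replication.
#'
#' @param trace An [ec_trace()].
#' @param fc Cutoff (-3 dB) frequency in Hz, or `NULL` to skip filtering.
#' @return The filtered [ec_trace()].
#' @export
refilter <- function(trace, fc = 250) {
  if (is.null(fc)) return(trace)
  stopifnot(fc > 0)
  sigma_n <- 0.1325 / (fc * trace$dt)
  if (sigma_n < 0.25) return(trace)  # already below the target bandwidth
  half <- max(1L, ceiling(4 * sigma_n))
  k <- stats::dnorm(seq(-half, half), sd = sigma_n)
  k <- k / sum(k)
  x <- trace$current
  padded <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  sm <- stats::filter(padded, k, sides = 2)
  trace$current <- as.numeric(sm[(half + 1L):(half + length(x))])
  trace
}

#' Closed-channel current level from the amiloride segment
#'
#' The level at which all channels are shut, read as the mean current over
#' the (first) amiloride segment of the recording.
#'
#' @param trace An [ec_trace()].
#' @param ann A [segment_annotation()] containing an amiloride segment.
#' @return Closed level in the trace's current units.
#' @export
detect_closed_level <- function(trace, ann) {
  check_annotation(trace, ann)
  ia <- which(ann$condition == "amiloride")
  if (!length(ia)) stop("annotation has no amiloride segment")
  ia <- ia[1L]
  mean(trace$current[segment_indices(trace, ann$start[ia], ann$end[ia])])
}

#' Binned amplitude histogram of a patch recording
#'
#' Histograms the current relative to the all-closed level over the
#' analysis window (the washout segments when an annotation is supplied,
#' the full trace otherwise), after digital refiltering to `refilter_hz`.
#'
#' @param trace An [ec_trace()] (pA).
#' @param closed_level All-closed current level (same units).
#' @param bin_width Bin width in pA.
#' @param ann Optional [segment_annotation()]; washout segments define the
#'   analysis window.
#' @param refilter_hz Effective bandwidth for [refilter()], or `NULL` for
#'   none.
#' @return An object of class `amplitude_histogram`: list with `bin_mid`,
#'   `bin_edges`, `counts`, `closed_level`, `bin_width`, `total_samples`.
#' @export
build_histogram <- function(trace, closed_level, bin_width = 0.02,
                            ann = NULL, refilter_hz = 250) {
  stopifnot(bin_width > 0)
  trace <- refilter(trace, refilter_hz)
  x <- if (is.null(ann)) trace$current else {
    check_annotation(trace, ann)
    iw <- which(ann$condition == "washout")
    if (!length(iw)) stop("annotation has no washout segment")
    unlist(lapply(iw, function(k)
      trace$current[segment_indices(trace, ann$start[k], ann$end[k])]))
  }
  if (!length(x)) stop("empty analysis window")
  x <- x - closed_level
  # bins aligned so that 0 (the closed level) sits at a bin center
  lo <- (floor(min(x) / bin_width + 0.5) - 0.5) * bin_width
  hi <- (ceiling(max(x) / bin_width - 0.5) + 0.5) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  structure(list(bin_mid = edges[-length(edges)] + bin_width / 2,
                 bin_edges = edges, counts = counts,
                 closed_level = closed_level, bin_width = bin_width,
                 total_samples = length(x)),
            class = "amplitude_histogram")
}

# locate current-level modes in an amplitude histogram: kernel-smoothed
# local maxima, refined by per-mode Gaussian fits (weighted-mean fallback),
# pruned below a minimum dwell-mass fraction
fit_modes <- function(hist, min_mass = 0.001, smooth_bins = 2) {
  y <- hist$counts
  if (smooth_bins > 0) {
    half <- ceiling(3 * smooth_bins)
    k <- stats::dnorm(seq(-half, half), sd = smooth_bins)
    k <- k / sum(k)
    pad <- c(rep(0, half), y, rep(0, half))
    y <- as.numeric(stats::filter(pad, k, sides = 2))[half + seq_along(y)]
  }
  n <- length(y)
  peak <- which(y >= c(-Inf, y[-n]) & y > c(y[-1L], -Inf) &
                  y > max(y) * 1e-3)
  if (!length(peak)) stop("no modes detected in histogram")
  # assign every bin to its nearest peak, then measure mass and center
  assign <- peak[apply(abs(outer(seq_len(n), peak, "-")), 1L, which.min)]
  out <- lapply(peak, function(p) {
    idx <- which(assign == p)
    cts <- hist$counts[idx]; mid <- hist$bin_mid[idx]
    mass <- sum(cts) / hist$total_samples
    wm <- sum(mid * cts) / sum(cts)
    ctr <- tryCatch(suppressWarnings({
      df <- data.frame(m = mid, c = cts)
      st <- list(a = max(cts), mu = mid[which.max(cts)],
                 s = max(hist$bin_width, stats::sd(rep(mid, cts))))
      f <- stats::nls(c ~ a * exp(-(m - mu)^2 / (2 * s^2)), data = df,
                      start = st,
                      control = stats::nls.control(warnOnly = TRUE))
      mu <- stats::coef(f)[["mu"]]
      # reject fits that wander outside the mode's own bin window
      if (mu < min(mid) || mu > max(mid) || !f$convInfo$isConv) wm else mu
    }), error = function(e) wm)
    c(center = ctr, mass = mass)
  })
  modes <- as.data.frame(do.call(rbind, out))
  modes <- modes[modes$mass >= min_mass, , drop = FALSE]
  if (!nrow(modes)) stop("no modes above the mass threshold")
  # level 0 = closed (center nearest 0); deeper inward = higher level
  modes <- modes[order(-modes$center), , drop = FALSE]
  modes$level <- seq_len(nrow(modes)) - 1L
  rownames(modes) <- NULL
  modes
}

#' Unitary current amplitude from an amplitude histogram
#'
#' Mean spacing between adjacent fitted mode centers. Openings are inward
#' (negative); the magnitude is returned.
#'
#' @param hist An [build_histogram()] result.
#' @param min_mass Minimum fraction of samples a mode must hold.
#' @return Unitary current magnitude in pA.
#' @export
estimate_amplitude <- function(hist, min_mass = 0.001) {
  modes <- fit_modes(hist, min_mass)
  if (nrow(modes) < 2L) stop("no openings resolved (< 2 modes)")
  mean(abs(diff(modes$center)))
}

#' Channel activity NPo from an amplitude histogram
#'
#' NPo = sum over levels k of k times the fraction of time spent at level
#' k, with level occupancies taken from the histogram mass assigned to each
#' fitted mode (levels assumed contiguous from the closed level).
#'
#' @inheritParams estimate_amplitude
#' @return NPo (dimensionless, >= 0).
#' @export
estimate_npo <- function(hist, min_mass = 0.001) {
  modes <- fit_modes(hist, min_mass)
  sum(modes$level * modes$mass) / sum(modes$mass)
}

#' Apparent channel count and apparent open probability
#'
#' Apparent N is the maximum simultaneously open level carrying at least
#' `min_mass` of the dwell time (an automated proxy for visual
#' inspection). Po(app) = NPo / N is reported only for patches with no
#' more than three active channels, `NA` otherwise.
#'
#' @inheritParams estimate_amplitude
#' @param npo Optional precomputed NPo (defaults to [estimate_npo()]).
#' @return List with `apparent_n` and `po_app`.
#' @export
apparent_n_and_po <- function(hist, npo = NULL, min_mass = 0.001) {
  modes <- fit_modes(hist, min_mass)
  if (is.null(npo)) npo <- sum(modes$level * modes$mass) / sum(modes$mass)
  n_app <- max(modes$level)
  po <- if (n_app >= 1L && n_app <= 3L) npo / n_app else NA_real_
  list(apparent_n = n_app, po_app = po)
}

#' Chord conductance of a unitary current
#'
#' g = |i / V| with i in pA and V in mV, returned in pS. By convention V is
#' the liquid-junction-corrected effective trans-patch potential.
#'
#' @param i Unitary current in pA.
#' @param potential Driving potential in mV (non-zero).
#' @return Conductance in pS.
#' @examples
#' chord_conductance(0.38, -82)  # ~4.6 pS
#' @export
chord_conductance <- function(i, potential) {
  if (any(potential == 0)) stop("potential must be non-zero")
  abs(i / potential) * 1000
}

#' Full amplitude-histogram analysis of a patch recording
#'
#' Runs the complete single-channel pipeline: closed-level detection from
#' the amiloride segment, 250-Hz refiltered amplitude histogram over the
#' washout window, mode fitting, unitary amplitude, NPo, apparent N,
#' Po(app), and the chord conductance at the LJ-corrected holding
#' potential.
#'
#' @param trace An [ec_trace()] in pA.
#' @param ann A [segment_annotation()] with washout and amiloride segments.
#' @param holding Nominal holding potential in mV.
#' @param constants A [phys_constants()] (supplies the LJ correction).
#' @param bin_width,refilter_hz,min_mass Passed to the underlying steps.
#' @param lj_correct Use the effective (LJ-corrected) potential for the
#'   conductance (default) or the nominal holding potential.
#' @return A list of class `single_channel_result`: `i`, `apparent_n`,
#'   `npo`, `po_app`, `conductance_pS`, `closed_level`, `potential`.
#' @export
analyze_patch <- function(trace, ann, holding = -70,
                          constants = phys_constants(), bin_width = 0.02,
                          refilter_hz = 250, min_mass = 0.001,
                          lj_correct = TRUE) {
  closed <- detect_closed_level(trace, ann)
  hist <- build_histogram(trace, closed, bin_width, ann, refilter_hz)
  modes <- fit_modes(hist, min_mass)
  if (nrow(modes) < 2L) stop("no openings resolved (< 2 modes)")
  i <- mean(abs(diff(modes$center)))
  npo <- sum(modes$level * modes$mass) / sum(modes$mass)
  ap <- apparent_n_and_po(hist, npo, min_mass)
  v <- if (lj_correct) effective_potential(holding, constants) else holding
  structure(list(i = i, apparent_n = ap$apparent_n, npo = npo,
                 po_app = ap$po_app,
                 conductance_pS = chord_conductance(i, v),
                 closed_level = closed, potential = v,
                 histogram = hist, modes = modes),
            class = "single_channel_result")
}

#' @export
print.single_channel_result <- function(x, ...) {
  cat(sprintf(paste0("Single-channel result: i = %.3f pA, NPo = %.3f, ",
                     "apparent N = %d, Po(app) = %s\n",
                     "  chord conductance = %.2f pS at %g mV\n"),
              x$i, x$npo, x$apparent_n,
              if (is.na(x$po_app)) "NA" else sprintf("%.3f", x$po_app),
              x$conductance_pS, x$potential))
  invisible(x)
}

#' Direct time-average NPo
#'
#' Independent of the histogram route: the mean number of simultaneously
#' open channels over an idealized open-count sequence (e.g. the simulation
#' ground truth). Used as the oracle the histogram estimate is checked
#' against.
#'
#' @param open_count Integer vector of per-sample open-channel counts.
#' @return NPo.
#' @export
npo_time_average <- function(open_count) mean(open_count)
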