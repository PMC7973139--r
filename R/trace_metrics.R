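#' Averaging-window conventions for trace metrics
#'
#' Whole-cell metrics are read from plateau averages: the mean over the
#' final `plateau_fraction` of each annotated segment (default the last
#' 20%), by which time the solution-exchange relaxations have settled.
#' The divalent-removal metric additionally excludes a guard window at the
#' end of the removal segment where a transient Ca2+-activated chloride
#' spike can precede divalent re-addition.
#'
#' @param plateau_fraction Fraction of each segment tail averaged, in
#'   (0, 1].
#' @param guard_s Seconds excluded at the end of a divalent-free segment.
#' @return An object of class `metric_windows`.
#' @export
metric_windows <- function(plateau_fraction = 0.2, guard_s = 5) {
  stopifnot(plateau_fraction > 0, plateau_fraction <= 1, guard_s >= 0)
  structure(list(plateau_fraction = plateau_fraction, guard_s = guard_s),
            class = "metric_windows")
}

plateau_mean <- function(trace, t0, t1, fraction) {
  w0 <- t1 - (t1 - t0) * fraction
  mean(trace$current[segment_indices(trace, w0, t1)])
}

#' Amiloride-sensitive current magnitude from an annotated trace
#'
#' Delta-I_Ami = |washout plateau - amiloride plateau|: the current revealed
#' by washing the ENaC blocker amiloride out of the bath. Uses the first
#' amiloride/washout pair of adjacent segments. If the washout plateau is
#' not more inward than the amiloride baseline the estimate is clipped to 0
#' and flagged (attribute `"clipped"`), since a negative Delta-I_Ami is
#' physically meaningless under this protocol.
#'
#' @param trace An [ec_trace()] (inward currents negative).
#' @param ann A [segment_annotation()] containing at least one amiloride
#'   segment immediately followed by a washout segment.
#' @param windows A [metric_windows()].
#' @return Current magnitude (same units as the trace), with attribute
#'   `clipped` if the raw estimate was negative.
#' @export
measure_delta_ami <- function(trace, ann, windows = metric_windows()) {
  check_annotation(trace, ann)
  ia <- which(ann$condition == "amiloride")
  iw <- which(ann$condition == "washout")
  if (!length(ia) || !length(iw))
    stop("annotation must contain amiloride and washout segments")
  # first washout preceded by an amiloride segment
  pair <- NULL
  for (w in iw) if (any(ia == w - 1L)) { pair <- c(w - 1L, w); break }
  if (is.null(pair))
    stop("no washout segment adjacent to an amiloride segment")
  m_ami <- plateau_mean(trace, ann$start[pair[1L]], ann$end[pair[1L]],
                        windows$plateau_fraction)
  m_wash <- plateau_mean(trace, ann$start[pair[2L]], ann$end[pair[2L]],
                         windows$plateau_fraction)
  di <- m_ami - m_wash  # inward negative: washout more negative => positive
  if (di < 0) {
    warning("washout plateau less inward than amiloride baseline; ",
            "Delta-I_Ami clipped to 0")
    return(structure(0, clipped = TRUE))
  }
  structure(di, clipped = FALSE)
}

#' Divalent-removal current magnitude (hemichannel readout)
#'
#' The increase in inward current when extracellular Ca2+/Mg2+ are removed,
#' disinhibiting connexin hemichannels: |most-inward current during the
#' divalent-free window - preceding baseline plateau|. The guard window at
#' the end of the removal segment is excluded so the transient chloride
#' spike around re-addition does not contaminate the extremum.
#'
#' @inheritParams measure_delta_ami
#' @return Current magnitude >= 0.
#' @export
measure_divalent_removal <- function(trace, ann,
                                     windows = metric_windows()) {
  check_annotation(trace, ann)
  idv <- which(ann$condition == "divalent_free")
  if (!length(idv)) stop("annotation has no divalent_free segment")
  idv <- idv[1L]
  if (idv == 1L) stop("divalent_free segment has no preceding baseline")
  base <- plateau_mean(trace, ann$start[idv - 1L], ann$end[idv - 1L],
                       windows$plateau_fraction)
  t1 <- max(ann$end[idv] - windows$guard_s,
            ann$start[idv] + trace$dt)
  win <- segment_indices(trace, ann$start[idv], t1)
  extremum <- min(trace$current[win])  # most inward
  max(base - extremum, 0)
}

#' Relative inhibition of a test measurement vs a control mean
#'
#' Computed from the ratio of an individual measurement to the mean of its
#' batch-matched controls, reported with the positive-for-inhibition sign
#' convention used in summary figures: a test current at 46% of the control
#' mean is a 54% inhibition.
#'
#' @param delta_i Individual current magnitude.
#' @param control_mean Mean of the matched control group (> 0).
#' @return Inhibition in percent (positive = inhibited).
#' @examples
#' relative_inhibition(0.46, 1)  # 54
#' @export
relative_inhibition <- function(delta_i, control_mean) {
  if (any(control_mean <= 0)) stop("control_mean must be > 0")
  -(delta_i / control_mean - 1) * 100
}

#' Fold stimulation of a current by a treatment
#'
#' Simple after/before ratio, e.g. proteolytic activation by chymotrypsin
#' which raises open probability from ~0.3 toward 1 and so stimulates
#' currents roughly threefold.
#'
#' @param before,after Current magnitudes; `before` must be > 0.
#' @return The ratio `after / before`.
#' @export
fold_stimulation <- function(before, after) {
  if (any(before <= 0)) stop("'before' current must be > 0")
  after / before
}

#' Batch-matched normalization of a cohort table
#'
#' Divides every oocyte's `delta_i_ami` by the mean `delta_i_ami` of the
#' control-group oocytes from the same donor batch, removing the
#' multiplicative batch-to-batch expression differences that dominate
#' oocyte cohorts. Control-group normalized means are 1 per batch by
#' construction.
#'
#' @param cohort A [cohort_table()].
#' @param control_group Name of the control group; every batch must contain
#'   at least one control oocyte.
#' @return The cohort with a `normalized` column appended.
#' @export
batch_normalize <- function(cohort, control_group) {
  stopifnot(inherits(cohort, "cohort_table"))
  ctrl <- cohort[cohort$group == control_group, ]
  means <- tapply(ctrl$delta_i_ami, ctrl$batch_id, mean)
  missing <- setdiff(unique(cohort$batch_id), names(means))
  if (length(missing))
    stop("batch(es) without control-group oocytes: ",
         paste(missing, collapse = ", "))
  cohort$normalized <- cohort$delta_i_ami / as.numeric(means[cohort$batch_id])
  cohort
}

#' Per-group summary statistics
#'
#' Mean, SEM (sd/sqrt(n)), number of oocytes n, and number of distinct
#' donor batches N per experimental group. SEM of a single observation is
#' reported as `NA`, not 0.
#'
#' @param cohort A [cohort_table()].
#' @param column Which column to summarize (default `"delta_i_ami"`).
#' @return A data.frame with one row per group: `group`, `mean`, `sem`,
#'   `n`, `N`.
#' @export
summarize_groups <- function(cohort, column = "delta_i_ami") {
  stopifnot(column %in% names(cohort))
  groups <- unique(cohort$group)
  do.call(rbind, lapply(groups, function(g) {
    v <- cohort[cohort$group == g, column]
    n <- length(v)
    data.frame(group = g, mean = mean(v),
               sem = if (n > 1L) stats::sd(v) / sqrt(n) else NA_real_,
               n = n,
               N = length(unique(cohort$batch_id[cohort$group == g])),
               stringsAsFactors = FALSE)
  }))
}
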