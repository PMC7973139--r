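#' Membrane-current trace
#'
#' A uniformly sampled current time series. Currents are stored signed with
#' the inward-negative convention; derived Delta-I metrics are reported as
#' non-negative magnitudes.
#'
#' @param current Numeric vector of currents (non-empty).
#' @param dt Sampling interval in seconds (> 0).
#' @param units `"nA"` or `"pA"`.
#' @param label Optional label.
#' @return An object of class `ec_trace`.
#' @export
ec_trace <- function(current, dt, units = c("nA", "pA"), label = "") {
  units <- match.arg(units)
  stopifnot(is.numeric(current), length(current) > 0L,
            is.numeric(dt), length(dt) == 1L, dt > 0)
  structure(list(current = as.numeric(current), dt = dt, units = units,
                 label = label),
            class = "ec_trace")
}

#' @export
print.ec_trace <- function(x, ...) {
  cat(sprintf("ec_trace '%s': %d samples @ dt = %g s (%.1f s), units %s\n",
              x$label, length(x$current), x$dt,
              length(x$current) * x$dt, x$units))
  invisible(x)
}

#' Trace duration in seconds
#' @param trace An [ec_trace()].
#' @return Duration in seconds.
#' @export
trace_duration <- function(trace) length(trace$current) * trace$dt

trace_time <- function(trace) (seq_along(trace$current) - 1L) * trace$dt

#' Segment annotation for a trace
#'
#' Labeled, non-overlapping time intervals tying trace regions to the
#' experimental condition in effect (which solution was flowing, whether
#' amiloride or MTSET was present, ...). Mirrors the solution bars drawn
#' over published recordings.
#'
#' @param start,end Numeric vectors of interval bounds in seconds.
#' @param condition Character vector; each element one of `"amiloride"`,
#'   `"washout"`, `"divalent_free"`, `"mtset"`, `"chymotrypsin"`,
#'   `"baseline"`.
#' @param solution Character vector of solution names (recycled).
#' @return An object of class `segment_annotation` (a data.frame).
#' @export
segment_annotation <- function(start, end, condition, solution = "ND96") {
  conds <- c("amiloride", "washout", "divalent_free", "mtset",
             "chymotrypsin", "baseline")
  if (!all(condition %in% conds))
    stop("condition must be among: ", paste(conds, collapse = ", "))
  stopifnot(length(start) == length(end), length(condition) == length(start))
  if (any(start < 0) || any(end <= start))
    stop("segments require 0 <= start < end")
  o <- order(start)
  start <- start[o]; end <- end[o]
  condition <- condition[o]
  solution <- rep_len(solution, length(start))[o]
  if (length(start) > 1L && any(start[-1L] < end[-length(end)]))
    stop("segments must be non-overlapping")
  structure(data.frame(start = start, end = end, condition = condition,
                       solution = solution, stringsAsFactors = FALSE),
            class = c("segment_annotation", "data.frame"))
}

# validate that segments fit inside the trace
check_annotation <- function(trace, ann) {
  if (!inherits(ann, "segment_annotation")) stop("ann must be a segment_annotation")
  if (max(ann$end) > trace_duration(trace) + 1e-9)
    stop("annotation extends past the end of the trace")
  invisible(TRUE)
}

# sample indices covering [t0, t1) of a trace
segment_indices <- function(trace, t0, t1) {
  i0 <- floor(t0 / trace$dt) + 1L
  i1 <- min(ceiling(t1 / trace$dt), length(trace$current))
  if (i1 < i0) stop("empty segment window")
  seq.int(i0, i1)
}

#' Per-oocyte whole-cell measurement record
#'
#' One row of a cohort table: amiloride-sensitive current magnitude
#' (`delta_i_ami`) and divalent-removal current magnitude (`delta_i_camg`)
#' for one oocyte, tagged with its donor batch and experimental group.
#'
#' @param oocyte_id,batch_id,group Identifiers; `batch_id` must be non-empty
#'   (batch-matched normalization requires it).
#' @param delta_i_ami,delta_i_camg Current magnitudes, >= 0.
#' @return A one-row data.frame.
#' @export
oocyte_measurement <- function(oocyte_id, batch_id, group,
                               delta_i_ami, delta_i_camg = NA_real_) {
  stopifnot(nzchar(batch_id))
  if (!is.na(delta_i_ami) && delta_i_ami < 0)
    stop("delta_i_ami stored as magnitude, must be >= 0")
  if (!is.na(delta_i_camg) && delta_i_camg < 0)
    stop("delta_i_camg stored as magnitude, must be >= 0")
  data.frame(oocyte_id = oocyte_id, batch_id = batch_id, group = group,
             delta_i_ami = delta_i_ami, delta_i_camg = delta_i_camg,
             stringsAsFactors = FALSE)
}

#' Assemble a cohort table
#'
#' @param rows A data.frame of [oocyte_measurement()] rows (or rbind of them).
#' @return The validated cohort data.frame with class `cohort_table`.
#' @export
cohort_table <- function(rows) {
  need <- c("oocyte_id", "batch_id", "group", "delta_i_ami")
  if (!all(need %in% names(rows)))
    stop("cohort rows need columns: ", paste(need, collapse = ", "))
  if (any(!nzchar(rows$batch_id))) stop("batch_id must be non-empty")
  class(rows) <- unique(c("cohort_table", class(rows)))
  rows
}
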