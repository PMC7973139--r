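#' Kinetic parameters of the surface-channel trafficking model
#'
#' Ground truth for the forward two-pool model: channels at the cell surface
#' are retrieved by first-order endocytosis (rate constant `lambda_ret`,
#' per minute) and replaced by a constant insertion flux of unmodified
#' channels (`j_ins`, channels/min). A covalent sulfhydryl modification
#' event converts every unmodified surface channel to the high-open-
#' probability modified state (`po_modified`, default exactly 1); channels
#' inserted afterwards carry the baseline open probability `po_baseline`.
#' `unitary` scales channel counts to the whole-cell current readout (pA or
#' nA per channel at the holding driving force).
#'
#' @param lambda_ret First-order retrieval rate constant, per minute (>= 0).
#' @param j_ins Insertion flux of unmodified channels, channels/min (>= 0).
#' @param n0 Initial surface channel count (> 0).
#' @param po_baseline Open probability of unmodified channels, in
#'   `[0, po_modified]`.
#' @param po_modified Open probability after covalent modification
#'   (default 1).
#' @param unitary Current per open channel (arbitrary current units).
#' @return An object of class `trafficking_params`.
#' @export
trafficking_params <- function(lambda_ret, j_ins = 0, n0 = 1000,
                               po_baseline = 0.3, po_modified = 1,
                               unitary = 1) {
  stopifnot(lambda_ret >= 0, j_ins >= 0, n0 > 0,
            po_baseline >= 0, po_modified <= 1,
            po_baseline <= po_modified, unitary >= 0)
  structure(list(lambda_ret = lambda_ret, j_ins = j_ins, n0 = n0,
                 po_baseline = po_baseline, po_modified = po_modified,
                 unitary = unitary),
            class = "trafficking_params")
}

#' Impose the steady-state insertion/retrieval balance
#'
#' Sets the insertion flux to `lambda_ret * n0` so that total surface channel
#' count is time-invariant (retrieval of modified channels exactly balanced
#' by insertion of unmodified ones). With `lambda_ret = 0` the membrane is
#' static and the flux is 0.
#'
#' @param params A [trafficking_params()].
#' @return `params` with `j_ins` replaced by the balancing flux.
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "trafficking_params"))
  params$j_ins <- params$lambda_ret * params$n0
  params
}

#' Simulate the two-pool surface state through a modification protocol
#'
#' Between modification events both pools follow linear kinetics with
#' closed-form solutions (no ODE solver error):
#' dN_mod/dt = -lambda N_mod and dN_unmod/dt = J - lambda N_unmod.
#' At each event time every unmodified channel becomes modified
#' instantaneously (the 5-min reagent exposure is treated as complete).
#'
#' @param params A [trafficking_params()]. All `n0` channels start
#'   unmodified.
#' @param mtset_times Times (minutes) of modification events.
#' @param t_grid Strictly increasing output grid in minutes. Grid points
#'   coinciding with an event report the post-event state.
#' @return A data.frame with columns `t`, `n_modified`, `n_unmodified`.
#' @export
simulate_trafficking <- function(params, mtset_times = 0,
                                 t_grid = seq(0, 70, by = 1)) {
  stopifnot(inherits(params, "trafficking_params"))
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing")
  mtset_times <- sort(mtset_times)
  lam <- params$lambda_ret; J <- params$j_ins

  # advance one pool pair by dt minutes
  step <- function(nm, nu, dt) {
    if (lam > 0) {
      e <- exp(-lam * dt)
      c(nm * e, J / lam + (nu - J / lam) * e)
    } else {
      c(nm, nu + J * dt)
    }
  }

  # event-driven sweep over merged time points
  t0 <- min(c(t_grid, mtset_times))
  nm <- 0; nu <- params$n0; t_cur <- t0
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = 2L)
  ev <- mtset_times
  for (i in seq_along(t_grid)) {
    tt <- t_grid[i]
    while (length(ev) && ev[1L] <= tt) {
      s <- step(nm, nu, ev[1L] - t_cur)
      nm <- s[1L] + s[2L]; nu <- 0  # modification event
      t_cur <- ev[1L]; ev <- ev[-1L]
    }
    s <- step(nm, nu, tt - t_cur)
    nm <- s[1L]; nu <- s[2L]; t_cur <- tt
    out[i, ] <- c(nm, nu)
  }
  data.frame(t = t_grid, n_modified = out[, 1L], n_unmodified = out[, 2L])
}

#' Predicted amiloride-sensitive current from a surface state
#'
#' Delta-I = unitary * (N_mod * Po_mod + N_unmod * Po_baseline). The driving
#' force is absorbed into `unitary`.
#'
#' @param state A data.frame with `n_modified`, `n_unmodified` columns (as
#'   returned by [simulate_trafficking()]), or a single-row list.
#' @param params A [trafficking_params()].
#' @return Numeric vector of predicted currents, one per state row.
#' @export
predicted_delta_ami <- function(state, params) {
  stopifnot(inherits(params, "trafficking_params"))
  params$unitary * (state$n_modified * params$po_modified +
                    state$n_unmodified * params$po_baseline)
}
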