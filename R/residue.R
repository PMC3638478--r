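# Exact network residue functions.
#
# With a unit tracer impulse shared across the inlets in proportion to
# their flow, the tracer mass still inside the network at time t, R(t),
# is a finite sum of rectangles: one rectangle per vessel per distinct
# upstream pathway. A pathway that reaches the upstream node of vessel
# (i -> j) with probability w (product of the flow-split fractions along
# the pathway) and accumulated delay tau contributes a rectangle of
# height w * Q_ij / outflow(i) on [tau, tau + T_ij). The computation is
# a single dynamic-programming sweep over the flow DAG in topological
# order, propagating "arrival atoms" (weight, delay) from the inlets;
# no pathway is ever enumerated explicitly.
#
# R(t) is represented exactly by its breakpoints, never on a time grid.

new_residue_function <- function(breakpoints, values) {
  structure(list(breakpoints = breakpoints, values = values),
            class = "residue_function")
}

#' Residue function of a single vessel
#'
#' A plug of tracer traverses a single vessel in exactly its transit
#' time, so R(t) is the unit rectangle on `[0, T)` and the transit-time
#' distribution a single atom at `T`.
#'
#' @param T Transit time, s (> 0).
#' @return A `residue_function`.
#' @export
single_vessel_residue <- function(T) {
  if (length(T) != 1 || !is.finite(T) || T <= 0)
    abort_capres("transit time must be a single positive number",
                 "capres_validation_error")
  new_residue_function(c(0, T), c(1, 0))
}

#' Evaluate a residue function
#'
#' @param R A `residue_function`.
#' @param t Times (s), >= 0; R is right-continuous and 0 beyond its last
#'   breakpoint.
#' @return R(t), vectorized.
#' @export
residue_eval <- function(R, t) {
  if (any(t < 0)) abort_capres("t must be >= 0", "capres_validation_error")
  idx <- findInterval(t, R$breakpoints)
  R$values[idx]
}

#' Integral of a residue function (equals the mean transit time)
#'
#' Exact piecewise integration over the compact support; for a
#' mass-conserving network this equals `sum(live V) / Q_in`.
#'
#' @param R A `residue_function`.
#' @return The integral of R over `[0, Inf)`, s.
#' @export
residue_integral <- function(R) {
  m <- length(R$breakpoints)
  if (m < 2) return(0)
  sum(R$values[-m] * diff(R$breakpoints))
}

#' First time the residue function falls to or below a level
#'
#' @param R A `residue_function`.
#' @param level Threshold in `(0, 1]`.
#' @return The first `t` with `R(t) <= level` (a breakpoint).
#' @export
residue_time_below <- function(R, level) {
  k <- which(R$values <= level)
  if (length(k) == 0) return(Inf)
  R$breakpoints[min(k)]
}

#' Largest absolute difference between two residue functions
#'
#' Both functions are piecewise constant, so the supremum over `[0, Inf)`
#' is attained on the intervals delimited by the union of their
#' breakpoints; each interval is probed at its midpoint. Slivers
#' narrower than `rel_tol` (relative) between nominally identical
#' breakpoints that differ only in floating-point representation are
#' ignored.
#'
#' @param R1,R2 `residue_function` objects.
#' @param rel_tol Relative width below which an interval between
#'   near-identical breakpoints is disregarded.
#' @return Sup-norm distance (up to `rel_tol`-slivers).
#' @export
residue_sup_gap <- function(R1, R2, rel_tol = 1e-9) {
  tt <- sort(unique(c(R1$breakpoints, R2$breakpoints)))
  keep <- c(TRUE, diff(tt) > rel_tol * pmax(abs(tt[-1]), 1e-12))
  tt <- tt[keep]
  probes <- c((tt[-1] + tt[-length(tt)]) / 2, max(tt) + 1)
  max(abs(residue_eval(R1, probes) - residue_eval(R2, probes)))
}

# ---- DAG dynamic programming ------------------------------------------

# Merge atoms with (near-)equal delays; prune negligible weights.
merge_atoms <- function(w, d, merge_tol = 1e-9, prune_tol = 1e-14) {
  dropped <- 0
  if (length(w) == 0) return(list(w = w, d = d, dropped = dropped))
  o <- order(d)
  w <- w[o]; d <- d[o]
  if (length(d) > 1) {
    gap <- diff(d)
    new_grp <- c(TRUE, gap > merge_tol * pmax(abs(d[-1]), 1e-12))
    grp <- cumsum(new_grp)
    if (max(grp) < length(d)) {
      ws <- as.numeric(rowsum(w, grp))
      dm <- as.numeric(rowsum(w * d, grp)) / ws
      w <- ws; d <- dm
    }
  }
  keep <- w >= prune_tol
  if (!all(keep)) {
    dropped <- sum(w[!keep])
    w <- w[keep]; d <- d[keep]
  }
  list(w = w, d = d, dropped = dropped)
}

# Single DP sweep: per-node arrival spectra plus all residue rectangles.
residue_dp <- function(sol, merge_tol = 1e-9, prune_tol = 1e-14) {
  nodes <- sol$net$nodes
  le <- sol$edges[sol$edges$live, , drop = FALSE]
  topo <- sol$topo
  role <- stats::setNames(nodes$role, as.character(nodes$id))

  out_by <- split(seq_len(nrow(le)), as.character(le$from))
  in_by <- split(seq_len(nrow(le)), as.character(le$to))

  # inlet shares of the common arterial input
  inlet_ids <- as.character(nodes$id[nodes$role == "arteriole_inlet"])
  pend_w <- new.env(parent = emptyenv())
  pend_d <- new.env(parent = emptyenv())
  for (id in inlet_ids) {
    oe <- out_by[[id]]
    share <- if (is.null(oe)) 0 else sum(le$Q[oe]) / sol$Q_in
    ie <- in_by[[id]]
    if (!is.null(ie)) share <- share - sum(le$Q[ie]) / sol$Q_in
    if (share > 0) {
      assign(id, list(share), envir = pend_w)
      assign(id, list(0), envir = pend_d)
    }
  }

  spectra <- vector("list", length(topo))
  names(spectra) <- topo
  rect_s <- vector("list", length(topo))
  rect_e <- vector("list", length(topo))
  rect_m <- vector("list", length(topo))
  dropped <- 0

  for (v in topo) {
    if (!exists(v, envir = pend_w, inherits = FALSE)) next
    w <- unlist(get(v, envir = pend_w), use.names = FALSE)
    d <- unlist(get(v, envir = pend_d), use.names = FALSE)
    sp <- merge_atoms(w, d, merge_tol, prune_tol)
    dropped <- dropped + sp$dropped
    spectra[[v]] <- list(weights = sp$w, delays = sp$d)
    if (length(sp$w) == 0) next

    oe <- out_by[[v]]
    if (is.null(oe) || length(oe) == 0) {
      # terminal node: tracer exits here (outlets) or is stranded
      if (role[[v]] != "venule_outlet") dropped <- dropped + sum(sp$w)
      next
    }
    outflow <- sum(le$Q[oe])
    for (k in oe) {
      b <- le$Q[k] / outflow
      tw <- sp$w * b
      td <- sp$d + le$T[k]
      rect_s[[v]] <- c(rect_s[[v]], list(sp$d))
      rect_e[[v]] <- c(rect_e[[v]], list(td))
      rect_m[[v]] <- c(rect_m[[v]], list(tw))
      tgt <- as.character(le$to[k])
      if (exists(tgt, envir = pend_w, inherits = FALSE)) {
        assign(tgt, c(get(tgt, envir = pend_w), list(tw)), envir = pend_w)
        assign(tgt, c(get(tgt, envir = pend_d), list(td)), envir = pend_d)
      } else {
        assign(tgt, list(tw), envir = pend_w)
        assign(tgt, list(td), envir = pend_d)
      }
    }
  }

  list(
    spectra = spectra,
    rect_start = unlist(rect_s, use.names = FALSE) %||% numeric(0),
    rect_end = unlist(rect_e, use.names = FALSE) %||% numeric(0),
    rect_mag = unlist(rect_m, use.names = FALSE) %||% numeric(0),
    dropped = dropped
  )
}

#' Arrival spectra of all network nodes
#'
#' For every node the spectrum of tracer arrivals is a finite set of
#' atoms (weight, delay): the probability that an inlet-injected tracer
#' particle reaches the node along some pathway with that accumulated
#' delay. Inlet nodes start with a single atom at delay 0 whose weight is
#' their share of the total inlet flow; each vessel propagates atoms with
#' weight multiplied by its flow fraction and delay increased by its
#' transit time. Atoms with delays equal within `merge_tol` (relative)
#' are merged; weights below `prune_tol` are dropped with the total
#' dropped mass reported.
#'
#' @param sol A `flow_solution` (its live flow graph must be acyclic,
#'   which the solver guarantees).
#' @param merge_tol,prune_tol Numerical housekeeping tolerances.
#' @return Object of class `arrival_spectrum`: a list with per-node
#'   `spectra` (each `list(weights, delays)`) and `dropped_mass`.
#' @export
arrival_spectra <- function(sol, merge_tol = 1e-9, prune_tol = 1e-14) {
  dp <- residue_dp(sol, merge_tol, prune_tol)
  structure(list(spectra = dp$spectra, dropped_mass = dp$dropped),
            class = "arrival_spectrum")
}

#' Exact residue function of a solved network
#'
#' Accumulates the rectangle contribution of every perfused vessel under
#' every upstream pathway into a single piecewise-constant function via a
#' sorted breakpoint sweep. The result starts at R(0) = 1 (asserted to
#' 1e-6 — the normalization by total inlet flow must emerge from mass
#' conservation, it is never imposed), is non-increasing and reaches 0 at
#' the longest perfused pathway time.
#'
#' @inheritParams arrival_spectra
#' @return A `residue_function`.
#' @export
network_residue <- function(sol, merge_tol = 1e-9, prune_tol = 1e-14) {
  dp <- residue_dp(sol, merge_tol, prune_tol)
  if (dp$dropped > 1e-9)
    abort_capres(sprintf("dropped atom mass %.3g exceeds 1e-9", dp$dropped),
                 "capres_consistency_error")
  tt <- c(dp$rect_start, dp$rect_end)
  dv <- c(dp$rect_mag, -dp$rect_mag)
  o <- order(tt)
  tt <- tt[o]; dv <- dv[o]
  # group events at (near-)identical times
  grp <- cumsum(c(TRUE, diff(tt) > merge_tol * pmax(abs(tt[-1]), 1e-12)))
  bt <- as.numeric(rowsum(tt * abs(dv), grp)) /
    pmax(as.numeric(rowsum(abs(dv), grp)), .Machine$double.xmin)
  bt[1] <- min(tt)
  dg <- as.numeric(rowsum(dv, grp))
  vals <- cumsum(dg)

  # compact: drop interior breakpoints with negligible net change
  keep <- c(TRUE, abs(dg[-1]) > 1e-12)
  keep[length(keep)] <- TRUE
  bt <- bt[keep]
  vals <- vals[keep]

  if (abs(bt[1]) > merge_tol)
    abort_capres("residue support does not start at 0",
                 "capres_consistency_error")
  bt[1] <- 0
  if (abs(vals[1] - 1) > 1e-6)
    abort_capres(sprintf(
      "R(0) = %.8f deviates from 1 beyond 1e-6 (dead-edge mishandling?)",
      vals[1]), "capres_consistency_error")
  if (any(diff(vals) > 1e-9))
    abort_capres("residue function is not non-increasing",
                 "capres_consistency_error")
  vals <- cummin(pmin(vals, vals[1]))
  if (abs(vals[length(vals)]) > 1e-9)
    abort_capres("residue function does not decay to 0",
                 "capres_consistency_error")
  vals[length(vals)] <- 0
  vals <- pmax(vals, 0)
  new_residue_function(bt, vals)
}

#' Transit-time distribution of a residue function
#'
#' h(t) = -dR/dt: one probability atom per downward breakpoint of R,
#' with mass equal to the drop. Reports the mean transit time
#' `MTT = sum(mass * time)` and the capillary transit-time heterogeneity
#' `CTTH = sd of the distribution`.
#'
#' @param R A `residue_function`.
#' @return Object of class `transit_time_distribution` with fields
#'   `times`, `masses`, `MTT`, `CTTH`.
#' @export
transit_time_distribution <- function(R) {
  v <- R$values
  if (any(diff(v) > 1e-9))
    abort_capres("residue function is not non-increasing",
                 "capres_validation_error")
  drops <- -diff(v)
  times <- R$breakpoints[-1]
  keep <- drops > 0
  times <- times[keep]
  masses <- drops[keep]
  mtt <- sum(masses * times)
  m2 <- sum(masses * times^2)
  ctth <- sqrt(max(m2 - mtt^2, 0))
  structure(list(times = times, masses = masses, MTT = mtt, CTTH = ctth),
            class = "transit_time_distribution")
}

#' @export
print.residue_function <- function(x, ...) {
  cat(sprintf("<residue_function> %d breakpoints, support [0, %.4g] s, integral (MTT) %.4g s\n",
              length(x$breakpoints), max(x$breakpoints), residue_integral(x)))
  invisible(x)
}

#' @export
print.transit_time_distribution <- function(x, ...) {
  cat(sprintf("<transit_time_distribution> %d atoms, total mass %.6f\n",
              length(x$times), sum(x$masses)))
  cat(sprintf("  MTT %.4g s, CTTH %.4g s\n", x$MTT, x$CTTH))
  invisible(x)
}
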