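# Independent cross-checks for the analytical residue function:
# stochastic particle tracking and brute-force pathway enumeration.
# Both exploit the fact that R(t) equals the survival function of the
# network traversal time of a flow-weighted random walk on the live DAG.

#' Monte-Carlo residue function
#'
#' Tracks tracer particles through the live flow DAG: each particle is
#' injected at an inlet with probability proportional to the inlet flow
#' and routed at every node to an outgoing vessel with probability
#' proportional to its flow, accumulating the vessel transit times. The
#' empirical survival function of the total traversal times is returned
#' as a `residue_function`.
#'
#' @param sol A `flow_solution`.
#' @param n_particles Number of particles (>= 1).
#' @param seed Integer seed.
#' @return An empirical `residue_function`.
#' @export
monte_carlo_residue <- function(sol, n_particles = 1e5, seed = 1L) {
  if (n_particles < 1)
    abort_capres("n_particles must be >= 1", "capres_validation_error")
  n_particles <- as.integer(n_particles)
  le <- sol$edges[sol$edges$live, , drop = FALSE]
  nodes <- sol$net$nodes
  out_by <- split(seq_len(nrow(le)), as.character(le$from))
  in_by <- split(seq_len(nrow(le)), as.character(le$to))
  inlet_ids <- as.character(nodes$id[nodes$role == "arteriole_inlet"])

  with_seed(seed, {
    shares <- vapply(inlet_ids, function(id) {
      s <- if (is.null(out_by[[id]])) 0 else sum(le$Q[out_by[[id]]])
      if (!is.null(in_by[[id]])) s <- s - sum(le$Q[in_by[[id]]])
      max(s, 0)
    }, numeric(1))
    counts <- as.vector(stats::rmultinom(1, n_particles, shares))

    at_node <- new.env(parent = emptyenv())
    for (i in seq_along(inlet_ids)) {
      if (counts[i] > 0)
        assign(inlet_ids[i], list(numeric(counts[i])), envir = at_node)
    }

    exit_times <- vector("list", 0)
    for (v in sol$topo) {
      if (!exists(v, envir = at_node, inherits = FALSE)) next
      times <- unlist(get(v, envir = at_node), use.names = FALSE)
      if (length(times) == 0) next
      oe <- out_by[[v]]
      if (is.null(oe) || length(oe) == 0) {
        exit_times <- c(exit_times, list(times))
        next
      }
      if (length(oe) == 1) {
        choice <- rep.int(1L, length(times))
      } else {
        choice <- sample.int(length(oe), length(times), replace = TRUE,
                             prob = le$Q[oe])
      }
      for (k in seq_along(oe)) {
        sel <- choice == k
        if (!any(sel)) next
        tgt <- as.character(le$to[oe[k]])
        tk <- times[sel] + le$T[oe[k]]
        if (exists(tgt, envir = at_node, inherits = FALSE)) {
          assign(tgt, c(get(tgt, envir = at_node), list(tk)), envir = at_node)
        } else {
          assign(tgt, list(tk), envir = at_node)
        }
      }
      rm(list = v, envir = at_node)
    }
    et <- sort(unlist(exit_times, use.names = FALSE))
    n <- length(et)
    ut <- unique(et)
    surv <- 1 - findInterval(ut, et) / n
    new_residue_function(c(0, ut), c(1, surv))
  })
}

#' Residue function by explicit pathway enumeration
#'
#' Brute-force oracle: enumerates every inlet-to-outlet pathway of the
#' live flow DAG by depth-first search, with pathway probability equal to
#' the product of the inlet share and the flow-split fractions, and
#' pathway time equal to the sum of vessel transit times. R(t) is the
#' survival function of the resulting discrete traversal-time
#' distribution. Exponential in network size; intended for small
#' fixtures (roughly <= 15 vessels).
#'
#' @param sol A `flow_solution`.
#' @param max_paths Safety cap on the number of enumerated pathways.
#' @return A `residue_function`.
#' @export
enumerate_paths_residue <- function(sol, max_paths = 1e6) {
  le <- sol$edges[sol$edges$live, , drop = FALSE]
  nodes <- sol$net$nodes
  out_by <- split(seq_len(nrow(le)), as.character(le$from))
  in_by <- split(seq_len(nrow(le)), as.character(le$to))
  inlet_ids <- as.character(nodes$id[nodes$role == "arteriole_inlet"])

  probs <- numeric(0)
  times <- numeric(0)
  n_paths <- 0L
  visit <- function(v, w, t) {
    oe <- out_by[[v]]
    if (is.null(oe) || length(oe) == 0) {
      n_paths <<- n_paths + 1L
      if (n_paths > max_paths)
        abort_capres("pathway enumeration exceeded max_paths",
                     "capres_validation_error")
      probs[n_paths] <<- w
      times[n_paths] <<- t
      return(invisible())
    }
    outflow <- sum(le$Q[oe])
    for (k in oe)
      visit(as.character(le$to[k]), w * le$Q[k] / outflow, t + le$T[k])
  }
  for (id in inlet_ids) {
    s <- if (is.null(out_by[[id]])) 0 else sum(le$Q[out_by[[id]]])
    if (!is.null(in_by[[id]])) s <- s - sum(le$Q[in_by[[id]]])
    if (s > 0) visit(id, s / sol$Q_in, 0)
  }
  o <- order(times)
  times <- times[o]; probs <- probs[o]
  grp <- cumsum(c(TRUE, diff(times) > 1e-12 * pmax(times[-1], 1e-12)))
  ut <- as.numeric(rowsum(times * probs, grp)) /
    as.numeric(rowsum(probs, grp))
  mass <- as.numeric(rowsum(probs, grp))
  surv <- sum(mass) - cumsum(mass)
  surv[length(surv)] <- 0
  new_residue_function(c(0, ut), c(sum(mass), pmax(surv, 0)))
}
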