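# Steady Poiseuille flow on a vessel network.
#
# Each vessel is a resistor with conductance g = pi d^4 / (128 mu(d) L)
# where mu(d) is the apparent blood viscosity at the working haematocrit.
# Inlet nodes are held at delta_p, outlet nodes at 0, and interior node
# pressures follow from mass conservation (a weighted graph Laplacian
# system). Internal units: um, s, Pa, so flows are um^3/s; conversion to
# clinical units happens only in haemodynamics().

#' Solve steady Poiseuille flow on a capillary network
#'
#' @param net A `vessel_network`.
#' @param delta_p Pressure difference (Pa) between the arteriole-capillary
#'   and capillary-venule junctions; inlets are fixed at `delta_p`,
#'   outlets at 0.
#' @param plasma_viscosity Plasma viscosity, mPa s.
#' @param haematocrit Discharge haematocrit (constant across the bed).
#' @param viscosity_law Pries law variant, see
#'   [pries_relative_viscosity()].
#' @param flow_tolerance Edges with `|Q| < flow_tolerance * Q_in` are
#'   classified dead (no perfusion) and excluded from the flow-directed
#'   DAG, residue and blood-volume computations.
#' @param on_floating What to do with connected components containing no
#'   boundary node (possible after occlusion): `"dead"` marks their
#'   edges dead with undefined pressures; `"error"` raises a solver
#'   error.
#' @return A `flow_solution`: node `pressures` (Pa, named by node id; NA
#'   for floating components), an `edges` data frame with orientation
#'   (`from`, `to` along positive flow), flow `Q` (um^3/s), mean velocity
#'   `U` (um/s), transit time `T = L/U = V/Q` (s), volume `V` (um^3) and a
#'   `live` flag; total inlet flow `Q_in`; and the topological order of
#'   the live flow DAG.
#' @export
solve_flow <- function(net, delta_p = 1000, plasma_viscosity = 1.2,
                       haematocrit = 0.45,
                       viscosity_law = c("in_vivo", "in_vitro"),
                       flow_tolerance = 1e-12,
                       on_floating = c("dead", "error")) {
  viscosity_law <- match.arg(viscosity_law)
  on_floating <- match.arg(on_floating)
  if (delta_p <= 0)
    abort_capres("delta_p must be positive", "capres_validation_error")
  validate_network(net, require_connected = FALSE)

  nodes <- net$nodes
  edges <- net$edges
  n <- nrow(nodes)
  id2idx <- stats::setNames(seq_len(n), as.character(nodes$id))
  ei <- id2idx[as.character(edges$node_i)]
  ej <- id2idx[as.character(edges$node_j)]

  mu <- apparent_viscosity(edges$diameter, haematocrit, plasma_viscosity,
                           viscosity_law)                      # mPa s
  g <- pi * edges$diameter^4 / (128 * (mu * 1e-3) * edges$length) # um^3/(s Pa)

  is_in <- nodes$role == "arteriole_inlet"
  is_out <- nodes$role == "venule_outlet"
  boundary <- is_in | is_out

  # components of the (undirected) vessel graph
  g_und <- network_igraph(net)
  comp <- igraph::components(g_und)$membership[as.character(nodes$id)]
  bcomp <- unique(comp[boundary])
  if (length(intersect(unique(comp[is_in]), unique(comp[is_out]))) == 0)
    abort_capres("no inlet is connected to any outlet",
                 "capres_solver_error")
  floating <- !(comp %in% bcomp)
  deg <- tabulate(c(ei, ej), nbins = n)
  floating <- floating | (deg == 0 & !boundary)
  if (any(floating) && on_floating == "error")
    abort_capres(sprintf(
      "singular system: component(s) {%s} contain no boundary node",
      paste(sort(unique(comp[floating])), collapse = ",")),
      "capres_solver_error")

  solvable_edge <- !(floating[ei] | floating[ej])
  interior <- which(!boundary & !floating)

  p <- rep(NA_real_, n)
  p[is_in] <- delta_p
  p[is_out] <- 0

  if (length(interior) > 0) {
    se <- which(solvable_edge)
    ii <- ei[se]; jj <- ej[se]; gg <- g[se]
    # weighted Laplacian triplets over solvable nodes
    L <- Matrix::sparseMatrix(
      i = c(ii, jj, ii, jj),
      j = c(jj, ii, ii, jj),
      x = c(-gg, -gg, gg, gg),
      dims = c(n, n)
    )
    A <- L[interior, interior, drop = FALSE]
    bnd <- which(boundary)
    rhs <- -L[interior, bnd, drop = FALSE] %*% p[bnd]
    sol <- tryCatch(Matrix::solve(A, rhs),
                    error = function(e) abort_capres(
                      paste0("pressure system is singular: ", conditionMessage(e)),
                      "capres_solver_error"))
    p[interior] <- as.numeric(sol)
  }

  dp <- p[ei] - p[ej]
  dp[!solvable_edge] <- 0
  Q_signed <- g * dp
  # orient edges along positive flow
  fwd <- !is.na(Q_signed) & Q_signed >= 0
  from <- ifelse(fwd, edges$node_i, edges$node_j)
  to <- ifelse(fwd, edges$node_j, edges$node_i)
  Q <- abs(Q_signed)
  Q[is.na(Q)] <- 0

  # total inflow: sum of net outflow from inlet nodes
  from_idx <- id2idx[as.character(from)]
  to_idx <- id2idx[as.character(to)]
  Q_in <- sum(Q[is_in[from_idx]]) - sum(Q[is_in[to_idx]])
  if (Q_in <= 0)
    abort_capres("degenerate flow: total inlet flow is zero",
                 "capres_solver_error")

  live <- solvable_edge & Q >= flow_tolerance * Q_in
  area <- pi / 4 * edges$diameter^2
  V <- area * edges$length
  U <- ifelse(live, Q / area, NA_real_)
  Tt <- ifelse(live, V / Q, NA_real_)

  edf <- data.frame(
    from = from, to = to,
    Q = Q, U = U, T = Tt, V = V,
    length = edges$length, diameter = edges$diameter,
    live = live
  )

  topo <- flow_topo_order(edf, nodes)

  structure(list(
    net = net,
    pressures = stats::setNames(p, as.character(nodes$id)),
    edges = edf,
    Q_in = Q_in,
    delta_p = delta_p,
    params = list(plasma_viscosity = plasma_viscosity,
                  haematocrit = haematocrit,
                  viscosity_law = viscosity_law,
                  flow_tolerance = flow_tolerance),
    topo = topo
  ), class = "flow_solution")
}

# Topological order of the live flow DAG (node ids as character).
flow_topo_order <- function(edf, nodes) {
  le <- edf[edf$live, , drop = FALSE]
  verts <- as.character(nodes$id)
  gd <- igraph::graph_from_data_frame(
    data.frame(from = as.character(le$from), to = as.character(le$to)),
    directed = TRUE, vertices = data.frame(name = verts))
  ts <- tryCatch(igraph::topo_sort(gd, mode = "out"),
                 error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(ts) || length(ts) < length(verts))
    abort_capres("live flow graph is cyclic", "capres_consistency_error")
  names(ts)
}

#' Rescale a flow solution to a different driving pressure
#'
#' Poiseuille flow is linear in the boundary pressure difference, so the
#' solution at `factor * delta_p` is obtained without re-solving: all
#' pressures, flows and velocities scale by `factor` and all transit
#' times by `1/factor`.
#'
#' @param sol A `flow_solution`.
#' @param factor Positive scale factor on the pressure difference.
#' @return A `flow_solution`.
#' @export
rescale_pressure <- function(sol, factor) {
  if (factor <= 0)
    abort_capres("factor must be positive", "capres_validation_error")
  sol$pressures <- sol$pressures * factor
  sol$edges$Q <- sol$edges$Q * factor
  sol$edges$U <- sol$edges$U * factor
  sol$edges$T <- sol$edges$T / factor
  sol$Q_in <- sol$Q_in * factor
  sol$delta_p <- sol$delta_p * factor
  sol
}

#' Perfusion metrics of a solved network
#'
#' Converts the microscopic flow solution into the clinical perfusion
#' quantities: CBF (ml blood per 100 ml tissue per minute), CBV (ml per
#' 100 ml, counting only perfused vessels) and MTT (s). They satisfy
#' `MTT * CBF = 60 * CBV`.
#'
#' @param sol A `flow_solution`.
#' @param net The network it was solved on (defaults to the one stored in
#'   `sol`).
#' @return List with `CBF`, `CBV`, `MTT`.
#' @export
haemodynamics <- function(sol, net = sol$net) {
  cube_vol <- net$cube_edge^3                      # um^3
  if (sol$Q_in <= 0)
    abort_capres("degenerate flow: Q_in is zero", "capres_solver_error")
  V_live <- sum(sol$edges$V[sol$edges$live])
  CBF <- sol$Q_in / cube_vol * 6000                # -> ml/100ml/min
  CBV <- 100 * V_live / cube_vol
  MTT <- V_live / sol$Q_in                         # s
  list(CBF = CBF, CBV = CBV, MTT = MTT)
}

#' @export
print.flow_solution <- function(x, ...) {
  h <- haemodynamics(x)
  cat(sprintf("<flow_solution> dP = %g Pa, Q_in = %.4g um^3/s (%d live / %d edges)\n",
              x$delta_p, x$Q_in, sum(x$edges$live), nrow(x$edges)))
  cat(sprintf("  CBF %.1f ml/100ml/min, CBV %.2f ml/100ml, MTT %.3f s\n",
              h$CBF, h$CBV, h$MTT))
  invisible(x)
}
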