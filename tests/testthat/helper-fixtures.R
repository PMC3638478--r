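# Fixture builders: tiny hand-made networks with known flow solutions,
# and synthetic flow_solution objects for residue-layer unit tests.

# straight line of nodes along x in a cube, roles at the ends
fx_chain_network <- function(lengths, diameters, cube_edge = 300) {
  n <- length(lengths) + 1
  x <- seq(0, cube_edge, length.out = n)
  nodes <- data.frame(id = seq_len(n) - 1L, x = x, y = cube_edge / 2,
                      z = cube_edge / 2,
                      role = c("arteriole_inlet",
                               rep("interior", max(n - 2, 0)),
                               "venule_outlet"))
  edges <- data.frame(node_i = seq_len(n - 1) - 1L, node_j = seq_len(n - 1),
                      length = lengths, diameter = diameters)
  vessel_network(nodes, edges, cube_edge)
}

fx_single_vessel <- function(L = 60, d = 6, cube_edge = 250) {
  fx_chain_network(L, d, cube_edge)
}

# one inlet vessel splitting into two identical branches to two outlets
fx_symmetric_y <- function(cube_edge = 200) {
  nodes <- data.frame(
    id = 0:3,
    x = c(0, 100, 200, 200),
    y = c(100, 100, 50, 150),
    z = 100,
    role = c("arteriole_inlet", "interior", "venule_outlet", "venule_outlet"))
  edges <- data.frame(node_i = c(0L, 1L, 1L), node_j = c(1L, 2L, 3L),
                      length = c(80, 60, 60), diameter = c(8, 6, 6))
  vessel_network(nodes, edges, cube_edge)
}

# 8-node, 12-edge irregular network for oracle comparisons (fixed tables)
fx_small_network <- function(cube_edge = 200) {
  nodes <- data.frame(
    id = 0:7,
    x = c(0, 5, 60, 70, 110, 140, 195, 200),
    y = c(80, 150, 40, 120, 170, 60, 100, 30),
    z = c(100, 90, 120, 60, 110, 140, 80, 100),
    role = c("arteriole_inlet", "arteriole_inlet", "interior", "interior",
             "interior", "interior", "venule_outlet", "venule_outlet"))
  edges <- data.frame(
    node_i = c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 2L),
    node_j = c(2L, 3L, 3L, 4L, 3L, 5L, 4L, 5L, 6L, 5L, 7L, 7L),
    length = c(70, 90, 55, 75, 40, 85, 66, 58, 92, 49, 77, 120),
    diameter = c(6.5, 5.8, 7.1, 6.0, 5.5, 6.8, 6.2, 5.9, 7.4, 6.1, 5.6, 6.3))
  vessel_network(nodes, edges, cube_edge)
}

# Build a flow_solution directly from a directed edge table (from, to, Q,
# T). Bypasses the Poiseuille solver so residue-layer tests can pin
# transit times exactly.
fx_solution <- function(from, to, Q, T, roles) {
  ids <- sort(unique(c(from, to)))
  nodes <- data.frame(id = ids, x = 0, y = 0, z = 0,
                      role = roles[as.character(ids)],
                      isolated = FALSE, stringsAsFactors = FALSE)
  edges <- data.frame(from = from, to = to, Q = Q, T = T, V = Q * T,
                      U = NA_real_, length = NA_real_, diameter = NA_real_,
                      live = TRUE)
  net <- structure(list(nodes = nodes, edges = edges, cube_edge = 1),
                   class = "vessel_network")
  gd <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to)),
    directed = TRUE, vertices = data.frame(name = as.character(ids)))
  topo <- names(igraph::topo_sort(gd, mode = "out"))
  inlet_ids <- ids[nodes$role == "arteriole_inlet"]
  q_in <- sum(Q[from %in% inlet_ids]) - sum(Q[to %in% inlet_ids])
  structure(list(net = net, pressures = NULL, edges = edges, Q_in = q_in,
                 delta_p = NA_real_, params = list(), topo = topo),
            class = "flow_solution")
}

# series inlet -> mid -> outlet with transit times T1, T2
fx_sol_series <- function(T1 = 1, T2 = 2) {
  fx_solution(from = c(0L, 1L), to = c(1L, 2L), Q = c(1, 1), T = c(T1, T2),
              roles = c(`0` = "arteriole_inlet", `1` = "interior",
                        `2` = "venule_outlet"))
}

# two vessels in parallel from inlet to outlet, flow ratio q1:q2
fx_sol_parallel <- function(q1 = 2, q2 = 1, T1 = 1, T2 = 2) {
  fx_solution(from = c(0L, 0L), to = c(1L, 1L), Q = c(q1, q2), T = c(T1, T2),
              roles = c(`0` = "arteriole_inlet", `1` = "venule_outlet"))
}

# diamond: inlet splits 2:1 to a and b, both rejoin at the outlet
fx_sol_diamond <- function() {
  fx_solution(from = c(0L, 0L, 1L, 2L), to = c(1L, 2L, 3L, 3L),
              Q = c(2, 1, 2, 1), T = c(0.4, 1.1, 0.6, 0.9),
              roles = c(`0` = "arteriole_inlet", `1` = "interior",
                        `2` = "interior", `3` = "venule_outlet"))
}

# small-cube generator config for fast stochastic property tests
fx_small_config <- function() {
  utils::modifyList(default_network_config(), list(
    cube_edge_um = 150,
    target_density_per_mm3 = 7718
  ))
}

expect_capres_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}

# bypass connectivity validation (for deliberately broken fixtures)
new_vessel_network_for_tests <- function(nodes, edges, cube_edge) {
  nodes$isolated <- !(nodes$id %in% c(edges$node_i, edges$node_j))
  structure(list(nodes = nodes, edges = edges, cube_edge = cube_edge),
            class = "vessel_network")
}
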