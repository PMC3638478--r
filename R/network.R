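# Synthetic capillary network generation and morphometry.
#
# Networks are geometric graphs in a tissue cube: nodes carry 3-D
# coordinates (micrometres) and a role (interior, arteriole inlet or
# venule outlet); edges are vessels with a length and a diameter that are
# sampled attributes, deliberately decoupled from the straight-line node
# distance (capillaries are tortuous, so anatomical length exceeds chord
# length).

#' Default generator configuration
#'
#' Morphometric targets for the human cortical capillary bed: a 250 um
#' cube fed by 3 arteriole-capillary junctions and drained by 2
#' capillary-venule junctions, with vessel density 7718 per mm^3, mean
#' node connectivity 3.22, vessel length 59.71 +/- 51.61 um and diameter
#' 6.24 +/- 1.30 um.
#'
#' @return A named list of generator parameters (all lengths in um,
#'   density in vessels per mm^3).
#' @export
default_network_config <- function() {
  list(
    cube_edge_um = 250,
    n_inlets = 3L,
    n_outlets = 2L,
    target_density_per_mm3 = 7718,
    target_connectivity = 3.22,
    length_mean_um = 59.71,
    length_sd_um = 51.61,
    diameter_mean_um = 6.24,
    diameter_sd_um = 1.30,
    diameter_min_um = 2,
    max_calibration_iters = 500L
  )
}

new_vessel_network <- function(nodes, edges, cube_edge) {
  structure(list(nodes = nodes, edges = edges, cube_edge = cube_edge),
            class = "vessel_network")
}

#' Construct a vessel network from node and edge tables
#'
#' For user-supplied geometries. Node ids are 0-based integers; roles are
#' `"interior"`, `"arteriole_inlet"` or `"venule_outlet"`. Vessel length
#' is an independent anatomical attribute (tortuosity), not required to
#' equal the straight-line node distance.
#'
#' @param nodes Data frame with columns `id`, `x`, `y`, `z` (um), `role`.
#' @param edges Data frame with columns `node_i`, `node_j`, `length`
#'   (um), `diameter` (um).
#' @param cube_edge Tissue cube edge length, um.
#' @return A validated `vessel_network`.
#' @export
vessel_network <- function(nodes, edges, cube_edge) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (!"isolated" %in% names(nodes))
    nodes$isolated <- !(nodes$id %in% c(edges$node_i, edges$node_j))
  validate_network(new_vessel_network(nodes, edges, cube_edge))
}

#' Validate a vessel network
#'
#' Checks the structural invariants: connectedness, no self-loops or
#' duplicate edges, positive lengths and diameters, coordinates inside
#' the cube. Isolated nodes flagged by [occlude()] are tolerated.
#'
#' @param net A `vessel_network`.
#' @param require_connected Require the graph (ignoring flagged isolated
#'   nodes) to be a single connected component.
#' @return `net`, invisibly.
#' @export
validate_network <- function(net, require_connected = TRUE) {
  nodes <- net$nodes
  edges <- net$edges
  if (!is.data.frame(nodes) || !is.data.frame(edges))
    abort_capres("nodes and edges must be data frames", "capres_validation_error")
  if (net$cube_edge <= 0)
    abort_capres("cube_edge must be positive", "capres_validation_error")
  if (any(edges$length <= 0) || any(edges$diameter <= 0))
    abort_capres("all vessel lengths and diameters must be positive",
                 "capres_validation_error")
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  if (any(xyz < 0) || any(xyz > net$cube_edge))
    abort_capres("node coordinates must lie within the cube",
                 "capres_validation_error")
  if (any(edges$node_i == edges$node_j))
    abort_capres("self-loop edge found", "capres_validation_error")
  key <- paste(pmin(edges$node_i, edges$node_j), pmax(edges$node_i, edges$node_j))
  if (anyDuplicated(key))
    abort_capres("duplicate edge found", "capres_validation_error")
  if (!all(c(edges$node_i, edges$node_j) %in% nodes$id))
    abort_capres("edge endpoint not among node ids", "capres_validation_error")
  if (require_connected) {
    isolated <- if ("isolated" %in% names(nodes)) nodes$isolated else
      !(nodes$id %in% c(edges$node_i, edges$node_j))
    g <- network_igraph(net)
    comp <- igraph::components(g)
    live_nodes <- as.character(nodes$id[!isolated])
    memb <- comp$membership[live_nodes]
    if (length(unique(memb)) > 1)
      abort_capres("network is not connected", "capres_validation_error")
    deg <- igraph::degree(g)[live_nodes]
    if (any(deg < 1))
      abort_capres("unflagged node with degree 0", "capres_validation_error")
  }
  invisible(net)
}

# Undirected igraph view of a vessel_network; vertices named by node id.
network_igraph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(net$edges$node_i),
               to = as.character(net$edges$node_j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$id))
  )
}

# Greedy moment calibration: resample single entries, accept moves that
# reduce the relative mismatch of (mean, sd) against the targets.
calibrate_moments <- function(x, target_mean, target_sd, resample, iters) {
  score <- function(v) {
    abs(mean(v) - target_mean) / target_mean + abs(stats::sd(v) - target_sd) / target_sd
  }
  s <- score(x)
  n <- length(x)
  for (i in seq_len(iters)) {
    j <- sample.int(n, 1L)
    old <- x[j]
    x[j] <- resample(1L)
    s2 <- score(x)
    if (s2 < s) s <- s2 else x[j] <- old
  }
  x
}

rtrunc_normal <- function(n, mean, sd, lower) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::rnorm(n, mean, sd)
    out <- c(out, cand[cand > lower])
  }
  out[seq_len(n)]
}

#' Generate a synthetic capillary network
#'
#' Builds a random geometric capillary bed inside a cube. Node positions
#' are uniform in the cube; a minimum spanning tree (Prim) over Euclidean
#' distances guarantees connectedness, and additional short edges (drawn
#' among k-nearest-neighbour pairs) are added until the vessel count
#' implied by the target density is reached. Vessel lengths are
#' gamma-distributed and diameters truncated-normal, each greedily
#' calibrated to the configured mean and standard deviation. The
#' `n_inlets` nodes nearest the face x = 0 become arteriole inlets and
#' the `n_outlets` nodes nearest the opposite face become venule outlets.
#'
#' The vessel count is `round(density * cube volume)` and the node count
#' `round(2 * n_edges / target_connectivity)`, so density and mean degree
#' match their targets by construction.
#'
#' @param config Generator configuration, see [default_network_config()].
#' @param seed Integer seed; identical `(config, seed)` pairs give
#'   byte-identical networks.
#' @return A `vessel_network`.
#' @export
generate_network <- function(config = default_network_config(), seed = 1L) {
  cfg <- utils::modifyList(default_network_config(), config)
  if (cfg$cube_edge_um <= 0 || cfg$n_inlets < 1 || cfg$n_outlets < 1)
    abort_capres("cube_edge_um must be positive and inlet/outlet counts >= 1",
                 "capres_validation_error")
  if (cfg$target_density_per_mm3 < 0 || cfg$length_mean_um <= 0 ||
      cfg$diameter_mean_um <= 0)
    abort_capres("non-positive generator target", "capres_validation_error")

  vol_mm3 <- (cfg$cube_edge_um / 1000)^3
  n_edges <- as.integer(round(cfg$target_density_per_mm3 * vol_mm3))
  n_nodes <- as.integer(round(2 * n_edges / cfg$target_connectivity))
  if (n_nodes < cfg$n_inlets + cfg$n_outlets + 1L)
    abort_capres(sprintf(
      "target density yields %d nodes; need at least %d (inlets + outlets + 1)",
      n_nodes, cfg$n_inlets + cfg$n_outlets + 1L), "capres_validation_error")
  if (n_edges < n_nodes - 1L)
    abort_capres("target density yields fewer edges than a spanning tree",
                 "capres_validation_error")

  with_seed(seed, {
    xyz <- matrix(stats::runif(3L * n_nodes, 0, cfg$cube_edge_um), ncol = 3)
    colnames(xyz) <- c("x", "y", "z")
    d <- as.matrix(stats::dist(xyz))

    g_full <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE,
                                                  mode = "undirected")
    tree <- igraph::mst(g_full, algorithm = "prim")
    el <- igraph::as_edgelist(tree, names = FALSE)
    a <- pmin(el[, 1], el[, 2])
    b <- pmax(el[, 1], el[, 2])

    # candidate short extra edges: k-nearest-neighbour pairs not in tree
    n_extra <- n_edges - (n_nodes - 1L)
    k <- 6L
    repeat {
      nn <- t(apply(d, 1, function(r) order(r)[2:(k + 1L)]))
      ca <- rep(seq_len(n_nodes), each = k)
      cb <- as.vector(t(nn))
      lo <- pmin(ca, cb); hi <- pmax(ca, cb)
      key <- unique(paste(lo, hi))
      key <- setdiff(key, paste(a, b))
      if (length(key) >= n_extra || k >= n_nodes - 1L) break
      k <- min(n_nodes - 1L, k * 2L)
    }
    if (n_extra > 0L) {
      pick <- sample(key, n_extra)
      pk <- do.call(rbind, strsplit(pick, " "))
      a <- c(a, as.integer(pk[, 1]))
      b <- c(b, as.integer(pk[, 2]))
    }

    len <- stats::rgamma(n_edges,
                         shape = (cfg$length_mean_um / cfg$length_sd_um)^2,
                         scale = cfg$length_sd_um^2 / cfg$length_mean_um)
    len <- calibrate_moments(
      len, cfg$length_mean_um, cfg$length_sd_um,
      function(n) stats::rgamma(n,
                                shape = (cfg$length_mean_um / cfg$length_sd_um)^2,
                                scale = cfg$length_sd_um^2 / cfg$length_mean_um),
      cfg$max_calibration_iters)
    dia <- rtrunc_normal(n_edges, cfg$diameter_mean_um, cfg$diameter_sd_um,
                         cfg$diameter_min_um)
    dia <- calibrate_moments(
      dia, cfg$diameter_mean_um, cfg$diameter_sd_um,
      function(n) rtrunc_normal(n, cfg$diameter_mean_um, cfg$diameter_sd_um,
                                cfg$diameter_min_um),
      cfg$max_calibration_iters)

    check_calib <- function(x, tm, ts, what) {
      if (abs(mean(x) - tm) / tm > 0.10)
        abort_capres(sprintf("calibration failed for %s_mean (got %.2f, target %.2f)",
                             what, mean(x), tm), "capres_calibration_error")
      if (abs(stats::sd(x) - ts) / ts > 0.30)
        abort_capres(sprintf("calibration failed for %s_sd (got %.2f, target %.2f)",
                             what, stats::sd(x), ts), "capres_calibration_error")
    }
    check_calib(len, cfg$length_mean_um, cfg$length_sd_um, "length")
    check_calib(dia, cfg$diameter_mean_um, cfg$diameter_sd_um, "diameter")

    role <- rep("interior", n_nodes)
    ord <- order(xyz[, "x"])
    inlets <- ord[seq_len(cfg$n_inlets)]
    outlets <- rev(ord)[seq_len(cfg$n_outlets)]
    if (length(intersect(inlets, outlets)) > 0)
      abort_capres("too few nodes to separate inlets from outlets",
                   "capres_validation_error")
    role[inlets] <- "arteriole_inlet"
    role[outlets] <- "venule_outlet"

    nodes <- data.frame(id = seq_len(n_nodes) - 1L,
                        x = xyz[, "x"], y = xyz[, "y"], z = xyz[, "z"],
                        role = role, isolated = FALSE,
                        stringsAsFactors = FALSE)
    edges <- data.frame(node_i = a - 1L, node_j = b - 1L,
                        length = len, diameter = dia)
    net <- new_vessel_network(nodes, edges, cfg$cube_edge_um)
    validate_network(net)
  })
}

#' Morphometric summary of a network
#'
#' @param net A `vessel_network`.
#' @return List with vessel density (mm^-3), connectivity (mean node
#'   degree), unweighted length/diameter mean and sample s.d. (um) and
#'   the vessel count.
#' @export
network_stats <- function(net) {
  if (nrow(net$edges) == 0)
    abort_capres("network has no edges", "capres_validation_error")
  e <- net$edges
  vol_mm3 <- (net$cube_edge / 1000)^3
  list(
    vessel_density = nrow(e) / vol_mm3,
    connectivity = 2 * nrow(e) / nrow(net$nodes),
    length_mean = mean(e$length),
    length_sd = stats::sd(e$length),
    diameter_mean = mean(e$diameter),
    diameter_sd = stats::sd(e$diameter),
    n_vessels = nrow(e)
  )
}

#' Randomly occlude a fraction of vessels
#'
#' Removes `round(fraction * n_edges)` edges chosen uniformly at random
#' without replacement, emulating capillary blockage. Nodes left with no
#' incident vessel are retained and flagged `isolated`. Errors if the
#' occlusion disconnects every inlet from every outlet (no perfusable
#' path remains).
#'
#' @param net A `vessel_network`.
#' @param fraction Proportion of vessels to block, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A new `vessel_network`; the input is unmodified.
#' @export
occlude <- function(net, fraction, seed = 1L) {
  if (fraction < 0 || fraction >= 1)
    abort_capres("fraction must be in [0, 1)", "capres_validation_error")
  n_remove <- as.integer(round(fraction * nrow(net$edges)))
  if (n_remove == 0L) return(net)
  keep <- with_seed(seed, {
    drop <- sample.int(nrow(net$edges), n_remove)
    setdiff(seq_len(nrow(net$edges)), drop)
  })
  edges <- net$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- net$nodes
  nodes$isolated <- !(nodes$id %in% c(edges$node_i, edges$node_j))
  out <- new_vessel_network(nodes, edges, net$cube_edge)

  g <- network_igraph(out)
  comp <- igraph::components(g)$membership
  in_comp <- comp[as.character(nodes$id[nodes$role == "arteriole_inlet"])]
  out_comp <- comp[as.character(nodes$id[nodes$role == "venule_outlet"])]
  if (length(intersect(in_comp, out_comp)) == 0)
    abort_capres("occlusion disconnected every inlet from every outlet",
                 "capres_connectivity_error")
  out
}

#' @export
print.vessel_network <- function(x, ...) {
  s <- tryCatch(network_stats(x), error = function(e) NULL)
  cat(sprintf("<vessel_network> %d nodes, %d vessels in a %g um cube\n",
              nrow(x$nodes), nrow(x$edges), x$cube_edge))
  cat(sprintf("  inlets: %d, outlets: %d\n",
              sum(x$nodes$role == "arteriole_inlet"),
              sum(x$nodes$role == "venule_outlet")))
  if (!is.null(s))
    cat(sprintf("  density %.0f mm^-3, connectivity %.2f, length %.1f +/- %.1f um, diameter %.2f +/- %.2f um\n",
                s$vessel_density, s$connectivity, s$length_mean, s$length_sd,
                s$diameter_mean, s$diameter_sd))
  invisible(x)
}
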