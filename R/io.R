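# Reading and writing networks and derived objects in plain-text formats.

#' Write a vessel network to JSON
#'
#' The file holds `cube_edge_um`, a `nodes` array (`id, x, y, z, role`)
#' and an `edges` array (`node_i, node_j, length, diameter`); node ids
#' are 0-based integers. Serialization is deterministic for a given
#' network.
#'
#' @param net A `vessel_network`.
#' @param path Output file path (or connection).
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  nodes <- net$nodes[, c("id", "x", "y", "z", "role")]
  obj <- list(cube_edge_um = net$cube_edge, nodes = nodes, edges = net$edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a vessel network from JSON
#'
#' @param path File written by [write_network_json()] (or any JSON with
#'   the same fields).
#' @return A `vessel_network`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes)
  nodes$id <- as.integer(nodes$id)
  edges <- as.data.frame(obj$edges)
  edges$node_i <- as.integer(edges$node_i)
  edges$node_j <- as.integer(edges$node_j)
  nodes$isolated <- !(nodes$id %in% c(edges$node_i, edges$node_j))
  net <- new_vessel_network(nodes, edges, obj$cube_edge_um)
  validate_network(net, require_connected = FALSE)
  net
}

#' Write a vessel network as a CSV pair
#'
#' @param net A `vessel_network`.
#' @param nodes_path,edges_path Output paths for the node and edge
#'   tables.
#' @return Invisibly, the two paths.
#' @export
write_network_csv <- function(net, nodes_path, edges_path) {
  utils::write.csv(net$nodes[, c("id", "x", "y", "z", "role")],
                   nodes_path, row.names = FALSE)
  utils::write.csv(net$edges, edges_path, row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}

#' Read a vessel network from a CSV pair
#'
#' @param nodes_path,edges_path Node and edge tables with the columns of
#'   [write_network_csv()].
#' @param cube_edge_um Cube edge length, um.
#' @return A `vessel_network`.
#' @export
read_network_csv <- function(nodes_path, edges_path, cube_edge_um) {
  nodes <- utils::read.csv(nodes_path, stringsAsFactors = FALSE)
  edges <- utils::read.csv(edges_path, stringsAsFactors = FALSE)
  nodes$isolated <- !(nodes$id %in% c(edges$node_i, edges$node_j))
  net <- new_vessel_network(nodes, edges, cube_edge_um)
  validate_network(net, require_connected = FALSE)
  net
}

#' Export a residue function as CSV
#'
#' Two columns: `t_start_s` (breakpoint) and `value` (R on the half-open
#' interval starting there).
#'
#' @param R A `residue_function`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_residue_csv <- function(R, path) {
  utils::write.csv(data.frame(t_start_s = R$breakpoints, value = R$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a residue function from CSV
#'
#' @param path File with columns `t_start_s`, `value`.
#' @return A `residue_function`.
#' @export
read_residue_csv <- function(path) {
  df <- utils::read.csv(path)
  new_residue_function(df$t_start_s, df$value)
}
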