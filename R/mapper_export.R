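#' Convert a Mapper graph to an igraph object
#'
#' Nodes carry `size`, `interval_index`, `mean_support`,
#' `mean_confidence` and `mean_lift` attributes; edges carry
#' `shared_count`. Isolated nodes are preserved.
#'
#' @param graph A `mapper_graph` from [run_mapper()] or [build_nerve()].
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "mapper_graph"))
  vertices <- data.frame(
    name = graph$nodes$node_id,
    size = graph$nodes$size,
    interval_index = graph$nodes$interval_index,
    mean_support = graph$nodes$mean_support,
    mean_confidence = graph$nodes$mean_confidence,
    mean_lift = graph$nodes$mean_lift,
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = graph$edges$from, to = graph$edges$to,
                      shared_count = graph$edges$shared_count,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Write a Mapper graph to GraphML
#'
#' @param graph A `mapper_graph`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_mapper_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Write a Mapper graph to Graphviz DOT
#'
#' @param graph A `mapper_graph`.
#' @param path Output `.dot` path.
#' @return `path`, invisibly.
#' @export
write_mapper_dot <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "dot")
  invisible(path)
}

#' Write the node-membership table of a Mapper graph
#'
#' Flat CSV with one row per (node, member rule): columns `node_id`,
#' `rule_id`.
#'
#' @param graph A `mapper_graph`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mapper_membership <- function(graph, path) {
  out <- tibble::tibble(
    node_id = rep(graph$nodes$node_id,
                  vapply(graph$nodes$members, length, integer(1))),
    rule_id = unlist(graph$nodes$members)
  )
  readr::write_csv(out, path)
  invisible(path)
}
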