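#' Interaction graph
#'
#' Simple undirected interaction topology. A mean-field graph is the
#' complete graph without materialized edges (every other agent is a
#' neighbour); otherwise the graph is stored as an adjacency list built
#' from an edge matrix. Node ids are 1..n internally.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param edges Two-column integer matrix/data.frame of undirected edges
#'   (ignored when `mean_field = TRUE`). Self-loops and duplicates are
#'   dropped.
#' @param mean_field Logical; complete-graph topology.
#' @return An object of class `interaction_graph` with fields `n_nodes`,
#'   `mean_field`, and (for materialized graphs) `adj`, a list of
#'   neighbour index vectors, and `edges`, the deduplicated edge matrix.
#' @export
interaction_graph <- function(n_nodes, edges = NULL, mean_field = FALSE) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 2L) stop("need at least 2 nodes")
  if (mean_field)
    return(structure(list(n_nodes = n_nodes, mean_field = TRUE,
                          adj = NULL, edges = NULL),
                     class = "interaction_graph"))
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  if (ncol(edges) != 2L) stop("edges must have two columns")
  if (nrow(edges)) {
    if (any(edges < 1L | edges > n_nodes))
      stop("edge endpoint outside 1..n_nodes")
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]   # no loops
    key <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(key)
  }
  adj <- rep(list(integer(0)), n_nodes)
  if (nrow(edges)) {
    both <- rbind(edges, edges[, 2:1, drop = FALSE])
    sp <- split(both[, 2], both[, 1])
    for (nm in names(sp)) adj[[as.integer(nm)]] <- sort(unname(sp[[nm]]))
  }
  structure(list(n_nodes = n_nodes, mean_field = FALSE,
                 adj = adj, edges = edges),
            class = "interaction_graph")
}

#' Complete (mean-field) interaction graph
#' @param n Number of agents.
#' @return An `interaction_graph` with the mean-field flag set.
#' @export
mean_field_graph <- function(n) interaction_graph(n, mean_field = TRUE)

#' Neighbours of a node
#' @param graph An [interaction_graph()].
#' @param i Node index (1-based).
#' @return Integer vector of neighbour indices.
#' @export
graph_neighbors <- function(graph, i) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (graph$mean_field) return(setdiff(seq_len(graph$n_nodes), i))
  graph$adj[[i]]
}

#' Number of edges
#' @param graph An [interaction_graph()].
#' @return Edge count (mean-field: n(n-1)/2).
#' @export
n_edges <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (graph$mean_field) return(graph$n_nodes * (graph$n_nodes - 1) / 2)
  nrow(graph$edges)
}

#' @export
print.interaction_graph <- function(x, ...) {
  if (x$mean_field)
    cat("<interaction_graph> mean-field,", x$n_nodes, "nodes\n")
  else
    cat("<interaction_graph>", x$n_nodes, "nodes,", nrow(x$edges),
        "edges\n")
  invisible(x)
}

#' Convert an igraph object
#' @param g An undirected `igraph` graph.
#' @return An [interaction_graph()].
#' @export
as_interaction_graph <- function(g) {
  stopifnot(inherits(g, "igraph"))
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  interaction_graph(igraph::vcount(g), edges = igraph::as_edgelist(g))
}

# 0-based adjacency for the compiled driver; NULL means mean-field
adjacency_for_cpp <- function(graph) {
  if (graph$mean_field) return(NULL)
  lapply(graph$adj, function(v) as.integer(v - 1L))
}
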