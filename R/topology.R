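# Topological descriptors of the thresholded abstraction graph, viewed as a
# 1-dimensional simplicial complex.

#' Threshold an abstraction graph
#'
#' Keeps edges whose connectivity is at least `tau` (inclusive, following the
#' reporting convention "connectivity >= 0.05"); every cluster node is
#' retained, including nodes left isolated.
#'
#' @param graph an [compute_paga()] result, or a symmetric non-negative
#'   connectivity matrix with zero diagonal.
#' @param tau connectivity threshold (default 0.05).
#' @return An undirected simple `igraph` graph whose vertices are the clusters
#'   (edge attribute `weight` carries the connectivity).
#' @export
threshold_abstraction <- function(graph, tau = 0.05) {
  conn <- if (inherits(graph, "abstraction_graph")) graph$connectivity else as.matrix(graph)
  if (tau < 0) stop("`tau` must be non-negative")
  if (nrow(conn) != ncol(conn)) stop("connectivity matrix must be square")
  keep <- conn
  keep[conn < tau | conn <= 0] <- 0
  g <- igraph::graph_from_adjacency_matrix(keep, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(rownames(conn))) {
    igraph::V(g)$name <- rownames(conn)
  }
  g
}

#' Betti numbers of a graph
#'
#' Treats an undirected simple graph as a 1-complex: `beta0` is the number of
#' connected components and `beta1 = E - V + beta0` the number of independent
#' loops (the cycle-space rank). Any forest has `beta1 = 0`.
#'
#' @param graph an `igraph` graph (no self-loops), or an [compute_paga()]
#'   result / connectivity matrix, in which case it is first passed through
#'   [threshold_abstraction()] at `tau`.
#' @param tau threshold used when `graph` is not already an `igraph` object
#'   (default 0.05).
#' @return An object of class `topology_summary`: list with `n_nodes`,
#'   `n_edges`, `beta0`, `beta1`, `tau`.
#' @examples
#' tri <- igraph::make_ring(3)
#' betti_numbers(tri)$beta1 # 1
#' @export
betti_numbers <- function(graph, tau = 0.05) {
  if (!igraph::is_igraph(graph)) {
    graph <- threshold_abstraction(graph, tau = tau)
  } else {
    tau <- NA_real_
  }
  if (any(igraph::which_loop(graph))) stop("self-loops are not allowed")
  v <- as.integer(igraph::vcount(graph))
  e <- as.integer(igraph::ecount(graph))
  b0 <- if (v == 0L) 0L else as.integer(igraph::components(graph)$no)
  structure(
    list(n_nodes = v, n_edges = e, beta0 = b0,
         beta1 = e - v + b0, tau = tau),
    class = "topology_summary"
  )
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf("<topology_summary: V = %d, E = %d, beta0 = %d, beta1 = %d%s>\n",
              x$n_nodes, x$n_edges, x$beta0, x$beta1,
              if (!is.na(x$tau)) sprintf(", tau = %g", x$tau) else ""))
  invisible(x)
}

#' Serialize a topology summary to JSON
#'
#' @param x a [betti_numbers()] result.
#' @param path output file path.
#' @param extra named list appended to the record (e.g. seed, config echo).
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(x, path, extra = list()) {
  stopifnot(inherits(x, "topology_summary"))
  rec <- c(list(n_nodes = x$n_nodes, n_edges = x$n_edges,
                beta0 = x$beta0, beta1 = x$beta1, tau = x$tau), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
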