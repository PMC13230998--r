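# Partition-based graph abstraction: cluster-level connectivity from the
# directed kNN adjacency.

#' Cluster-level PAGA connectivity
#'
#' Computes the symmetric cluster-pair connectivity of partition-based graph
#' abstraction from the binarized directed kNN adjacency: with \eqn{e_{ab}} the
#' number of kNN edges between clusters `a` and `b` (both directions),
#' \eqn{\epsilon_a} the number of directed edges incident to cluster `a`
#' (within-cluster plus outgoing inter-cluster), and \eqn{n_a} the cluster
#' sizes, the connectivity is
#' \deqn{c_{ab} = \min\!\left(1,\;
#'   \frac{e_{ab}}{(\epsilon_a n_b + \epsilon_b n_a)/(n - 1)}\right),}
#' i.e. the observed inter-cluster edge count relative to its expectation under
#' random edge placement given cluster sizes. Pairs with no inter-cluster edge
#' have connectivity zero. This is the current default statistic of the
#' published reference implementation and agrees with it to numerical
#' precision.
#'
#' @param x a [run_standard_workflow()] result, or a directed binary adjacency
#'   matrix (cells x cells; entry `[i, j] != 0` means j is a kNN of i).
#' @param clusters per-cell cluster labels (defaults to `x$clusters` for a
#'   workflow result). Every cluster must be non-empty.
#' @return An object of class `abstraction_graph`: list with `connectivity`
#'   (K x K symmetric, zero diagonal, cluster names as dimnames), `sizes`,
#'   `inter_edges` (symmetrized inter-cluster kNN edge counts), `n_cells`.
#' @export
compute_paga <- function(x, clusters = NULL) {
  if (inherits(x, "manifold_workflow")) {
    adj <- x$knn_adj
    clusters <- clusters %||% x$clusters
  } else {
    adj <- x
    if (is.null(clusters)) stop("`clusters` is required for a raw adjacency")
  }
  adj <- methods::as(methods::as(adj, "CsparseMatrix"), "generalMatrix")
  n <- nrow(adj)
  if (length(clusters) != n) stop("`clusters` must label every vertex")
  adj@x[] <- 1 # binarize

  lev <- sort(unique(clusters))
  k <- length(lev)
  memb <- match(clusters, lev)
  ns <- as.integer(table(factor(memb, levels = seq_len(k))))
  if (any(ns == 0L)) stop("empty clusters are not allowed")

  ind <- Matrix::sparseMatrix(i = seq_len(n), j = memb, x = 1,
                              dims = c(n, k))
  e <- as.matrix(Matrix::t(ind) %*% adj %*% ind) # directed cluster-pair counts
  inner <- diag(e)
  inter <- e
  diag(inter) <- 0
  es <- inner + rowSums(inter) # epsilon_a
  esym <- inter + t(inter)

  conn <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b || esym[a, b] == 0) next
      expected <- (es[a] * ns[b] + es[b] * ns[a]) / (n - 1)
      conn[a, b] <- if (expected == 0) 1 else min(1, esym[a, b] / expected)
    }
  }
  dimnames(conn) <- dimnames(esym) <- list(as.character(lev), as.character(lev))

  structure(
    list(connectivity = conn, sizes = stats::setNames(ns, as.character(lev)),
         inter_edges = esym, n_cells = n),
    class = "abstraction_graph"
  )
}

#' @export
print.abstraction_graph <- function(x, ...) {
  k <- nrow(x$connectivity)
  cat(sprintf("<abstraction_graph: %d clusters over %d cells>\n", k, x$n_cells))
  nz <- sum(x$connectivity[upper.tri(x$connectivity)] > 0)
  cat(sprintf("  connected pairs: %d of %d\n", nz, k * (k - 1) / 2))
  invisible(x)
}
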