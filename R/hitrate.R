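# High/low-information partition and random-walk hit rates on the weighted
# neighbor graph.

#' Partition cells into high/low-information sets by depth
#'
#' High-information cells are those with total UMI count strictly above
#' `depth_threshold`; all others are low-information. The threshold is
#' dataset-relative (e.g. chosen to retain roughly the deepest 40% of cells).
#'
#' @param pop a `cell_population`, a [run_standard_workflow()] result, or a
#'   numeric vector of per-cell depths.
#' @param depth_threshold non-negative depth threshold (strict `>`).
#' @return An object of class `information_labels`: list with logical `high`,
#'   `depths`, `depth_threshold`, and the two class counts.
#' @export
label_by_depth <- function(pop, depth_threshold) {
  if (depth_threshold < 0) stop("`depth_threshold` must be non-negative")
  depths <- if (inherits(pop, "cell_population")) {
    pop$depths
  } else if (inherits(pop, "manifold_workflow")) {
    pop$depths
  } else {
    as.numeric(pop)
  }
  high <- depths > depth_threshold
  if (all(high) || !any(high)) {
    warning("all cells fall on one side of the depth threshold; ",
            "downstream diagnostics may be vacuous")
  }
  structure(
    list(high = high, depths = depths,
         depth_threshold = depth_threshold,
         n_high = sum(high), n_low = sum(!high)),
    class = "information_labels"
  )
}

#' @export
print.information_labels <- function(x, ...) {
  cat(sprintf("<information_labels: %d high / %d low (depth > %g)>\n",
              x$n_high, x$n_low, x$depth_threshold))
  invisible(x)
}

# resolve (graph, high flag) from the flexible argument forms
resolve_walk_inputs <- function(graph, labels) {
  w <- if (inherits(graph, "manifold_workflow")) graph$graph else graph
  if (igraph::is_igraph(w)) {
    w <- igraph::as_adjacency_matrix(w, attr = if ("weight" %in%
      igraph::edge_attr_names(w)) "weight" else NULL, sparse = TRUE)
  }
  w <- methods::as(methods::as(w, "CsparseMatrix"), "generalMatrix")
  if (any(w@x < 0)) stop("graph weights must be positive")
  high <- if (inherits(labels, "information_labels")) labels$high else as.logical(labels)
  if (length(high) != nrow(w)) stop("labels must cover every vertex")
  list(w = w, high = high)
}

#' Monte-Carlo random-walk hit rate
#'
#' For each low-information cell, simulates `trials` random walks of at most
#' `k_walk` steps on the weighted neighbor graph (transition probability
#' proportional to incident edge weight, no self-transitions) and records the
#' fraction of walks that reach any high-information cell at least once. Walks
#' absorb at the first hit; the starting vertex never counts as a hit. Isolated
#' low cells receive rate 0 with a warning.
#'
#' @param graph a [run_standard_workflow()] result, a symmetric weighted
#'   adjacency matrix, or a weighted `igraph` graph.
#' @param labels an [label_by_depth()] object or logical high-information flag.
#' @param k_walk walk length in steps (default 5).
#' @param trials walks per low cell (default 1,000).
#' @param seed integer seed (one stream drives all cells' walks).
#' @return An object of class `hit_rate_table`: data frame with columns `cell`
#'   (vertex index), `depth` (if known), `hit_rate`; attributes `k_walk`,
#'   `trials`, `seed`, `depth_threshold`.
#' @export
compute_hit_rate <- function(graph, labels, k_walk = 5L, trials = 1000L,
                             seed = NULL) {
  stopifnot(k_walk >= 1, trials >= 1)
  inp <- resolve_walk_inputs(graph, labels)
  w <- inp$w; high <- inp$high
  n <- nrow(w)
  low <- which(!high)

  # adjacency lists (symmetric matrix: column j = neighbors of j)
  ptr <- w@p
  nbrs <- lapply(seq_len(n), function(j) w@i[(ptr[j] + 1L):ptr[j + 1L]] + 1L)
  nbrs[ptr[-1L] == ptr[-(n + 1L)]] <- list(integer(0))
  wts <- lapply(seq_len(n), function(j) {
    if (ptr[j + 1L] > ptr[j]) w@x[(ptr[j] + 1L):ptr[j + 1L]] else numeric(0)
  })

  isolated <- low[lengths(nbrs[low]) == 0L]
  if (length(isolated)) {
    warning(length(isolated), " isolated low-information cell(s); hit rate 0")
  }

  rates <- with_seed(seed, vapply(low, function(v) {
    if (length(nbrs[[v]]) == 0L) return(0)
    cur <- rep.int(v, trials)
    done <- logical(trials)
    hit <- logical(trials)
    for (s in seq_len(k_walk)) {
      act <- which(!done)
      if (length(act) == 0L) break
      cs <- cur[act]
      for (u in unique(cs)) {
        wk <- act[cs == u]
        nb <- nbrs[[u]]
        if (length(nb) == 0L) { # stuck off the start vertex
          done[wk] <- TRUE
          next
        }
        nxt <- if (length(nb) == 1L) {
          rep.int(nb, length(wk))
        } else {
          nb[sample.int(length(nb), length(wk), replace = TRUE, prob = wts[[u]])]
        }
        cur[wk] <- nxt
        landed_high <- high[nxt]
        hit[wk[landed_high]] <- TRUE
        done[wk[landed_high]] <- TRUE
      }
    }
    mean(hit)
  }, numeric(1)))

  depths <- if (inherits(labels, "information_labels")) labels$depths[low] else NA_real_
  out <- data.frame(cell = low, depth = depths, hit_rate = rates)
  attr(out, "k_walk") <- as.integer(k_walk)
  attr(out, "trials") <- as.integer(trials)
  attr(out, "seed") <- seed
  attr(out, "depth_threshold") <- if (inherits(labels, "information_labels")) {
    labels$depth_threshold
  } else {
    NA_real_
  }
  attr(out, "n_vertices") <- n
  class(out) <- c("hit_rate_table", "data.frame")
  out
}

#' Exact random-walk hit probability
#'
#' Closed-form absorption probability of reaching any high-information vertex
#' within `k_walk` steps, obtained by powering the substochastic transition
#' matrix restricted to low-information vertices:
#' \eqn{p = \sum_{t=0}^{k-1} Q^t r}, where `Q` is the low-to-low transition
#' block and `r` the per-step probability of stepping into the high set. Serves
#' as the analytic oracle for [compute_hit_rate()].
#'
#' @inheritParams compute_hit_rate
#' @return Numeric vector of probabilities, one per low-information vertex (in
#'   vertex order), with the vertex indices as names.
#' @export
exact_hit_probability <- function(graph, labels, k_walk = 5L) {
  stopifnot(k_walk >= 0)
  inp <- resolve_walk_inputs(graph, labels)
  w <- inp$w; high <- inp$high
  deg <- Matrix::rowSums(w)
  low <- which(!high)
  if (k_walk == 0L || length(low) == 0L) {
    return(stats::setNames(numeric(length(low)), low))
  }
  inv <- ifelse(deg > 0, 1 / deg, 0)
  p <- Matrix::Diagonal(x = inv) %*% w
  q <- p[low, low, drop = FALSE]
  r <- Matrix::rowSums(p[low, high, drop = FALSE])
  acc <- r
  v <- r
  for (t in seq_len(k_walk - 1L)) {
    v <- as.numeric(q %*% v)
    acc <- acc + v
  }
  # guard roundoff spill just beyond [0, 1]
  stats::setNames(pmin(pmax(as.numeric(acc), 0), 1), low)
}

#' Rank correlation between hit rate and observation depth
#'
#' Spearman correlation (average-rank tie handling, two-sided p-value from the
#' t approximation) between per-cell hit rates and total UMI counts of the
#' low-information cells.
#'
#' @param hit_table a [compute_hit_rate()] result.
#' @param depths per-cell depths matched to the table rows (default: the
#'   table's own `depth` column).
#' @return List with `rho`, `p_value`, `n`. Constant input yields `NA` values
#'   with a warning.
#' @export
spearman_hitrate_vs_depth <- function(hit_table, depths = NULL) {
  depths <- depths %||% hit_table$depth
  rates <- hit_table$hit_rate
  if (length(rates) < 3L) stop("at least 3 low-information cells are required")
  if (length(depths) != length(rates)) stop("`depths` must match the table")
  if (stats::sd(rates) == 0 || stats::sd(depths) == 0) {
    warning("constant input; Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(rates)))
  }
  ct <- suppressWarnings(stats::cor.test(depths, rates, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(rates))
}
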