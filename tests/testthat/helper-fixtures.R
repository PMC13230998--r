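# Shared fixtures and tiny constructors for the test suite. Everything is
# generated in code; heavier simulated objects are memoised per session.

# Hand-built fraction model from explicit raw weights.
tiny_model <- function(f, fei = 1L) {
  manifoldtopo:::new_fraction_model(
    f = as.numeric(f), kind = "edited", n_genes = length(f),
    first_expressed_index = as.integer(fei),
    params = manifoldtopo:::default_fraction_params(),
    integer_weights = all(f == round(f)),
    edits = list(),
    base = list(kind = "combined", first_expressed_index = as.integer(fei))
  )
}

# Population with prescribed per-cell depths, one expressed gene per cell
# unless a counts matrix is given directly.
tiny_pop <- function(depths, labels = rep("S", length(depths))) {
  counts <- Matrix::sparseMatrix(
    i = rep(1L, length(depths)), j = seq_along(depths), x = as.numeric(depths),
    dims = c(2L, length(depths))
  )
  rownames(counts) <- c("G1", "G2")
  colnames(counts) <- sprintf("c%03d", seq_along(depths))
  manifoldtopo:::new_cell_population(counts, labels)
}

pop_from_counts <- function(counts, labels = rep("S", ncol(counts))) {
  manifoldtopo:::new_cell_population(counts, labels)
}

# Memoised medium-size simulated mixture + workflow shared across test files.
.fixtures <- new.env(parent = emptyenv())

fixture_mixture <- function() {
  if (is.null(.fixtures$pop)) {
    .fixtures$pop <- simulate_population_X(
      seed = 7, n_cells = c(Cell1 = 250L, Cell2 = 120L, Cell3 = 120L)
    )
    .fixtures$wf <- run_standard_workflow(.fixtures$pop, workflow_config(seed = 7))
  }
  list(pop = .fixtures$pop, wf = .fixtures$wf)
}

# Cells sampled from one model at one exact depth.
simulate_cells_fixed_depth <- function(model, n, depth, seed) {
  manifoldtopo:::simulate_cells(
    list(list(model = model, n = n, label = "S")),
    seed = seed, depth_mean = depth, depth_sd = 0, depth_floor = 1
  )
}

# Symmetric weighted adjacency from an edge list (1-based, undirected).
adj_from_edges <- function(n, from, to, w = 1) {
  m <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = rep(w, 2L),
                            dims = c(n, n))
  methods::as(m, "generalMatrix")
}

# Independent flood-fill component count (no igraph).
flood_fill_components <- function(n, from, to) {
  comp <- integer(n)
  nbr <- vector("list", n)
  for (e in seq_along(from)) {
    nbr[[from[e]]] <- c(nbr[[from[e]]], to[e])
    nbr[[to[e]]] <- c(nbr[[to[e]]], from[e])
  }
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cid
      stack <- c(stack, nbr[[v]][comp[nbr[[v]]] == 0L])
    }
  }
  cid
}

# Independent cycle-space rank via union-find spanning forest: edges whose
# endpoints are already connected add one independent cycle each.
spanning_forest_cycle_rank <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  extra <- 0L
  for (e in seq_along(from)) {
    ra <- find(from[e]); rb <- find(to[e])
    if (ra == rb) extra <- extra + 1L else parent[ra] <- rb
  }
  extra
}
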