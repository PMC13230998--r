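# The standard graph-based single-cell workflow: QC, log1p normalization,
# HVG selection, scaling, PCA, weighted kNN graph, Louvain clustering,
# optional UMAP embedding; plus PC transfer onto a reference fit.

#' Configuration of the standard workflow
#'
#' Defaults follow common practice for droplet scRNA-seq: per-cell
#' normalization to 10,000 counts then log1p; 2,000 dispersion-selected highly
#' variable genes; per-gene standardization clipped at 10; 30 principal
#' components; a weighted kNN graph connecting each cell to its nearest 1% of
#' cells (floor 5 neighbors, which only binds on tiny inputs); Louvain
#' clustering at resolution 1.
#'
#' @param target_sum per-cell normalization total (default 10,000).
#' @param n_hvg number of highly variable genes (default 2,000).
#' @param scale_clip absolute cap applied after per-gene standardization
#'   (default 10; `Inf` disables clipping).
#' @param n_pcs number of principal components (default 30).
#' @param neighbor_fraction fraction of all cells used as neighbors; the
#'   neighbor count is `max(min_neighbors, round(neighbor_fraction * n_cells))`.
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed integer seed controlling PCA initialization, Louvain and the
#'   optional embedding.
#' @param compute_embedding also compute a 2-D UMAP embedding
#'   (visualization-only; never used by topology computations).
#' @param min_neighbors floor on the neighbor count (default 5).
#' @return An object of class `workflow_config`.
#' @export
workflow_config <- function(target_sum = 1e4, n_hvg = 2000L, scale_clip = 10,
                            n_pcs = 30L, neighbor_fraction = 0.01,
                            resolution = 1, seed = 0L,
                            compute_embedding = FALSE, min_neighbors = 5L) {
  stopifnot(target_sum > 0, n_hvg >= 1, n_pcs >= 1,
            neighbor_fraction > 0, neighbor_fraction <= 1,
            resolution > 0, min_neighbors >= 1)
  if (!is.null(scale_clip) && scale_clip <= 0) stop("`scale_clip` must be positive")
  structure(
    list(target_sum = target_sum, n_hvg = as.integer(n_hvg),
         scale_clip = scale_clip %||% Inf, n_pcs = as.integer(n_pcs),
         neighbor_fraction = neighbor_fraction, resolution = resolution,
         seed = as.integer(seed), compute_embedding = compute_embedding,
         min_neighbors = as.integer(min_neighbors)),
    class = "workflow_config"
  )
}

#' @export
print.workflow_config <- function(x, ...) {
  cat("<workflow_config>\n")
  cat(sprintf("  target_sum=%g n_hvg=%d scale_clip=%g n_pcs=%d\n",
              x$target_sum, x$n_hvg, x$scale_clip, x$n_pcs))
  cat(sprintf("  neighbor_fraction=%g (floor %d) resolution=%g seed=%d\n",
              x$neighbor_fraction, x$min_neighbors, x$resolution, x$seed))
  invisible(x)
}

#' Remove cells with high mitochondrial content
#'
#' Keeps cells whose mitochondrial UMI percentage is strictly below `max_pct`
#' (default 15), where mitochondrial genes are identified by a name prefix.
#'
#' @param counts genes x cells count matrix (or `cell_population`).
#' @param gene_names gene symbols (default: row names of `counts`).
#' @param max_pct maximum mitochondrial percentage (strict `<`).
#' @param prefix gene-name prefix marking mitochondrial genes (default
#'   `"MT-"`).
#' @return The column-filtered counts (same class as the input); the kept cell
#'   indices are attached as attribute `"kept"`.
#' @export
qc_filter_mito <- function(counts, gene_names = NULL, max_pct = 15,
                           prefix = "MT-") {
  pop <- NULL
  if (inherits(counts, "cell_population")) {
    pop <- counts
    counts <- pop$counts
  }
  gene_names <- gene_names %||% rownames(counts)
  if (is.null(gene_names) || length(gene_names) != nrow(counts)) {
    stop("`gene_names` must match the rows of `counts`")
  }
  mito <- startsWith(gene_names, prefix)
  if (!any(mito)) {
    warning("no gene name matches prefix '", prefix, "'; keeping all cells")
    keep <- seq_len(ncol(counts))
  } else {
    tot <- Matrix::colSums(counts)
    mt <- Matrix::colSums(counts[mito, , drop = FALSE])
    pct <- ifelse(tot > 0, 100 * mt / tot, 0)
    keep <- unname(which(pct < max_pct))
  }
  if (!is.null(pop)) {
    return(subset_population(pop, keep,
                             op = list(type = "qc_filter_mito", max_pct = max_pct)))
  }
  out <- counts[, keep, drop = FALSE]
  attr(out, "kept") <- keep
  out
}

# log1p of per-cell counts rescaled to a fixed total; sparsity preserved.
normalize_log1p <- function(counts, target_sum) {
  depths <- Matrix::colSums(counts)
  if (any(depths == 0)) stop("cells with zero total counts cannot be normalized")
  x <- counts %*% Matrix::Diagonal(x = target_sum / depths)
  x <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
  x@x <- log1p(x@x)
  dimnames(x) <- dimnames(counts)
  x
}

# row (gene) means and variances of a sparse matrix, denominator n - 1
row_stats <- function(x) {
  n <- ncol(x)
  mu <- Matrix::rowMeans(x)
  x2 <- x
  x2@x <- x2@x^2
  ssq <- Matrix::rowSums(x2)
  v <- (ssq - n * mu^2) / max(1, n - 1)
  v[v < 0] <- 0 # numeric guard
  list(mean = mu, var = v)
}

# Dispersion-based HVG selection (the field's classic recipe): dispersion =
# var/mean of the de-logged normalized counts, log-dispersion z-scored within
# 20 equal-width bins of log1p(mean); top n genes by normalized dispersion.
select_hvg <- function(xnorm, n_hvg, n_bins = 20L) {
  y <- xnorm
  y@x <- expm1(y@x)
  st <- row_stats(y)
  expressed <- which(st$mean > 0 & st$var > 0)
  if (length(expressed) == 0L) stop("no expressed gene with positive variance")
  disp <- log(st$var[expressed] / st$mean[expressed])
  mu <- log1p(st$mean[expressed])
  br <- seq(min(mu), max(mu), length.out = n_bins + 1L)
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  bm <- tapply(disp, bin, mean)[bin]
  bs <- tapply(disp, bin, stats::sd)[bin]
  # singleton/degenerate bins: use the raw dispersion relative to the bin mean
  z <- ifelse(is.na(bs) | bs == 0, disp / ifelse(bm == 0, 1, bm), (disp - bm) / bs)
  n_take <- min(n_hvg, length(expressed))
  sel <- expressed[order(-z, expressed)[seq_len(n_take)]]
  sort(sel)
}

# exact kNN in PC space; returns neighbor index and distance matrices (n x k),
# self excluded.
knn_in_pc_space <- function(scores, k) {
  n <- nrow(scores)
  if (k >= n) stop("neighbor count must be below the number of cells")
  res <- RANN::nn2(scores, k = k + 1L)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    nb <- res$nn.idx[i, ]
    dd <- res$nn.dists[i, ]
    drop <- match(i, nb)
    if (is.na(drop)) drop <- k + 1L # degenerate ties: self not returned
    idx[i, ] <- nb[-drop][seq_len(k)]
    dst[i, ] <- dd[-drop][seq_len(k)]
  }
  list(idx = idx, dist = dst)
}

#' Run the standard single-cell workflow
#'
#' Executes, in order: per-cell normalization to `target_sum` and log1p;
#' dispersion-based selection of `n_hvg` highly variable genes; per-gene
#' standardization (mean 0, variance 1) clipped at `scale_clip`; PCA to
#' `n_pcs`; construction of a weighted kNN graph in PC space (neighbor count
#' `max(min_neighbors, round(neighbor_fraction * n_cells))`, fuzzy-simplicial
#' connectivity weights with locally adaptive bandwidth, symmetrized by fuzzy
#' union); Louvain clustering at
#' the configured resolution; optionally a 2-D UMAP embedding. All stochastic
#' steps are governed by `config$seed`.
#'
#' @param x a `cell_population` or a genes x cells count matrix.
#' @param config a [workflow_config()].
#' @return An object of class `manifold_workflow` with elements `pc_scores`
#'   (cells x PCs), `loadings` (HVG x PCs), `hvg` (gene indices), `gene_means`,
#'   `gene_sds`, `knn_idx`, `knn_adj` (directed binary kNN adjacency, the input
#'   to [compute_paga()]), `graph` (symmetric weighted adjacency used for
#'   Louvain and random walks), `clusters` (0-based integer labels, decreasing
#'   size), `embedding` (or `NULL`), `depths`, `barcodes`, `k_nn`, `config`.
#' @export
run_standard_workflow <- function(x, config = workflow_config()) {
  stopifnot(inherits(config, "workflow_config"))
  counts <- if (inherits(x, "cell_population")) x$counts else x
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  n <- ncol(counts)
  k_nn <- max(config$min_neighbors,
              as.integer(round(config$neighbor_fraction * n)))
  if (n < 2L * k_nn) {
    stop(sprintf("too few cells (%d) for %d neighbors", n, k_nn))
  }

  xnorm <- normalize_log1p(counts, config$target_sum)
  hvg <- select_hvg(xnorm, config$n_hvg)

  xs <- as.matrix(xnorm[hvg, , drop = FALSE])
  st <- row_stats(xnorm[hvg, , drop = FALSE])
  sds <- sqrt(st$var)
  xs <- (xs - st$mean) / sds
  clip <- config$scale_clip
  xs[xs > clip] <- clip
  xs[xs < -clip] <- -clip

  n_pcs <- min(config$n_pcs, length(hvg), n - 1L)
  a <- t(xs) # cells x genes
  dec <- with_seed(config$seed, {
    if (n_pcs >= 0.5 * min(dim(a)) || min(dim(a)) < 10L) {
      sv <- svd(a, nu = n_pcs, nv = n_pcs)
      list(u = sv$u, d = sv$d[seq_len(n_pcs)], v = sv$v)
    } else {
      sv <- irlba::irlba(a, nv = n_pcs)
      list(u = sv$u, d = sv$d, v = sv$v)
    }
  })
  # canonical sign: largest-magnitude loading positive
  flip <- vapply(seq_len(n_pcs), function(j) {
    v <- dec$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  loadings <- sweep(dec$v, 2L, flip, "*")
  scores <- sweep(dec$u, 2L, dec$d * flip, "*")
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_pcs))

  nnr <- knn_in_pc_space(scores, k_nn)
  knn_adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k_nn),
    j = as.integer(t(nnr$idx)),
    x = 1, dims = c(n, n)
  )
  # fuzzy-simplicial-set connectivities (the standard weighting of the field's
  # reference workflow) on the exact kNN, self included as first neighbor
  graph <- uwot::similarity_graph(
    nn_method = list(idx = cbind(seq_len(n), nnr$idx),
                     dist = cbind(0, nnr$dist))
  )
  graph <- methods::as(methods::as(graph, "CsparseMatrix"), "generalMatrix")
  Matrix::diag(graph) <- 0
  graph <- Matrix::drop0(graph)

  g <- igraph::graph_from_adjacency_matrix(graph, mode = "undirected",
                                           weighted = TRUE)
  memb <- with_seed(derive_seed(config$seed, 101L),
                    igraph::membership(
                      igraph::cluster_louvain(g, resolution = config$resolution)))
  clusters <- relabel_by_size(as.integer(memb))

  embedding <- NULL
  if (isTRUE(config$compute_embedding)) {
    embedding <- with_seed(derive_seed(config$seed, 202L),
                           uwot::umap(scores,
                                      n_neighbors = min(k_nn + 1L, n - 1L)))
    colnames(embedding) <- c("UMAP1", "UMAP2")
  }

  structure(
    list(
      pc_scores = scores,
      loadings = loadings,
      hvg = hvg,
      hvg_names = rownames(counts)[hvg],
      gene_means = st$mean,
      gene_sds = sds,
      knn_idx = nnr$idx,
      knn_adj = knn_adj,
      graph = graph,
      clusters = clusters,
      embedding = embedding,
      depths = as.integer(Matrix::colSums(counts)),
      barcodes = colnames(counts),
      k_nn = k_nn,
      n_cells = n,
      config = config
    ),
    class = "manifold_workflow"
  )
}

# 0-based cluster labels ordered by decreasing size (ties: smallest member
# index first), matching the field's convention for cluster naming.
relabel_by_size <- function(memb) {
  sizes <- table(memb)
  first <- tapply(seq_along(memb), memb, min)
  ord <- order(-as.integer(sizes), as.integer(first))
  old <- as.integer(names(sizes))[ord]
  match(memb, old) - 1L
}

#' @export
print.manifold_workflow <- function(x, ...) {
  cat(sprintf("<manifold_workflow: %d cells, %d PCs, k_nn = %d>\n",
              x$n_cells, ncol(x$pc_scores), x$k_nn))
  tb <- table(x$clusters)
  cat(sprintf("  clusters (%d): %s\n", length(tb),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Project cells onto a reference PCA fit
#'
#' Normalizes new cells with the reference configuration, standardizes each
#' reference HVG with the reference per-gene statistics (clipped identically),
#' and projects onto the reference loadings. No statistic is refit, so the
#' reference population projects exactly onto its own scores. Genes absent from
#' the new matrix are imputed at the reference mean (zero after centering) with
#' a warning.
#'
#' @param counts genes x cells count matrix (or `cell_population`) to project.
#' @param reference a [run_standard_workflow()] result.
#' @return cells x PCs score matrix in the reference coordinate system.
#' @export
project_onto_loadings <- function(counts, reference) {
  stopifnot(inherits(reference, "manifold_workflow"))
  if (inherits(counts, "cell_population")) counts <- counts$counts
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")

  use_names <- !is.null(rownames(counts)) && !is.null(reference$hvg_names)
  if (use_names) {
    ridx <- match(reference$hvg_names, rownames(counts))
  } else {
    if (nrow(counts) < max(reference$hvg)) {
      stop("count matrix lacks the reference genes and carries no row names")
    }
    ridx <- reference$hvg
  }
  missing <- is.na(ridx)
  if (any(missing)) {
    warning(sum(missing), " reference HVG(s) absent from the input; ",
            "imputed at the reference mean (zero after centering)")
  }

  xnorm <- normalize_log1p(counts, reference$config$target_sum)
  nh <- length(reference$hvg)
  xs <- matrix(rep(reference$gene_means, ncol(counts)), nrow = nh)
  xs[!missing, ] <- as.matrix(xnorm[ridx[!missing], , drop = FALSE])
  xs <- (xs - reference$gene_means) / reference$gene_sds
  clip <- reference$config$scale_clip
  xs[xs > clip] <- clip
  xs[xs < -clip] <- -clip
  scores <- t(xs) %*% reference$loadings
  rownames(scores) <- colnames(counts)
  scores
}
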