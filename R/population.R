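# Benchmark cell populations with ground-truth state labels and heterogeneous
# per-cell observation depth.

new_cell_population <- function(counts, labels, provenance = list()) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  depths <- Matrix::colSums(counts)
  pop <- structure(
    list(
      counts = counts,
      labels = as.character(labels),
      depths = as.integer(depths),
      provenance = provenance
    ),
    class = "cell_population"
  )
  validate_cell_population(pop)
  pop
}

validate_cell_population <- function(pop) {
  stopifnot(inherits(pop, "cell_population"))
  n <- ncol(pop$counts)
  if (length(pop$labels) != n) stop("labels do not match the number of cells")
  if (length(pop$depths) != n) stop("depths do not match the number of cells")
  if (any(pop$counts@x < 0)) stop("counts must be non-negative")
  if (any(pop$counts@x != round(pop$counts@x))) stop("counts must be integers")
  if (n > 0 && !isTRUE(all.equal(as.numeric(Matrix::colSums(pop$counts)),
                                 as.numeric(pop$depths)))) {
    stop("column sums of counts must equal the stored depths")
  }
  invisible(pop)
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("<cell_population%s: %d genes x %d cells>\n",
              if (!is.null(x$provenance$name)) paste0(" ", x$provenance$name) else "",
              nrow(x$counts), ncol(x$counts)))
  if (length(x$labels)) {
    tb <- table(x$labels)
    cat("  states:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
    cat(sprintf("  depth: median %d, range [%d, %d]\n",
                as.integer(stats::median(x$depths)), min(x$depths), max(x$depths)))
  }
  invisible(x)
}

# Sample one population from a list of groups, each group being
# list(model = <fraction_model>, n = <cells>, label = <state name>).
# All randomness is consumed sequentially under one local seed.
simulate_cells <- function(groups, seed = NULL, depth_mean = 5000,
                           depth_sd = 1500, depth_floor = 500,
                           name = "custom") {
  stopifnot(length(groups) >= 1L)
  n_genes <- groups[[1L]]$model$n_genes
  with_seed(seed, {
    i_list <- list(); j_list <- list(); x_list <- list()
    labels <- character(0)
    col <- 0L
    for (g in groups) {
      validate_fraction_model(g$model)
      if (g$model$n_genes != n_genes) stop("all group models must share n_genes")
      idx <- which(g$model$p > 0)
      pr <- g$model$p[idx]
      depths <- draw_depth(g$n, mean = depth_mean, sd = depth_sd,
                           floor = depth_floor)
      for (cix in seq_len(g$n)) {
        col <- col + 1L
        draw <- stats::rmultinom(1L, size = depths[cix], prob = pr)[, 1L]
        nz <- which(draw > 0L)
        i_list[[col]] <- idx[nz]
        j_list[[col]] <- rep.int(col, length(nz))
        x_list[[col]] <- draw[nz]
      }
      labels <- c(labels, rep.int(g$label, g$n))
    }
    counts <- Matrix::sparseMatrix(
      i = unlist(i_list), j = unlist(j_list), x = unlist(x_list),
      dims = c(n_genes, col)
    )
    rownames(counts) <- sprintf("G%05d", seq_len(n_genes))
    colnames(counts) <- sprintf("%s_%04d", labels, seq_len(col))
    new_cell_population(
      counts, labels,
      provenance = list(
        name = name, seed = seed,
        depth = list(mean = depth_mean, sd = depth_sd, floor = depth_floor),
        models = stats::setNames(lapply(groups, `[[`, "model"),
                                 vapply(groups, `[[`, "", "label")),
        groups = lapply(groups, function(g) list(label = g$label, n = g$n))
      )
    )
  })
}

#' Simulate benchmark population X (distinct cell types)
#'
#' Three completely distinct cell types sharing one expression-magnitude
#' spectrum: `Cell1` follows the combined reference model, `Cell2` and `Cell3`
#' follow two independent random permutations of its gene identities. Default
#' sizes are 2,000 / 1,000 / 1,000 cells; per-cell depths are drawn from
#' round(Normal(5,000, 1,500)) clamped at 500.
#'
#' @param seed master integer seed; all model edits and cell draws derive from it.
#' @param n_cells named integer vector of cells per state
#'   (`c(Cell1 = , Cell2 = , Cell3 = )`); scale down for quick runs.
#' @param base_model reference `fraction_model` (default the combined model on
#'   the full 36,601-gene panel).
#' @param depth_mean,depth_sd,depth_floor per-cell depth law.
#' @return A `cell_population` (genes x cells sparse integer counts, labels,
#'   depths, provenance including the per-state models).
#' @export
simulate_population_X <- function(seed = NULL,
                                  n_cells = c(Cell1 = 2000L, Cell2 = 1000L,
                                              Cell3 = 1000L),
                                  base_model = NULL,
                                  depth_mean = 5000, depth_sd = 1500,
                                  depth_floor = 500) {
  m1 <- base_model %||% build_fraction_model("combined")
  m2 <- permute_gene_identities(m1, seed = derive_seed(seed, 1L))
  m3 <- permute_gene_identities(m1, seed = derive_seed(seed, 2L))
  simulate_cells(
    list(list(model = m1, n = n_cells[["Cell1"]], label = "Cell1"),
         list(model = m2, n = n_cells[["Cell2"]], label = "Cell2"),
         list(model = m3, n = n_cells[["Cell3"]], label = "Cell3")),
    seed = derive_seed(seed, 3L),
    depth_mean = depth_mean, depth_sd = depth_sd, depth_floor = depth_floor,
    name = "X"
  )
}

#' Simulate benchmark population Y (pathway activation)
#'
#' Two states: `Cell1` (reference combined model) and `Cell4`, obtained from
#' `Cell1` by scaling the pool counts of 300 genes randomly selected from the
#' expressed range (ranks 26,602-36,601) by 2 or 0.5 (direction Bernoulli(0.5)
#' per gene). Default sizes 2,000 / 2,000.
#'
#' @inheritParams simulate_population_X
#' @param n_cells named integer vector (`c(Cell1 = , Cell4 = )`).
#' @param n_scaled,select_range see [scale_gene_subset()].
#' @return A `cell_population`.
#' @export
simulate_population_Y <- function(seed = NULL,
                                  n_cells = c(Cell1 = 2000L, Cell4 = 2000L),
                                  base_model = NULL,
                                  n_scaled = 300L,
                                  select_range = c(26602L, 36601L),
                                  depth_mean = 5000, depth_sd = 1500,
                                  depth_floor = 500) {
  m1 <- base_model %||% build_fraction_model("combined")
  m4 <- scale_gene_subset(m1, seed = derive_seed(seed, 1L),
                          up_factor = 2, down_factor = 0.5,
                          n_select = n_scaled, select_range = select_range)
  simulate_cells(
    list(list(model = m1, n = n_cells[["Cell1"]], label = "Cell1"),
         list(model = m4, n = n_cells[["Cell4"]], label = "Cell4")),
    seed = derive_seed(seed, 2L),
    depth_mean = depth_mean, depth_sd = depth_sd, depth_floor = depth_floor,
    name = "Y"
  )
}

#' Simulate benchmark population Z (step-wise lineage)
#'
#' Five states along the lineage A -> B (pathway activation) -> C (further
#' activation of the same pathway) -> D or E (epigenetic derepression), 1,000
#' cells per state by default:
#' \itemize{
#'   \item A: the combined reference model;
#'   \item B: 300 expressed-range genes scaled by 1.67 or 0.6;
#'   \item C: the same 300 genes, same per-gene directions, scaled again;
#'   \item D, E: from C, 10 genes drawn independently (different seeds) from
#'     ranks 1-26,601 have their pool count set to 50.
#' }
#'
#' @inheritParams simulate_population_X
#' @param cells_per_state cells per state (single integer, default 1,000).
#' @param n_scaled,select_range pathway-activation edit (see
#'   [scale_gene_subset()]).
#' @param n_derepressed,derepress_target,candidate_upper derepression edit (see
#'   [derepress_genes()]).
#' @return A `cell_population` with labels `A`..`E`.
#' @export
simulate_population_Z <- function(seed = NULL, cells_per_state = 1000L,
                                  base_model = NULL,
                                  n_scaled = 300L,
                                  select_range = c(26602L, 36601L),
                                  n_derepressed = 10L,
                                  derepress_target = 50,
                                  candidate_upper = 26601L,
                                  depth_mean = 5000, depth_sd = 1500,
                                  depth_floor = 500) {
  mA <- base_model %||% build_fraction_model("combined")
  mB <- scale_gene_subset(mA, seed = derive_seed(seed, 1L),
                          up_factor = 1.67, down_factor = 0.6,
                          n_select = n_scaled, select_range = select_range)
  eB <- mB$edits[[length(mB$edits)]]
  mC <- scale_gene_subset(mB, gene_ids = eB$gene_ids, directions = eB$directions,
                          up_factor = 1.67, down_factor = 0.6)
  mD <- derepress_genes(mC, n_select = n_derepressed,
                        target_count = derepress_target,
                        candidate_upper = candidate_upper,
                        seed = derive_seed(seed, 2L))
  mE <- derepress_genes(mC, n_select = n_derepressed,
                        target_count = derepress_target,
                        candidate_upper = candidate_upper,
                        seed = derive_seed(seed, 3L))
  groups <- Map(function(m, lab) list(model = m, n = cells_per_state, label = lab),
                list(mA, mB, mC, mD, mE), list("A", "B", "C", "D", "E"))
  simulate_cells(groups, seed = derive_seed(seed, 4L),
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 depth_floor = depth_floor, name = "Z")
}

# Column subset keeping labels/depths/provenance in step.
subset_population <- function(pop, idx, op = NULL) {
  validate_cell_population(pop)
  prov <- pop$provenance
  if (!is.null(op)) prov$ops <- c(prov$ops, list(op))
  new_cell_population(pop$counts[, idx, drop = FALSE], pop$labels[idx],
                      provenance = prov)
}

#' Keep cells above a total-UMI threshold
#'
#' Strictly-greater-than filter on per-cell depth (the high-information subset;
#' e.g. threshold 10,000 for the empirical monocyte subset, 4,000 for the
#' simulated lineage). Labels, ordering and provenance are carried through.
#'
#' @param pop a `cell_population`.
#' @param threshold depth threshold (cells with depth `> threshold` are kept).
#' @return A `cell_population`; empty (with a warning) if no cell qualifies.
#' @export
filter_by_total_umi <- function(pop, threshold) {
  validate_cell_population(pop)
  if (threshold < 0) stop("`threshold` must be non-negative")
  keep <- which(pop$depths > threshold)
  if (length(keep) == 0L) {
    warning("no cell exceeds the depth threshold; returning an empty population")
  }
  subset_population(pop, keep,
                    op = list(type = "filter_by_total_umi", threshold = threshold))
}

#' Keep the n deepest cells
#'
#' Selects the `n` cells with the largest total UMI counts (ties broken by
#' ascending original column index); the output preserves original column order.
#' This is the depth-ranked comparator to hit-rate-based filtering.
#'
#' @param pop a `cell_population`.
#' @param n number of cells to keep (`0 <= n <=` number of cells).
#' @return A `cell_population` with `n` cells.
#' @export
top_n_by_total_umi <- function(pop, n) {
  validate_cell_population(pop)
  n <- as.integer(n)
  if (n < 0L || n > ncol(pop$counts)) {
    stop("`n` must lie in [0, number of cells]")
  }
  sel <- sort(order(-pop$depths, seq_along(pop$depths))[seq_len(n)])
  subset_population(pop, sel, op = list(type = "top_n_by_total_umi", n = n))
}
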