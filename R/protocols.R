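# Stability protocols: progressive removal of unreliable cells, fixed-size
# subsample beta1 distributions, and hyperparameter sensitivity sweeps.

# deterministic ordering of low-information cells: ascending hit rate, then
# ascending depth, then original index
order_low_cells <- function(hit_table) {
  hit_table$cell[order(hit_table$hit_rate, hit_table$depth, hit_table$cell)]
}

#' Progressive removal curve
#'
#' Orders low-information cells by increasing random-walk hit rate (ties broken
#' by ascending depth, then cell index) and, for each requested fraction,
#' removes that share of the low-information cells, re-runs the standard
#' workflow on the remainder (the neighbor count is recomputed from
#' `neighbor_fraction`), computes PAGA, thresholds at `tau`, and records the
#' Betti numbers. Fraction 0 is the full population; fraction 1 is exactly the
#' high-information subset.
#'
#' @param pop a `cell_population`.
#' @param hit_table a [compute_hit_rate()] result covering `pop`'s
#'   low-information cells (vertex indices = column indices of `pop`).
#' @param config a [workflow_config()] reused for every re-run.
#' @param fractions fractions of low-information cells to remove (default
#'   `seq(0, 1, 0.1)`).
#' @param tau PAGA connectivity threshold (default 0.05).
#' @return An object of class `removal_curve`: data frame with columns
#'   `fraction`, `n_cells`, `n_clusters`, `beta0`, `beta1`; the kept cell
#'   indices per fraction are attached as attribute `"kept"`.
#' @export
progressive_removal_curve <- function(pop, hit_table, config = workflow_config(),
                                      fractions = seq(0, 1, by = 0.1),
                                      tau = 0.05) {
  validate_cell_population(pop)
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  n <- ncol(pop$counts)
  low_sorted <- order_low_cells(hit_table)
  n_low <- length(low_sorted)

  rows <- vector("list", length(fractions))
  kept_sets <- vector("list", length(fractions))
  for (fx in seq_along(fractions)) {
    f <- fractions[fx]
    n_rm <- as.integer(round(f * n_low))
    removed <- low_sorted[seq_len(n_rm)]
    keep <- setdiff(seq_len(n), removed)
    kept_sets[[fx]] <- keep
    ts <- tryCatch({
      sub <- subset_population(pop, keep,
                               op = list(type = "removal_curve", fraction = f))
      wf <- run_standard_workflow(sub, config)
      betti_numbers(compute_paga(wf), tau = tau)
    }, error = function(e) {
      warning(sprintf("fraction %.2f left too few cells (%d) for the workflow: %s",
                      f, length(keep), conditionMessage(e)))
      NULL
    })
    rows[[fx]] <- data.frame(
      fraction = f, n_cells = length(keep),
      n_clusters = if (is.null(ts)) NA_integer_ else ts$n_nodes,
      beta0 = if (is.null(ts)) NA_integer_ else ts$beta0,
      beta1 = if (is.null(ts)) NA_integer_ else ts$beta1
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "kept") <- kept_sets
  attr(out, "tau") <- tau
  attr(out, "depth_threshold") <- attr(hit_table, "depth_threshold")
  class(out) <- c("removal_curve", "data.frame")
  out
}

#' Subsampled beta1 distribution
#'
#' Repeatedly draws `n_cells` cells uniformly without replacement, runs the
#' standard workflow plus PAGA on each draw, thresholds at `tau`, and collects
#' the first Betti number. Per-draw seeds are derived deterministically from
#' `seed` and recorded, so the whole experiment replays exactly.
#'
#' @param pop a `cell_population`.
#' @param n_cells cells per draw (default 1,500; must not exceed the population
#'   size).
#' @param repeats number of draws (default 100).
#' @param config a [workflow_config()]; each draw runs with its own derived
#'   seed.
#' @param tau PAGA connectivity threshold (default 0.05).
#' @param seed master integer seed.
#' @return An object of class `subsample_beta1`: data frame with columns
#'   `draw`, `seed`, `beta1`, `n_clusters`; attributes `n_cells`, `tau`,
#'   `population`.
#' @export
subsample_beta1 <- function(pop, n_cells = 1500L, repeats = 100L,
                            config = workflow_config(), tau = 0.05,
                            seed = NULL) {
  validate_cell_population(pop)
  n <- ncol(pop$counts)
  n_cells <- as.integer(n_cells)
  if (n_cells > n) stop("`n_cells` exceeds the population size")
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    s_r <- derive_seed(seed, r) %||% NULL
    idx <- with_seed(s_r, sort(sample.int(n, n_cells)))
    sub <- subset_population(pop, idx,
                             op = list(type = "subsample", draw = r))
    cfg <- config
    cfg$seed <- s_r %||% config$seed
    wf <- run_standard_workflow(sub, cfg)
    ts <- betti_numbers(compute_paga(wf), tau = tau)
    rows[[r]] <- data.frame(draw = r, seed = s_r %||% NA_integer_,
                            beta1 = ts$beta1, n_clusters = ts$n_nodes)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_cells") <- n_cells
  attr(out, "tau") <- tau
  attr(out, "population") <- pop$provenance$name %||% "population"
  class(out) <- c("subsample_beta1", "data.frame")
  out
}

#' @export
print.subsample_beta1 <- function(x, ...) {
  cat(sprintf("<subsample_beta1: %s, %d draws of %d cells>\n",
              attr(x, "population"), nrow(x), attr(x, "n_cells")))
  cat(sprintf("  beta1: median %g, IQR [%g, %g]\n",
              stats::median(x$beta1),
              stats::quantile(x$beta1, 0.25), stats::quantile(x$beta1, 0.75)))
  invisible(x)
}

# Remove a share of the low-information cells ranked by hit rate (the
# "50%-filtered" population of the stability comparison).
filter_by_hit_rate <- function(pop, hit_table, remove_fraction = 0.5) {
  n <- ncol(pop$counts)
  low_sorted <- order_low_cells(hit_table)
  n_rm <- as.integer(round(remove_fraction * length(low_sorted)))
  keep <- setdiff(seq_len(n), low_sorted[seq_len(n_rm)])
  subset_population(pop, keep,
                    op = list(type = "filter_by_hit_rate",
                              remove_fraction = remove_fraction))
}

#' Default sensitivity grid
#'
#' The baseline setting (1% neighbors, 5-step walks, resolution 1) plus
#' one-at-a-time variations over neighbor fraction (1.5%, 2%), walk length
#' (10, 20) and Louvain resolution (1.2, 1.5); `full = TRUE` returns the full
#' factorial instead.
#'
#' @param full return the full 3 x 3 x 3 factorial (default `FALSE`:
#'   baseline + one-at-a-time, 7 rows).
#' @return Data frame with columns `neighbor_fraction`, `k_walk`, `resolution`.
#' @export
sensitivity_grid <- function(full = FALSE) {
  if (full) {
    return(expand.grid(neighbor_fraction = c(0.01, 0.015, 0.02),
                       k_walk = c(5L, 10L, 20L),
                       resolution = c(1, 1.2, 1.5)))
  }
  base <- data.frame(neighbor_fraction = 0.01, k_walk = 5L, resolution = 1)
  rbind(
    base,
    data.frame(neighbor_fraction = c(0.015, 0.02), k_walk = 5L, resolution = 1),
    data.frame(neighbor_fraction = 0.01, k_walk = c(10L, 20L), resolution = 1),
    data.frame(neighbor_fraction = 0.01, k_walk = 5L, resolution = c(1.2, 1.5))
  )
}

#' Hyperparameter sensitivity sweep of the beta1 comparison
#'
#' For every grid row, re-runs the full pipeline under that setting: standard
#' workflow on the whole population, hit rates at the row's walk length
#' (recomputed per setting), construction of the population variants — the full
#' population, the 50% hit-rate-filtered population, the depth-thresholded
#' high-information subset, and a depth-ranked comparator of the same size as
#' the 50% variant — then a [subsample_beta1()] distribution per variant.
#'
#' @param pop a `cell_population`.
#' @param depth_threshold depth threshold defining the high-information subset.
#' @param grid data frame with columns `neighbor_fraction`, `k_walk`,
#'   `resolution` (default [sensitivity_grid()]).
#' @param n_cells,repeats subsampling parameters (defaults 1,500 and 100;
#'   draws are truncated to the smallest variant when needed).
#' @param config base [workflow_config()] that each row modifies.
#' @param trials random-walk trials per low cell (default 1,000).
#' @param tau PAGA threshold (default 0.05).
#' @param seed master integer seed.
#' @return An object of class `sweep_result`: long data frame with the grid
#'   columns plus `population` (`"full"`, `"hitrate50"`, `"high_info"`,
#'   `"top_umi"`), `draw`, `beta1`, `n_clusters`.
#' @export
hyperparameter_sweep <- function(pop, depth_threshold, grid = sensitivity_grid(),
                                 n_cells = 1500L, repeats = 100L,
                                 config = workflow_config(), trials = 1000L,
                                 tau = 0.05, seed = NULL) {
  validate_cell_population(pop)
  if (nrow(grid) == 0L) stop("`grid` must be non-empty")
  need <- c("neighbor_fraction", "k_walk", "resolution")
  if (!all(need %in% names(grid))) {
    stop("`grid` needs columns: ", paste(need, collapse = ", "))
  }
  out <- vector("list", nrow(grid))
  for (gx in seq_len(nrow(grid))) {
    cfg <- config
    cfg$neighbor_fraction <- grid$neighbor_fraction[gx]
    cfg$resolution <- grid$resolution[gx]
    cfg$seed <- derive_seed(seed, gx) %||% config$seed
    wf <- run_standard_workflow(pop, cfg)
    labels <- label_by_depth(pop, depth_threshold)
    ht <- compute_hit_rate(wf, labels, k_walk = grid$k_walk[gx],
                           trials = trials,
                           seed = derive_seed(seed, c(gx, 1L)))
    variants <- list(
      full = pop,
      hitrate50 = filter_by_hit_rate(pop, ht, 0.5),
      high_info = filter_by_total_umi(pop, depth_threshold)
    )
    variants$top_umi <- top_n_by_total_umi(pop, ncol(variants$hitrate50$counts))
    res <- lapply(names(variants), function(nm) {
      v <- variants[[nm]]
      nc <- min(n_cells, ncol(v$counts))
      sb <- subsample_beta1(v, n_cells = nc, repeats = repeats, config = cfg,
                            tau = tau, seed = derive_seed(seed, c(gx, match(nm, names(variants)) + 1L)))
      data.frame(grid[gx, need, drop = FALSE], population = nm,
                 draw = sb$draw, beta1 = sb$beta1,
                 n_clusters = sb$n_clusters, row.names = NULL)
    })
    out[[gx]] <- do.call(rbind, res)
  }
  out <- do.call(rbind, out)
  attr(out, "depth_threshold") <- depth_threshold
  attr(out, "tau") <- tau
  class(out) <- c("sweep_result", "data.frame")
  out
}
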