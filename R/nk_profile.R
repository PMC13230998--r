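# Empirical UMI-multiplicity spectra: per-cell N_k and depth-binned means.

#' Per-cell UMI-multiplicity counts N_k
#'
#' For every cell, counts the number of genes observed exactly `k` times,
#' `k = 1..k_max` (`k = 0` is excluded). The partition identity
#' \eqn{\sum_k k N_{ik} = } total UMI of cell `i` holds whenever `k_max` covers
#' the largest observed multiplicity (the default).
#'
#' @param counts genes x cells matrix of non-negative integer UMI counts
#'   (dense, sparse, or a `cell_population`).
#' @param k_max largest multiplicity tabulated; default the observed maximum.
#' @return Integer matrix, cells x k (columns named `k1..k<k_max>`), with cell
#'   barcodes as row names when available.
#' @export
per_cell_nk <- function(counts, k_max = NULL) {
  if (inherits(counts, "cell_population")) counts <- counts$counts
  cm <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (length(cm@x)) {
    if (any(cm@x < 0)) stop("counts must be non-negative")
    if (any(cm@x != round(cm@x))) stop("counts must be integers")
  }
  n_cells <- ncol(cm)
  vals <- as.integer(cm@x)
  cell <- rep.int(seq_len(n_cells), diff(cm@p))
  pos <- vals >= 1L
  vals <- vals[pos]; cell <- cell[pos]
  if (is.null(k_max)) k_max <- if (length(vals)) max(vals) else 1L
  k_max <- as.integer(k_max)
  if (k_max < 1L) stop("`k_max` must be at least 1")
  keep <- vals <= k_max
  tab <- table(factor(cell[keep], levels = seq_len(n_cells)),
               factor(vals[keep], levels = seq_len(k_max)))
  nk <- matrix(as.integer(tab), nrow = n_cells, ncol = k_max)
  dimnames(nk) <- list(colnames(cm), paste0("k", seq_len(k_max)))
  nk
}

#' Depth-binned mean multiplicity profile
#'
#' Stratifies cells into half-open depth bins `[b*w, (b+1)*w)` of width `w`
#' (default 1,000) and averages the per-cell `N_k` within each bin. Empty bins
#' are dropped. Before averaging, the partition identity
#' \eqn{\sum_k k N_{ik} = } `totals[i]` is verified (disable with
#' `check = FALSE` when `nk_matrix` was tabulated with a truncated `k_max`).
#'
#' @param nk_matrix cells x k matrix from [per_cell_nk()].
#' @param totals per-cell total UMI counts (length = rows of `nk_matrix`).
#' @param bin_width depth bin width (default 1,000).
#' @param check verify the partition identity (default `TRUE`).
#' @return An object of class `nk_profile`: list with `mean_nk` (bins x k),
#'   `cells_per_bin`, `bin_lower` (inclusive lower edges), `bin_width`.
#' @export
bin_mean_nk <- function(nk_matrix, totals, bin_width = 1000L, check = TRUE) {
  nk_matrix <- as.matrix(nk_matrix)
  if (is.null(colnames(nk_matrix))) {
    colnames(nk_matrix) <- paste0("k", seq_len(ncol(nk_matrix)))
  }
  if (length(totals) != nrow(nk_matrix)) {
    stop("`totals` must have one entry per row of `nk_matrix`")
  }
  if (bin_width <= 0) stop("`bin_width` must be positive")
  if (check) {
    ks <- seq_len(ncol(nk_matrix))
    recon <- as.numeric(nk_matrix %*% ks)
    if (!isTRUE(all.equal(recon, as.numeric(totals)))) {
      stop("sum_k k*N_k does not reproduce the cell totals; ",
           "was `nk_matrix` truncated? (use check = FALSE)")
    }
  }
  bin <- floor(totals / bin_width)
  ub <- sort(unique(bin))
  fac <- factor(bin, levels = ub)
  mean_nk <- apply(nk_matrix, 2L, function(col) tapply(col, fac, mean))
  if (length(ub) == 1L) mean_nk <- matrix(mean_nk, nrow = 1L,
                                          dimnames = list(NULL, colnames(nk_matrix)))
  rownames(mean_nk) <- sprintf("[%d,%d)", as.integer(ub * bin_width),
                               as.integer((ub + 1) * bin_width))
  structure(
    list(
      mean_nk = mean_nk,
      cells_per_bin = as.integer(table(fac)),
      bin_lower = as.integer(ub * bin_width),
      bin_width = as.integer(bin_width)
    ),
    class = "nk_profile"
  )
}

#' @export
print.nk_profile <- function(x, ...) {
  cat(sprintf("<nk_profile: %d depth bins (width %d), k = 1..%d>\n",
              nrow(x$mean_nk), x$bin_width, ncol(x$mean_nk)))
  cat("  cells per bin:", paste(x$cells_per_bin, collapse = ", "), "\n")
  invisible(x)
}

#' Write a depth-binned multiplicity profile to TSV
#'
#' Rows are depth bins (first two columns: inclusive lower edge and cell
#' count), remaining columns the mean `N_k` values.
#'
#' @param profile an [bin_mean_nk()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nk_profile <- function(profile, path) {
  stopifnot(inherits(profile, "nk_profile"))
  df <- data.frame(
    bin_lower = profile$bin_lower,
    n_cells = profile$cells_per_bin,
    profile$mean_nk,
    check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
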