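# Sampling UMI count vectors and per-cell observation depths.

#' Sample a single-cell UMI count vector
#'
#' Draws the per-gene UMI counts of one cell at total depth `D` under the
#' equal-probability / distinct-UMI capture assumption, i.e. one multinomial
#' draw of `D` molecules with probabilities `model$p`. Column totals are exactly
#' `D`; genes with zero fraction always receive zero counts.
#'
#' @param model a [build_fraction_model()] object.
#' @param depth total UMI count `D` of the cell (positive integer).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return Integer vector of length `model$n_genes` summing to `depth`.
#' @export
sample_cell_counts <- function(model, depth, seed = NULL) {
  validate_fraction_model(model)
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1) {
    stop("`depth` must be a positive integer")
  }
  idx <- which(model$p > 0)
  draw <- with_seed(seed, stats::rmultinom(1L, size = as.integer(depth),
                                           prob = model$p[idx]))
  out <- integer(model$n_genes)
  out[idx] <- draw[, 1L]
  out
}

#' Draw a per-cell observation depth
#'
#' Per-cell total UMI counts are drawn as `round(Normal(mean, sd))` and clamped
#' below at `floor`, emulating the depth heterogeneity of droplet-based
#' scRNA-seq (defaults: mean 5,000, SD 1,500, floor 500).
#'
#' @param n number of depths to draw.
#' @param mean,sd parameters of the normal draw.
#' @param floor minimum depth (clamp, default 500).
#' @param seed optional integer seed.
#' @return Integer vector of length `n`, all entries `>= floor`.
#' @export
draw_depth <- function(n = 1L, mean = 5000, sd = 1500, floor = 500,
                       seed = NULL) {
  if (sd < 0) stop("`sd` must be non-negative")
  if (floor < 1) stop("`floor` must be at least 1")
  d <- with_seed(seed, stats::rnorm(n, mean, sd))
  pmax(as.integer(round(d)), as.integer(floor))
}
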