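# Ranked gene-fraction models of the per-cell cDNA pool.
#
# A "cell state" is modelled as a vector of per-gene fractions p_i of the cDNA
# pool, with genes indexed by ascending fraction. In the default human panel of
# 36,601 genes only the top ~10,000 ranks (i >= 26,601) are expressed. Raw
# molecule weights f_i grow linearly in rank, exponentially near the top rank,
# or both (the combined model used for all benchmark populations); p = f / sum(f).

default_fraction_params <- function() {
  list(linear_offset = 26301, linear_divisor = 300,
       exp_center = 36000, exp_scale = 75)
}

#' Build a ranked gene-fraction model of the cDNA pool
#'
#' Constructs per-gene cDNA-pool fractions \eqn{p_i} over `n_genes` ranked gene
#' slots. Only ranks `i >= first_expressed_index` may be expressed. Raw weights
#' are, per expressed rank `i`:
#' \itemize{
#'   \item `linear`: \eqn{f_i = \max(0, \lfloor (i - o)/d \rfloor)} with offset
#'     `o = linear_offset` and divisor `d = linear_divisor`;
#'   \item `exponential`: \eqn{f_i = \exp((i - c)/s)} with center
#'     `c = exp_center` and scale `s = exp_scale` (kept real-valued);
#'   \item `combined`: the sum of both, with the exponential term applied only
#'     for `i >= exp_center` (it is below `exp(-125)` before that) and the total
#'     rounded half-away-from-zero to an integer molecule count.
#' }
#' Fractions are the normalized weights, forced to zero below
#' `first_expressed_index`. With the defaults the total molecule count of the
#' combined model is on the order of 1e5 and roughly 10,000 genes are expressed.
#'
#' @param kind one of `"combined"`, `"linear"`, `"exponential"`. The combined
#'   model is the reference cell state used by the benchmark populations.
#' @param n_genes number of ranked gene slots (default 36,601, a typical human
#'   gene panel).
#' @param first_expressed_index smallest rank allowed to be expressed
#'   (default 26,601, leaving ~10,000 expressible genes).
#' @param params optional named list overriding any of `linear_offset`,
#'   `linear_divisor`, `exp_center`, `exp_scale`.
#' @return An object of class `fraction_model`: a list with elements `n_genes`,
#'   `first_expressed_index`, `kind`, `f` (raw weights), `p` (fractions summing
#'   to 1), `params`, `integer_weights`, and an `edits` log (empty here) that
#'   records later state edits for reproducible export.
#' @examples
#' m <- build_fraction_model("combined")
#' sum(m$p)                    # 1
#' sum(m$p > 0)                # ~10,000 expressed genes
#' @seealso [permute_gene_identities()], [scale_gene_subset()],
#'   [derepress_genes()], [expected_nk()], [sample_cell_counts()]
#' @export
build_fraction_model <- function(kind = c("combined", "linear", "exponential"),
                                 n_genes = 36601L,
                                 first_expressed_index = 26601L,
                                 params = list()) {
  kind <- match.arg(kind)
  n_genes <- as.integer(n_genes)
  first_expressed_index <- as.integer(first_expressed_index)
  if (is.na(n_genes) || n_genes < 1L) stop("`n_genes` must be a positive integer")
  if (first_expressed_index < 1L || first_expressed_index > n_genes) {
    stop("`first_expressed_index` must lie in [1, n_genes]")
  }
  params <- utils::modifyList(default_fraction_params(), params)
  if (params$linear_divisor <= 0 || params$exp_scale <= 0) {
    stop("`linear_divisor` and `exp_scale` must be positive")
  }

  i <- seq_len(n_genes)
  lin <- pmax(0, floor((i - params$linear_offset) / params$linear_divisor))
  f <- switch(kind,
    linear = lin,
    exponential = exp((i - params$exp_center) / params$exp_scale),
    combined = round_half_up(
      lin + ifelse(i >= params$exp_center,
                   exp((i - params$exp_center) / params$exp_scale), 0)
    )
  )
  f[i < first_expressed_index] <- 0
  if (sum(f) <= 0) stop("model has no expressed gene (all raw weights zero)")

  new_fraction_model(
    f = f, kind = kind, n_genes = n_genes,
    first_expressed_index = first_expressed_index,
    params = params,
    integer_weights = kind %in% c("linear", "combined"),
    edits = list(),
    base = list(kind = kind, first_expressed_index = first_expressed_index)
  )
}

new_fraction_model <- function(f, kind, n_genes, first_expressed_index, params,
                               integer_weights, edits, base) {
  p <- f / sum(f)
  m <- structure(
    list(
      n_genes = n_genes,
      first_expressed_index = first_expressed_index,
      kind = kind,
      f = f,
      p = p,
      params = params,
      integer_weights = integer_weights,
      edits = edits,
      base = base
    ),
    class = "fraction_model"
  )
  validate_fraction_model(m)
  m
}

validate_fraction_model <- function(m) {
  stopifnot(inherits(m, "fraction_model"))
  if (length(m$f) != m$n_genes || length(m$p) != m$n_genes) {
    stop("weight vectors do not match `n_genes`")
  }
  if (any(m$f < 0)) stop("raw weights must be non-negative")
  if (abs(sum(m$p) - 1) > 1e-12) stop("fractions must sum to 1")
  if (m$integer_weights && any(m$f != round(m$f))) {
    stop("integer-weight model carries non-integral raw weights")
  }
  fei <- m$first_expressed_index
  if (fei > 1L && any(m$p[seq_len(fei - 1L)] > 0)) {
    stop("nonzero fraction below `first_expressed_index`")
  }
  invisible(m)
}

# Smallest expressed rank, used to refresh first_expressed_index after edits.
first_expressed <- function(f) {
  w <- which(f > 0)
  if (length(w) == 0L) stop("model has no expressed gene")
  w[1L]
}

#' Permute gene identities of a fraction model
#'
#' Applies one uniformly-random permutation to all gene slots, modelling a
#' completely distinct cell type with the same overall expression-magnitude
#' spectrum (the multiset of fractions is preserved exactly).
#'
#' @param model a [build_fraction_model()] object.
#' @param seed integer seed for the permutation; `NULL` draws from the current
#'   RNG stream (the permutation is then recorded explicitly for export).
#' @return A `fraction_model` with `kind = "edited"`; the edit log records the
#'   permutation provenance.
#' @export
permute_gene_identities <- function(model, seed = NULL) {
  validate_fraction_model(model)
  perm <- with_seed(seed, sample.int(model$n_genes))
  edit <- list(op = "permute", seed = seed)
  if (is.null(seed)) edit$perm <- perm
  new_fraction_model(
    f = model$f[perm], kind = "edited",
    n_genes = model$n_genes,
    first_expressed_index = first_expressed(model$f[perm]),
    params = model$params,
    integer_weights = model$integer_weights,
    edits = c(model$edits, list(edit)),
    base = model$base
  )
}

#' Scale the pool counts of a random gene subset
#'
#' Models pathway (signalling) activation: a random subset of expressed-range
#' genes has its raw molecule count multiplied by `up_factor` or `down_factor`,
#' with the direction drawn Bernoulli(0.5) per gene. The selected gene ids and
#' per-gene directions are recorded on the result so that the identical edit can
#' be applied again (a further activation step along a lineage reuses the same
#' genes and directions).
#'
#' @param model a `fraction_model`.
#' @param gene_ids optional explicit gene ids to scale; when supplied,
#'   `n_select` and `select_range` are ignored.
#' @param seed integer seed for gene selection and directions.
#' @param up_factor,down_factor positive multiplicative factors (defaults 2 and
#'   0.5; a milder activation uses 1.67 and 0.6).
#' @param n_select number of genes drawn when `gene_ids` is `NULL` (default 300).
#' @param select_range inclusive rank range to draw from (default
#'   `c(26602, 36601)`, the expressed range above the first expressed rank).
#' @param directions optional logical vector (`TRUE` = up) matched to
#'   `gene_ids`, for reapplying a recorded edit.
#' @return A `fraction_model` with `kind = "edited"`; the scaled gene ids and
#'   directions are stored in the last entry of `$edits`.
#' @export
scale_gene_subset <- function(model, gene_ids = NULL, seed = NULL,
                              up_factor = 2, down_factor = 0.5,
                              n_select = 300L,
                              select_range = c(26602L, 36601L),
                              directions = NULL) {
  validate_fraction_model(model)
  if (up_factor <= 0 || down_factor <= 0) stop("scaling factors must be positive")
  if (is.null(gene_ids)) {
    lo <- as.integer(select_range[1L]); hi <- as.integer(select_range[2L])
    if (hi < lo || lo < 1L || hi > model$n_genes) {
      stop("empty or out-of-range selection range")
    }
    if (n_select > hi - lo + 1L) stop("`n_select` exceeds the selection range")
  } else {
    if (any(gene_ids < 1L | gene_ids > model$n_genes)) {
      stop("`gene_ids` out of range")
    }
  }
  drawn <- with_seed(seed, {
    ids <- if (is.null(gene_ids)) {
      sample(seq(as.integer(select_range[1L]), as.integer(select_range[2L])),
             as.integer(n_select))
    } else {
      as.integer(gene_ids)
    }
    dirs <- if (is.null(directions)) {
      sample(c(TRUE, FALSE), length(ids), replace = TRUE)
    } else {
      as.logical(directions)
    }
    list(ids = ids, dirs = dirs)
  })
  if (length(drawn$dirs) != length(drawn$ids)) {
    stop("`directions` must match `gene_ids` in length")
  }

  f <- model$f
  f[drawn$ids] <- f[drawn$ids] * ifelse(drawn$dirs, up_factor, down_factor)
  if (model$integer_weights) f <- round_half_up(f)

  new_fraction_model(
    f = f, kind = "edited",
    n_genes = model$n_genes,
    first_expressed_index = first_expressed(f),
    params = model$params,
    integer_weights = model$integer_weights,
    edits = c(model$edits, list(list(
      op = "scale", seed = seed,
      gene_ids = drawn$ids, directions = drawn$dirs,
      up_factor = up_factor, down_factor = down_factor
    ))),
    base = model$base
  )
}

#' Derepress silenced genes
#'
#' Models epigenetic derepression: `n_select` genes drawn without replacement
#' from ranks `1..candidate_upper` (by default the silenced/low range) have
#' their pool molecule count set to `target_count`, making them expressible.
#'
#' @param model a `fraction_model`.
#' @param n_select number of genes to derepress (default 10).
#' @param target_count pool molecule count assigned to each (default 50).
#' @param candidate_upper top of the candidate rank range (default 26,601).
#' @param seed integer seed for the draw.
#' @return A `fraction_model` with `kind = "edited"` and an updated
#'   `first_expressed_index` reflecting the newly expressible genes.
#' @export
derepress_genes <- function(model, n_select = 10L, target_count = 50,
                            candidate_upper = 26601L, seed = NULL) {
  validate_fraction_model(model)
  candidate_upper <- as.integer(candidate_upper)
  if (candidate_upper < 1L || candidate_upper > model$n_genes) {
    stop("`candidate_upper` must lie in [1, n_genes]")
  }
  if (target_count <= 0) stop("`target_count` must be positive")
  if (n_select > candidate_upper) stop("`n_select` exceeds the candidate range")
  if (n_select == 0L) return(model)

  ids <- with_seed(seed, sample.int(candidate_upper, as.integer(n_select)))
  f <- model$f
  f[ids] <- target_count
  new_fraction_model(
    f = f, kind = "edited",
    n_genes = model$n_genes,
    first_expressed_index = first_expressed(f),
    params = model$params,
    integer_weights = model$integer_weights && target_count == round(target_count),
    edits = c(model$edits, list(list(
      op = "derepress", seed = seed,
      gene_ids = ids, target_count = target_count
    ))),
    base = model$base
  )
}

#' @export
print.fraction_model <- function(x, ...) {
  cat(sprintf("<fraction_model: %s>\n", x$kind))
  cat(sprintf("  genes: %d (expressed: %d, first expressed rank: %d)\n",
              x$n_genes, sum(x$p > 0), x$first_expressed_index))
  cat(sprintf("  total raw weight: %.4g (%s)\n", sum(x$f),
              if (x$integer_weights) "integer molecule counts" else "real-valued"))
  if (length(x$edits)) {
    cat(sprintf("  edits: %s\n",
                paste(vapply(x$edits, `[[`, "", "op"), collapse = " -> ")))
  }
  invisible(x)
}

#' Export a fraction model to JSON
#'
#' Writes the base model definition plus the ordered edit log (operation, seed,
#' explicit gene lists/permutations where no seed was recorded) so that
#' [read_fraction_model()] reconstructs the model byte-for-byte.
#'
#' @param model a `fraction_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fraction_model <- function(model, path) {
  validate_fraction_model(model)
  rec <- list(
    format = "manifoldtopo/fraction_model",
    version = 1L,
    base_kind = model$base$kind,
    n_genes = model$n_genes,
    first_expressed_index_base = model$base$first_expressed_index,
    params = model$params,
    edits = model$edits
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a fraction model from JSON
#'
#' Rebuilds the base model and replays the recorded edit operations in order.
#'
#' @param path a file written by [write_fraction_model()].
#' @return A `fraction_model`.
#' @export
read_fraction_model <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(rec$format, "manifoldtopo/fraction_model")) {
    stop("not a manifoldtopo fraction-model file: ", path)
  }
  m <- build_fraction_model(
    kind = rec$base_kind,
    n_genes = rec$n_genes,
    first_expressed_index = rec$first_expressed_index_base,
    params = as.list(rec$params)
  )
  edits <- rec$edits
  if (length(edits)) {
    if (is.data.frame(edits)) edits <- split(edits, seq_len(nrow(edits)))
    for (e in edits) {
      e <- as.list(e)
      op <- unlist(e$op)
      if (op == "permute") {
        if (!is.null(e$perm) && !all(is.na(unlist(e$perm)))) {
          perm <- as.integer(unlist(e$perm))
          m <- new_fraction_model(
            f = m$f[perm], kind = "edited", n_genes = m$n_genes,
            first_expressed_index = first_expressed(m$f[perm]),
            params = m$params, integer_weights = m$integer_weights,
            edits = c(m$edits, list(list(op = "permute", perm = perm))),
            base = m$base
          )
        } else {
          m <- permute_gene_identities(m, seed = unlist(e$seed))
        }
      } else if (op == "scale") {
        m <- scale_gene_subset(
          m, gene_ids = as.integer(unlist(e$gene_ids)),
          directions = as.logical(unlist(e$directions)),
          up_factor = unlist(e$up_factor), down_factor = unlist(e$down_factor)
        )
      } else if (op == "derepress") {
        ids <- as.integer(unlist(e$gene_ids))
        f <- m$f
        f[ids] <- unlist(e$target_count)
        m <- new_fraction_model(
          f = f, kind = "edited", n_genes = m$n_genes,
          first_expressed_index = first_expressed(f),
          params = m$params,
          integer_weights = m$integer_weights,
          edits = c(m$edits, list(list(op = "derepress", gene_ids = ids,
                                       target_count = unlist(e$target_count)))),
          base = m$base
        )
      } else {
        stop("unknown edit operation in model file: ", op)
      }
    }
  }
  m
}
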