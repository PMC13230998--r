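# Internal helpers: local seeding and deterministic seed derivation.

#' Evaluate code under a locally-set RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded operations never perturb global reproducibility. `seed = NULL` uses
#' the current RNG stream unchanged.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic Lehmer-style mixing; results stay in [1, 2^31 - 2] so they are
#' always valid arguments to [set.seed()]. Used to give every repeat/sub-draw of
#' a protocol its own recorded seed.
#' @noRd
derive_seed <- function(master, index) {
  if (is.null(master)) return(NULL)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.numeric(master)) %% m)
  for (ix in as.numeric(index)) {
    s <- (s * 48271 + ix + 1) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

# round half away from zero (base round() is half-to-even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
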