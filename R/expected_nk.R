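# Expected UMI-multiplicity spectra E[N_k] under Poisson / negative-binomial
# sampling of UMIs from a gene-fraction model.

#' Expected number of genes observed exactly k times
#'
#' For a gene-fraction model and a sampling depth `D`, computes
#' \eqn{E[N_k] = \sum_i P(X_i = k)} for `k = 0..k_max`, where the per-gene UMI
#' count is \eqn{X_i \sim \mathrm{Poisson}(\lambda_i)} with
#' \eqn{\lambda_i = D p_i}, or \eqn{X_i \sim \mathrm{NB}(\mu_i, \theta)} with
#' mean \eqn{\mu_i = D p_i} and dispersion \eqn{\theta} (variance
#' \eqn{\mu + \mu^2/\theta}; large \eqn{\theta} recovers the Poisson limit).
#' Genes with \eqn{p_i = 0} contribute wholly to \eqn{k = 0}.
#'
#' Identical per-gene means are aggregated before evaluating the pmf, so the
#' computation is fast even for the full 36,601-gene panel; pmf and tail values
#' come from [stats::dpois()]/[stats::dnbinom()], which evaluate in log space.
#'
#' Two conservation identities hold exactly (up to the reported truncation):
#' gene conservation \eqn{\sum_{k\le k_{max}} E[N_k] + \mathrm{truncation\_mass}
#' = n_{genes}} and UMI conservation \eqn{\sum_{k\ge 1} k\,E[N_k] +
#' \mathrm{truncated\_umi} = D}.
#'
#' @param model a [build_fraction_model()] object.
#' @param family `"poisson"` or `"negbin"`.
#' @param depth total number of sampled UMIs `D` (positive).
#' @param theta dispersion for `family = "negbin"` (positive; required there,
#'   ignored for Poisson).
#' @param k_max largest multiplicity evaluated; `NULL` (default) picks the
#'   smallest `k` at which every gene's survival mass is below `tail_tol`,
#'   capped at `k_cap`.
#' @param tail_tol per-gene survival mass used by the automatic `k_max` rule
#'   (default 1e-12).
#' @param k_cap cap for the automatic `k_max` (default 200; pass `Inf` for
#'   conservation checks at heavy-tailed settings).
#' @return An object of class `expected_nk`: list with `values` (numeric vector
#'   indexed `k = 0..k_max`), `k_max`, `family`, `depth`, `theta`,
#'   `truncation_mass` (total probability beyond `k_max`, in genes) and
#'   `truncated_umi` (expected UMIs carried by counts beyond `k_max`).
#' @examples
#' m <- build_fraction_model("combined")
#' enk <- expected_nk(m, "poisson", depth = 5000)
#' enk$values[2]  # E[N_1]
#' @export
expected_nk <- function(model, family = c("poisson", "negbin"), depth,
                        theta = NULL, k_max = NULL, tail_tol = 1e-12,
                        k_cap = 200L) {
  validate_fraction_model(model)
  family <- match.arg(family)
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1) {
    stop("`depth` must be a positive number (total sampled UMIs)")
  }
  if (family == "negbin") {
    if (is.null(theta)) stop("`theta` is required for the negative binomial family")
    if (theta <= 0) stop("`theta` must be positive")
  } else {
    theta <- NULL
  }

  mu <- depth * model$p
  srt <- sort(mu)
  rl <- rle(srt)
  uv <- rl$values   # unique per-gene means
  uw <- rl$lengths  # multiplicities
  mu_max <- uv[length(uv)]

  if (is.null(k_max)) {
    k_auto <- if (family == "poisson") {
      stats::qpois(tail_tol, mu_max, lower.tail = FALSE)
    } else {
      stats::qnbinom(tail_tol, size = theta, mu = mu_max, lower.tail = FALSE)
    }
    k_max <- max(1, min(k_auto + 1, k_cap))
  }
  if (k_max < 1) stop("`k_max` must be at least 1")
  k_max <- if (is.finite(k_max)) as.integer(k_max) else stop("`k_max` must be finite")

  ks <- 0:k_max
  pmf <- if (family == "poisson") {
    outer(ks, uv, function(k, m) stats::dpois(k, m))
  } else {
    outer(ks, uv, function(k, m) stats::dnbinom(k, size = theta, mu = m))
  }
  values <- as.numeric(pmf %*% uw)
  names(values) <- paste0("k", ks)

  if (family == "poisson") {
    tail_p <- stats::ppois(k_max, uv, lower.tail = FALSE)
    # k P(X = k) = lambda P(X = k - 1)  =>  E[X; X > K] = lambda P(X >= K)
    tail_e <- uv * stats::ppois(k_max - 1, uv, lower.tail = FALSE)
  } else {
    tail_p <- stats::pnbinom(k_max, size = theta, mu = uv, lower.tail = FALSE)
    # size-biased NB shift: k P(X = k) = mu P(Y = k - 1), Y ~ NB(theta + 1)
    tail_e <- uv * stats::pnbinom(k_max - 1, size = theta + 1,
                                  mu = uv * (theta + 1) / theta,
                                  lower.tail = FALSE)
  }

  structure(
    list(
      values = values,
      k_max = k_max,
      family = family,
      depth = depth,
      theta = theta,
      truncation_mass = sum(uw * tail_p),
      truncated_umi = sum(uw * tail_e),
      n_genes = model$n_genes
    ),
    class = "expected_nk"
  )
}

#' @export
print.expected_nk <- function(x, ...) {
  cat(sprintf("<expected_nk: %s, D = %g%s>\n", x$family, x$depth,
              if (!is.null(x$theta)) sprintf(", theta = %g", x$theta) else ""))
  cat(sprintf("  k = 0..%d; E[N_1] = %.3f, E[N_2] = %.3f\n",
              x$k_max, x$values[2], x$values[3]))
  cat(sprintf("  truncation: %.3g genes, %.3g UMIs beyond k_max\n",
              x$truncation_mass, x$truncated_umi))
  invisible(x)
}

#' Conservation diagnostics of an expected-multiplicity curve
#'
#' Returns the relative errors of the two conservation identities: genes
#' (\eqn{\sum_k E[N_k]} + truncation vs `n_genes`) and UMIs
#' (\eqn{\sum_k k E[N_k]} + truncated tail expectation vs `D`), plus the raw
#' (truncation-uncorrected) versions.
#'
#' @param enk an [expected_nk()] object.
#' @return Named numeric vector with elements `gene_relerr`, `umi_relerr`,
#'   `gene_relerr_raw`, `umi_relerr_raw`.
#' @export
nk_conservation <- function(enk) {
  stopifnot(inherits(enk, "expected_nk"))
  ks <- 0:enk$k_max
  gene_sum <- sum(enk$values)
  umi_sum <- sum(ks * enk$values)
  c(
    gene_relerr = abs(gene_sum + enk$truncation_mass - enk$n_genes) / enk$n_genes,
    umi_relerr = abs(umi_sum + enk$truncated_umi - enk$depth) / enk$depth,
    gene_relerr_raw = abs(gene_sum - enk$n_genes) / enk$n_genes,
    umi_relerr_raw = abs(umi_sum - enk$depth) / enk$depth
  )
}
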