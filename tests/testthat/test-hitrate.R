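# High/low-information partition, random-walk hit rates and their exact oracle.

test_that("depth labelling splits strictly above the threshold", {
  lab <- label_by_depth(c(10000, 10001), 10000)
  expect_identical(lab$high, c(FALSE, TRUE))
  expect_warning(label_by_depth(c(5, 6), 0), "one side")
  expect_warning(label_by_depth(c(5, 6), 10), "one side")
  expect_error(label_by_depth(c(1, 2), -1), "non-negative")
})

test_that("the path fixture has the hand-computed absorption probabilities", {
  # L1 - L2 - H chain, unit weights
  w <- adj_from_edges(3, c(1, 2), c(2, 3))
  high <- c(FALSE, FALSE, TRUE)
  p <- exact_hit_probability(w, high, k_walk = 5)
  expect_equal(unname(p), c(3 / 4, 7 / 8), tolerance = 1e-12)

  ht <- compute_hit_rate(w, high, k_walk = 5, trials = 1000, seed = 2)
  tol <- 4 * sqrt(p * (1 - p) / 1000)
  expect_true(all(abs(ht$hit_rate - p) <= tol + 1e-9))
})

test_that("absorption probabilities are nested in the walk length", {
  w <- adj_from_edges(5, c(1, 2, 3, 4), c(2, 3, 4, 5))
  high <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  expect_equal(unname(exact_hit_probability(w, high, k_walk = 0)), rep(0, 4))
  prev <- rep(0, 4)
  for (k in 1:8) {
    cur <- unname(exact_hit_probability(w, high, k_walk = k))
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("boundary regimes: all-high neighborhoods hit surely, low-only never", {
  # star: low center surrounded by 3 high leaves
  w <- adj_from_edges(4, c(1, 1, 1), c(2, 3, 4))
  high <- c(FALSE, TRUE, TRUE, TRUE)
  ht <- compute_hit_rate(w, high, k_walk = 1, trials = 50, seed = 1)
  expect_equal(ht$hit_rate, 1)

  # two components: one low-only pair, one high pair
  w2 <- adj_from_edges(4, c(1, 3), c(2, 4))
  high2 <- c(FALSE, FALSE, TRUE, TRUE)
  ht2 <- compute_hit_rate(w2, high2, k_walk = 10, trials = 50, seed = 1)
  expect_equal(ht2$hit_rate, c(0, 0))
  expect_equal(unname(exact_hit_probability(w2, high2, 10)), c(0, 0))

  # isolated low vertex: rate 0 with a warning
  w3 <- adj_from_edges(3, 2, 3)
  expect_warning(ht3 <- compute_hit_rate(w3, c(FALSE, FALSE, TRUE),
                                         trials = 20, seed = 1), "isolated")
  expect_equal(ht3$hit_rate[ht3$cell == 1], 0)
})

test_that("Monte-Carlo rates track the matrix-power oracle on random graphs", {
  set.seed(17)
  for (r in 1:12) {
    n <- sample(6:20, 1)
    repeat {
      em <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      keep <- runif(nrow(em)) < 0.25
      if (sum(keep) >= n - 1) break
    }
    w <- Matrix::sparseMatrix(
      i = c(em[keep, 1], em[keep, 2]), j = c(em[keep, 2], em[keep, 1]),
      x = rep(runif(sum(keep), 0.1, 2), 2), dims = c(n, n)
    )
    high <- runif(n) < 0.4
    if (!any(high) || all(high)) next
    p <- suppressWarnings(exact_hit_probability(w, high, k_walk = 5))
    ht <- suppressWarnings(compute_hit_rate(w, high, k_walk = 5, trials = 1000,
                                            seed = r))
    tol <- 4 * sqrt(p * (1 - p) / 1000)
    expect_true(all(abs(ht$hit_rate - p) <= tol + 1e-9))
  }
})

test_that("the hit-rate table is reproducible and bounded", {
  fx <- fixture_mixture()
  lab <- label_by_depth(fx$pop, 5000)
  a <- compute_hit_rate(fx$wf, lab, trials = 100, seed = 5)
  b <- compute_hit_rate(fx$wf, lab, trials = 100, seed = 5)
  expect_identical(a$hit_rate, b$hit_rate)
  expect_true(all(a$hit_rate >= 0 & a$hit_rate <= 1))
  expect_equal(nrow(a), sum(!lab$high))
})

test_that("Spearman correlation handles monotone, tied and constant input", {
  ht <- data.frame(cell = 1:4, depth = c(1, 2, 3, 4),
                   hit_rate = c(0.1, 0.2, 0.5, 0.9))
  expect_equal(spearman_hitrate_vs_depth(ht)$rho, 1)
  ht$hit_rate <- rev(ht$hit_rate)
  expect_equal(spearman_hitrate_vs_depth(ht)$rho, -1)

  tied <- data.frame(cell = 1:3, depth = c(1, 1, 2),
                     hit_rate = c(0.1, 0.2, 0.3))
  got <- spearman_hitrate_vs_depth(tied)
  expect_equal(got$rho, cor(rank(tied$depth), rank(tied$hit_rate)),
               tolerance = 1e-12)

  const <- data.frame(cell = 1:3, depth = c(1, 2, 3), hit_rate = rep(0.5, 3))
  expect_warning(out <- spearman_hitrate_vs_depth(const), "constant")
  expect_true(is.na(out$rho))
  expect_error(spearman_hitrate_vs_depth(tied[1:2, ]), "at least 3")
})
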