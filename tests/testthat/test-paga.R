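# PAGA cluster connectivity, frozen against the published reference
# implementation on two fixture graphs.

# directed kNN fixture: 12 vertices, 2 planted clusters, k = 3
paga_fixture_12 <- function() {
  from <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4, 5, 5, 5, 6, 6, 6,
            7, 7, 7, 8, 8, 8, 9, 9, 9, 10, 10, 10, 11, 11, 11, 12, 12, 12)
  to <- c(4, 6, 10, 1, 3, 5, 1, 2, 5, 9, 10, 11, 1, 2, 3, 1, 4, 10,
          6, 8, 9, 7, 9, 12, 4, 11, 12, 1, 4, 6, 4, 9, 12, 4, 9, 11)
  adj <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(12, 12))
  list(adj = adj, clusters = rep(c(0L, 1L), each = 6L))
}

# directed kNN fixture: 18 vertices, 3 planted clusters, k = 4
paga_fixture_18 <- function() {
  edges <- c(1, 4, 1, 5, 1, 6, 1, 11, 2, 4, 2, 6, 2, 13, 2, 17, 3, 1, 3, 2,
             3, 4, 3, 5, 4, 1, 4, 2, 4, 5, 4, 6, 5, 1, 5, 2, 5, 4, 5, 6,
             6, 2, 6, 4, 6, 13, 6, 17, 7, 6, 7, 10, 7, 14, 7, 16, 8, 9,
             8, 10, 8, 11, 8, 12, 9, 8, 9, 10, 9, 11, 9, 12, 10, 8, 10, 9,
             10, 11, 10, 12, 11, 8, 11, 9, 11, 10, 11, 12, 12, 8, 12, 9,
             12, 10, 12, 11, 13, 2, 13, 6, 13, 15, 13, 17, 14, 7, 14, 13,
             14, 15, 14, 18, 15, 7, 15, 13, 15, 14, 15, 18, 16, 7, 16, 10,
             16, 12, 16, 14, 17, 2, 17, 6, 17, 13, 17, 15, 18, 7, 18, 13,
             18, 14, 18, 15)
  em <- matrix(edges, ncol = 2, byrow = TRUE)
  adj <- Matrix::sparseMatrix(i = em[, 1], j = em[, 2], x = 1, dims = c(18, 18))
  list(adj = adj, clusters = rep(c(0L, 1L, 2L), each = 6L))
}

test_that("connectivity matches the reference implementation on frozen fixtures", {
  fx <- paga_fixture_12()
  ag <- compute_paga(fx$adj, fx$clusters)
  expect_equal(ag$connectivity["0", "1"], 11 / 18, tolerance = 1e-12)
  expect_equal(ag$connectivity["1", "0"], 11 / 18, tolerance = 1e-12)
  expect_equal(diag(ag$connectivity), c("0" = 0, "1" = 0))

  fx3 <- paga_fixture_18()
  ag3 <- compute_paga(fx3$adj, fx3$clusters)
  expect_equal(ag3$connectivity["0", "1"], 0.11805555555555555, tolerance = 1e-12)
  expect_equal(ag3$connectivity["0", "2"], 0.4722222222222222, tolerance = 1e-12)
  expect_equal(ag3$connectivity["1", "2"], 0.4722222222222222, tolerance = 1e-12)
})

test_that("connectivity is symmetric, bounded by 1 and zero without cross edges", {
  # two disconnected 3-cliques (directed both ways), two clusters
  from <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6)
  to <- c(2, 3, 1, 3, 1, 2, 5, 6, 4, 6, 4, 5)
  adj <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(6, 6))
  ag <- compute_paga(adj, rep(c(0L, 1L), each = 3L))
  expect_equal(max(ag$connectivity), 0)

  fx <- paga_fixture_18()
  ag3 <- compute_paga(fx$adj, fx$clusters)
  expect_equal(ag3$connectivity, t(ag3$connectivity))
  expect_true(all(ag3$connectivity <= 1))
})

test_that("a single cluster yields no connectivity pairs", {
  fx <- paga_fixture_12()
  ag <- compute_paga(fx$adj, rep(0L, 12))
  expect_equal(dim(ag$connectivity), c(1, 1))
  expect_equal(as.numeric(ag$connectivity), 0)
})

test_that("workflow results feed PAGA directly and label checks fire", {
  fx <- fixture_mixture()
  ag <- compute_paga(fx$wf)
  expect_equal(nrow(ag$connectivity), length(unique(fx$wf$clusters)))
  expect_error(compute_paga(paga_fixture_12()$adj, rep(0L, 5)), "vertex")
})
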