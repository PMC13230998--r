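# The standard workflow: QC, normalization, HVG, PCA, kNN graph, Louvain,
# and PC transfer.

test_that("mitochondrial QC applies a strict percentage cutoff", {
  counts <- cbind(c(1, 9), c(3, 17), c(0, 10))
  rownames(counts) <- c("MT-CO1", "ACTB")
  colnames(counts) <- c("a", "b", "c")
  kept <- qc_filter_mito(counts) # 10%, 15%, 0%
  expect_identical(colnames(kept), c("a", "c")) # 15.0% is removed (strict <)
  expect_identical(attr(kept, "kept"), c(1L, 3L))

  rownames(counts) <- c("GENE1", "GENE2")
  expect_warning(out <- qc_filter_mito(counts), "prefix")
  expect_equal(ncol(out), 3)
})

test_that("the workflow result satisfies its structural contract", {
  fx <- fixture_mixture()
  wf <- fx$wf
  n <- ncol(fx$pop$counts)
  expect_length(wf$clusters, n)
  expect_true(all(wf$clusters >= 0))
  expect_equal(wf$k_nn, max(5, round(0.01 * n)))
  # directed kNN adjacency: out-degree k_nn, no self loops
  expect_equal(unname(Matrix::rowSums(wf$knn_adj)), rep(wf$k_nn, n))
  expect_equal(sum(Matrix::diag(wf$knn_adj)), 0)
  # weighted graph: symmetric, positive, no self loops, every cell connected
  expect_equal(max(abs(wf$graph - Matrix::t(wf$graph))), 0)
  expect_true(all(wf$graph@x > 0))
  expect_equal(sum(Matrix::diag(wf$graph)), 0)
  expect_true(all(Matrix::rowSums(wf$graph > 0) >= 1))
  expect_equal(dim(wf$pc_scores), c(n, 30))
})

test_that("identical input and seed give identical clusterings", {
  fx <- fixture_mixture()
  wf2 <- run_standard_workflow(fx$pop, workflow_config(seed = 7))
  expect_identical(wf2$clusters, fx$wf$clusters)
  expect_equal(wf2$pc_scores, fx$wf$pc_scores)
})

test_that("distinct cell types separate into pure clusters at equal depth", {
  pure_seeds <- vapply(1:5, function(s) {
    pop <- simulate_population_X(seed = s,
                                 n_cells = c(Cell1 = 150L, Cell2 = 150L,
                                             Cell3 = 0L),
                                 depth_sd = 0)
    wf <- run_standard_workflow(pop, workflow_config(seed = s))
    tb <- table(pop$labels, wf$clusters)
    # every cluster is single-type and both types got at least one cluster
    all(colSums(tb > 0) == 1) && all(rowSums(tb) > 0)
  }, logical(1))
  expect_gte(sum(pure_seeds), 4)
})

test_that("too few cells for the neighbor rule is an error", {
  pop <- tiny_pop(rep(1000, 6))
  expect_error(run_standard_workflow(pop), "too few cells")
})

test_that("projection onto own loadings reproduces the fitted scores", {
  fx <- fixture_mixture()
  proj <- project_onto_loadings(fx$pop, fx$wf)
  expect_lt(max(abs(proj - fx$wf$pc_scores)), 1e-8)
})

test_that("projection matches a brute-force dense oracle", {
  fx <- fixture_mixture()
  wf <- fx$wf
  sub <- fx$pop$counts[, 1:7, drop = FALSE]
  proj <- project_onto_loadings(sub, wf)
  # oracle: full dense normalize/center/scale/clip/multiply, written out
  dep <- colSums(as.matrix(sub))
  xn <- log1p(t(t(as.matrix(sub)) / dep * wf$config$target_sum))
  xs <- (xn[wf$hvg, ] - wf$gene_means) / wf$gene_sds
  xs[xs > wf$config$scale_clip] <- wf$config$scale_clip
  xs[xs < -wf$config$scale_clip] <- -wf$config$scale_clip
  oracle <- t(xs) %*% wf$loadings
  expect_equal(unname(proj), unname(oracle), tolerance = 1e-10)
})

test_that("reference genes missing from the input are imputed at the center", {
  fx <- fixture_mixture()
  wf <- fx$wf
  sub <- fx$pop$counts[-wf$hvg[1], 1:5, drop = FALSE] # drop one reference HVG
  expect_warning(proj <- project_onto_loadings(sub, wf), "imputed")
  expect_equal(dim(proj), c(5, ncol(wf$pc_scores)))
})
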