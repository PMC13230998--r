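# Benchmark populations X/Y/Z and depth-based subset operators.

test_that("population X carries the prescribed states, sizes and depth floor", {
  pop <- simulate_population_X(seed = 3, n_cells = c(Cell1 = 40L, Cell2 = 20L,
                                                     Cell3 = 20L))
  expect_equal(ncol(pop$counts), 80)
  expect_equal(as.integer(table(pop$labels)[c("Cell1", "Cell2", "Cell3")]),
               c(40L, 20L, 20L))
  expect_true(all(pop$depths >= 500))
  expect_equal(as.numeric(Matrix::colSums(pop$counts)), as.numeric(pop$depths))
})

test_that("permuted cell types share almost no expressed genes with the reference", {
  pop <- simulate_population_X(seed = 3, n_cells = c(Cell1 = 5L, Cell2 = 5L,
                                                     Cell3 = 5L))
  ms <- pop$provenance$models
  s1 <- which(ms$Cell1$p > 0)
  s2 <- which(ms$Cell2$p > 0)
  # expected overlap of a random permutation: (10001/36601) * 10001 ~ 2733
  expect_lt(length(intersect(s1, s2)) / length(s1), 0.35)
  expect_gt(length(intersect(s1, s2)) / length(s1), 0.15)
})

test_that("identical seeds reproduce populations bit-for-bit", {
  a <- simulate_population_X(seed = 9, n_cells = c(Cell1 = 15L, Cell2 = 8L,
                                                   Cell3 = 8L))
  b <- simulate_population_X(seed = 9, n_cells = c(Cell1 = 15L, Cell2 = 8L,
                                                   Cell3 = 8L))
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$labels, b$labels)
})

test_that("population Y scales exactly 300 recorded genes of the reference model", {
  pop <- simulate_population_Y(seed = 5, n_cells = c(Cell1 = 5L, Cell4 = 5L))
  ms <- pop$provenance$models
  edit <- ms$Cell4$edits[[length(ms$Cell4$edits)]]
  expect_length(edit$gene_ids, 300)
  expect_true(all(edit$gene_ids >= 26602 & edit$gene_ids <= 36601))
  ndiff <- sum(ms$Cell1$f != ms$Cell4$f)
  # all differing genes are edited ones; a few unit-count genes scaled down
  # round back to their original integer count
  expect_lte(ndiff, 300)
  expect_gte(ndiff, 280)
  expect_true(all(which(ms$Cell1$f != ms$Cell4$f) %in% edit$gene_ids))
  expect_equal(sum(ms$Cell4$p), 1, tolerance = 1e-12)
})

test_that("population Z follows the lineage edit structure", {
  pop <- simulate_population_Z(seed = 5, cells_per_state = 4L)
  expect_equal(as.integer(table(pop$labels)), rep(4L, 5))
  ms <- pop$provenance$models
  eB <- ms$B$edits[[length(ms$B$edits)]]
  eC <- ms$C$edits[[length(ms$C$edits)]]
  expect_identical(eB$gene_ids, eC$gene_ids)
  expect_identical(eB$directions, eC$directions)
  for (st in c("D", "E")) {
    ids <- ms[[st]]$edits[[length(ms[[st]]$edits)]]$gene_ids
    expect_length(ids, 10)
    expect_true(all(ms[[st]]$p[ids] > 0))
    # newly expressed genes below the expressed range = the draws landing there
    expect_equal(sum(ms[[st]]$p[1:26600] > 0), sum(ids <= 26600))
  }
  # D and E draw independently
  idsD <- ms$D$edits[[length(ms$D$edits)]]$gene_ids
  idsE <- ms$E$edits[[length(ms$E$edits)]]$gene_ids
  expect_false(identical(sort(idsD), sort(idsE)))
})

test_that("depth filtering is strictly greater-than and keeps bookkeeping", {
  pop <- tiny_pop(c(3999, 4000, 4001), labels = c("a", "b", "c"))
  kept <- filter_by_total_umi(pop, 4000)
  expect_equal(ncol(kept$counts), 1)
  expect_identical(kept$labels, "c")
  expect_equal(as.numeric(Matrix::colSums(kept$counts)), 4001)

  expect_identical(filter_by_total_umi(pop, 0)$depths, pop$depths)
  expect_warning(filter_by_total_umi(pop, 1e7), "empty")
  expect_error(filter_by_total_umi(pop, -1), "non-negative")
})

test_that("top-n selection is depth-ranked with index tie-breaking", {
  pop <- tiny_pop(c(5, 9, 9, 2))
  top <- top_n_by_total_umi(pop, 2)
  expect_equal(top$depths, c(9L, 9L))
  expect_identical(colnames(top$counts), c("c002", "c003"))
  expect_equal(ncol(top_n_by_total_umi(pop, 0)$counts), 0)
  expect_identical(top_n_by_total_umi(pop, 4)$depths, pop$depths)
  expect_error(top_n_by_total_umi(pop, 5), "n")
})
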