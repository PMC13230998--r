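# Gene-fraction models: construction, invariants, and cell-state edits.

test_that("linear and combined weights take the hand-computed boundary values", {
  lin <- build_fraction_model("linear")
  expect_equal(lin$f[26601], 1)
  expect_equal(lin$f[26600], 0)
  expect_equal(lin$f[26901], 2) # next step of the staircase

  cmb <- build_fraction_model("combined")
  expect_equal(cmb$f[36601], 34 + round(exp(601 / 75)))
  expect_equal(cmb$f[26601], 1)
  # total molecule count on the order of 1e5
  expect_gt(sum(cmb$f), 1e5)
  expect_lt(sum(cmb$f), 1e6)
})

test_that("fractions are a probability vector, silent below the first expressed rank", {
  for (kind in c("linear", "exponential", "combined")) {
    m <- build_fraction_model(kind)
    expect_equal(sum(m$p), 1, tolerance = 1e-12)
    expect_true(all(m$p[1:26600] == 0))
    expect_true(all(m$f >= 0))
    expect_equal(sum(m$p > 0), 10001)
  }
})

test_that("linear and combined fractions are nondecreasing with integral weights", {
  for (kind in c("linear", "combined")) {
    m <- build_fraction_model(kind)
    expect_true(all(diff(m$p) >= 0))
    expect_true(all(m$f == round(m$f)))
  }
  # the pure exponential model keeps real-valued weights
  expect_false(build_fraction_model("exponential")$integer_weights)
})

test_that("invalid construction arguments are rejected", {
  expect_error(build_fraction_model("combined", n_genes = 0), "positive")
  expect_error(build_fraction_model("combined", n_genes = 100,
                                    first_expressed_index = 101), "n_genes")
  expect_error(build_fraction_model("combined", params = list(exp_scale = -1)),
               "positive")
})

test_that("gene-identity permutation preserves the fraction multiset and moves support", {
  m <- build_fraction_model("combined")
  p1 <- permute_gene_identities(m, seed = 1)
  expect_identical(sort(p1$p), sort(m$p))
  expect_equal(sum(p1$p), 1, tolerance = 1e-12)
  expect_identical(p1$kind, "edited")

  p2 <- permute_gene_identities(m, seed = 2)
  s1 <- which(p1$p > 0); s2 <- which(p2$p > 0)
  expect_false(identical(s1, s2))
  # same seed replays the same permutation
  expect_identical(permute_gene_identities(m, seed = 1)$p, p1$p)
})

test_that("a constant-weight model is invariant under permutation", {
  m <- tiny_model(rep(3, 8))
  expect_identical(permute_gene_identities(m, seed = 5)$f, m$f)
})

test_that("subset scaling matches hand computation and renormalizes", {
  m <- tiny_model(c(0, 4), fei = 2)
  out <- scale_gene_subset(m, gene_ids = 2L, directions = FALSE,
                           up_factor = 2, down_factor = 0.5)
  expect_equal(out$f, c(0, 2))
  expect_equal(out$p, c(0, 1))

  # unit factors leave the model unchanged
  m2 <- build_fraction_model("combined")
  id <- scale_gene_subset(m2, seed = 3, up_factor = 1, down_factor = 1)
  expect_equal(id$p, m2$p)

  expect_error(scale_gene_subset(m2, seed = 1, up_factor = -1), "positive")
  expect_error(scale_gene_subset(m, gene_ids = 9L, up_factor = 2), "range")
})

test_that("scaling records its gene set and directions for exact reuse", {
  a <- build_fraction_model("combined")
  b <- scale_gene_subset(a, seed = 4, up_factor = 1.67, down_factor = 0.6)
  e <- b$edits[[length(b$edits)]]
  expect_length(e$gene_ids, 300)
  expect_true(all(e$gene_ids >= 26602 & e$gene_ids <= 36601))
  cc <- scale_gene_subset(b, gene_ids = e$gene_ids, directions = e$directions,
                          up_factor = 1.67, down_factor = 0.6)
  e2 <- cc$edits[[length(cc$edits)]]
  expect_identical(e2$gene_ids, e$gene_ids)
  expect_identical(e2$directions, e$directions)
  # repeated same-direction scaling is monotone per gene on the raw weights
  up <- e$gene_ids[e$directions]
  expect_true(all(cc$f[up] >= b$f[up]))
})

test_that("derepression awakens silenced genes at the target pool count", {
  m <- tiny_model(c(0, 100), fei = 2)
  out <- derepress_genes(m, n_select = 1, target_count = 50,
                         candidate_upper = 1, seed = 1)
  expect_equal(out$p, c(1 / 3, 2 / 3))
  expect_equal(out$first_expressed_index, 1L)

  big <- build_fraction_model("combined")
  d <- derepress_genes(big, seed = 9)
  ids <- d$edits[[length(d$edits)]]$gene_ids
  expect_length(ids, 10)
  expect_true(all(ids >= 1 & ids <= 26601))
  expect_true(all(d$p[ids] > 0))

  expect_identical(derepress_genes(big, n_select = 0), big)
  expect_error(derepress_genes(m, n_select = 5, candidate_upper = 1), "exceeds")
})

test_that("an edited model round-trips byte-for-byte through JSON", {
  m <- build_fraction_model("combined")
  m <- permute_gene_identities(m, seed = 11)
  m <- scale_gene_subset(m, seed = 12, up_factor = 2, down_factor = 0.5,
                         n_select = 50, select_range = c(2, 36601))
  m <- derepress_genes(m, n_select = 5, seed = 13)
  fp <- withr::local_tempfile(fileext = ".json")
  write_fraction_model(m, fp)
  m2 <- read_fraction_model(fp)
  expect_identical(m2$f, m$f)
  expect_identical(m2$p, m$p)
  expect_identical(m2$first_expressed_index, m$first_expressed_index)
})
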