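test_that("ct tables read back with flooring and id validation", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("id,Tal1,Mycn", "c1,12.1,40", "c2,18.5,39.2"), path)
  ct <- read_ct_table(path)
  expect_equal(unname(ct$values), matrix(c(12.1, 18.5, 40, 39.2), 2, 2))
  expect_equal(ct$gene_ids, c("Tal1", "Mycn"))
  expect_equal(n_nondetect(ct), 1)

  writeLines(c("id,Tal1,Mycn", "c1,41.3,20"), path)
  expect_message(ct2 <- read_ct_table(path), "floored 1")
  expect_equal(ct2$values[1, "Tal1"], 40)

  writeLines(c("id,Tal1,Tal1", "c1,12,13"), path)
  expect_error(read_ct_table(path), "duplicate gene ids")

  writeLines(c("id,Tal1,Mycn", "c1,oops,20"), path)
  expect_error(read_ct_table(path), "non-numeric entry 'oops'.*row 'c1'.*column 'Tal1'")
})

test_that("ct_matrix enforces its invariants", {
  v <- matrix(c(10, 20, 30, 40), 2, 2)
  expect_error(ct_matrix(v, cell_ids = c("a", "a")), "duplicate cell ids")
  expect_error(ct_matrix(matrix(c(-1, 20, 30, 40), 2, 2)), "must lie in")
  expect_error(ct_matrix(matrix(c(10, 20, 30, 41), 2, 2)), "must lie in")
  expect_error(ct_matrix(v, cell_ids = "only_one"), "dimensions")
})

test_that("normalisation is median-centred, sign-correct and clamped", {
  ct <- ct_matrix(matrix(c(20, 22, 24), 3, 1, dimnames = list(NULL, "g")))
  expect_equal(unname(normalize_ct(ct)$values[, 1]), c(2, 0, -2))

  # nondetect at the floor clamps to -clamp_bound
  ct2 <- ct_matrix(matrix(c(20, 20, 40), 3, 1, dimnames = list(NULL, "g")))
  expect_equal(unname(normalize_ct(ct2, clamp_bound = 5)$values[, 1]), c(0, 0, -5))

  # constant column normalises to all zero
  ct3 <- ct_matrix(matrix(17.3, 4, 1, dimnames = list(NULL, "g")))
  expect_true(all(normalize_ct(ct3)$values == 0))

  expect_error(normalize_ct(ct_matrix(matrix(numeric(), 0, 0))), "empty")
})

test_that("normalisation is bounded and shift-equivariant", {
  sim <- make_separated_fixture(seed = 42, n_cells = 60)
  e <- normalize_ct(sim$ct, clamp_bound = 5)
  expect_lte(max(abs(e$values)), 5)

  # adding a constant to one gene's Ct column leaves its normalised values
  # unchanged (the median shifts identically); stay away from the clamp
  v <- sim$ct$values
  v2 <- v
  v2[, 3] <- v2[, 3] + 1.5
  e1 <- normalize_ct(ct_matrix(v), clamp_bound = 50)
  e2 <- normalize_ct(ct_matrix(v2), clamp_bound = 50)
  expect_equal(e1$values[, 3], e2$values[, 3])
})

test_that("pooled medians drive joint normalisation", {
  a <- ct_matrix(matrix(c(10, 12), 2, 1, dimnames = list(c("a1", "a2"), "g")))
  b <- ct_matrix(matrix(c(20, 22), 2, 1, dimnames = list(c("b1", "b2"), "g")))
  med <- pooled_gene_medians(list(a, b))
  expect_equal(unname(med), 16)
  ea <- normalize_ct(a, gene_medians = med, clamp_bound = 10)
  expect_equal(unname(ea$values[, 1]), c(6, 4))
})

test_that("chip reaction count is the assay x sample product", {
  expect_identical(chip_reaction_count(chip_layout(1, 1)), 1L)
  expect_identical(chip_reaction_count(chip_layout(48, 96)), 4608L)
  # equals brute-force enumeration of the grid
  lay <- chip_layout(7, 13)
  grid <- expand.grid(assay = seq_len(7), sample = seq_len(13))
  expect_identical(chip_reaction_count(lay), nrow(grid))
  expect_error(chip_layout(0, 5), ">= 1")
})

test_that("expression and ct tables round-trip losslessly", {
  set.seed(9)
  v <- matrix(runif(15, -5, 5), 5, 3,
              dimnames = list(paste0("c", 1:5), c("ga", "gb", "gc")))
  e <- expression_matrix(v)
  p <- tempfile(fileext = ".tsv")
  write_expression_table(e, p)
  e2 <- read_expression_table(p)
  expect_identical(e2$values, e$values)
  expect_identical(e2$cell_ids, e$cell_ids)

  # second write is byte-identical
  p2 <- tempfile(fileext = ".tsv")
  write_expression_table(e2, p2)
  expect_identical(readLines(p), readLines(p2))

  ct <- make_separated_fixture(seed = 2, n_cells = 20)$ct
  pc <- tempfile(fileext = ".csv")
  write_ct_table(ct, pc)
  ct2 <- read_ct_table(pc)
  expect_identical(ct2$values, ct$values)

  expect_error(write_expression_table(expression_matrix(matrix(numeric(), 0, 0)), p),
               "empty")
})

test_that("chip heatmap layout reads transposed to cells x genes", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("id,c1,c2,c3", "Tal1,12,13,14", "Mycn,20,21,22"), p)
  ct <- read_chip_heatmap(p)
  expect_equal(ct$cell_ids, c("c1", "c2", "c3"))
  expect_equal(ct$gene_ids, c("Tal1", "Mycn"))
  expect_equal(unname(ct$values["c2", "Mycn"]), 21)
})

test_that("nondetect gene filter drops saturated genes only when asked", {
  v <- matrix(c(40, 40, 40, 12, 14, 40), 3, 2, dimnames = list(NULL, c("dead", "ok")))
  ct <- ct_matrix(v)
  expect_identical(filter_nondetect_genes(ct)$gene_ids, c("dead", "ok"))
  expect_identical(filter_nondetect_genes(ct, 0.5)$gene_ids, "ok")
  expect_error(filter_nondetect_genes(ct, 0.1), "all genes exceed")
})
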