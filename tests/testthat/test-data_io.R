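test_that("dense and matrix-market round trips preserve values", {
  m <- toy_matrix(6, 4)
  st <- expression_study("s1", m)

  dense <- withr::local_tempfile(fileext = ".tsv")
  write_study(st, dense, format = "dense")
  back <- load_study(dense, format = "dense", study_id = "s1")
  expect_identical(dim(back$values), dim(m))
  expect_equal(back$values, m)

  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_study(st, mtx, format = "matrix_market")
  back2 <- load_study(mtx, format = "matrix_market", study_id = "s1")
  expect_equal(back2$values, m)

  # real values survive within tight tolerance
  st_real <- expression_study("s2", m + 0.123456789)
  write_study(st_real, mtx, format = "matrix_market")
  back3 <- load_study(mtx, format = "matrix_market", study_id = "s2")
  expect_equal(back3$values, st_real$values, tolerance = 1e-12)
})

test_that("an all-zero sparse matrix loads with its declared shape", {
  mtx <- withr::local_tempfile(fileext = ".mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general", "3 2 0"),
             mtx)
  writeLines(c("gA", "gB", "gC"), sub("\\.mtx$", "_genes.txt", mtx))
  writeLines(c("c1", "c2"), sub("\\.mtx$", "_cells.txt", mtx))
  st <- load_study(mtx, format = "matrix_market", study_id = "s")
  expect_identical(dim(st$values), c(3L, 2L))
  expect_true(all(st$values == 0))
})

test_that("negative expression values are rejected at load", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tc1\tc2", "gA\t1\t2", "gB\t-1.0\t3"), f)
  expect_error(load_study(f, "dense", "s1"), "negative")
})

test_that("duplicate gene rows are averaged elementwise", {
  m <- rbind(c(2, 4), c(4, 8))
  dimnames(m) <- list(c("GeneA", "GeneA"), c("c1", "c2"))
  out <- collapse_duplicate_genes(expression_study("s", m))
  expect_equal(unname(out$values["GeneA", ]), c(3, 6))

  m3 <- rbind(c(0, 0), c(3, 0), c(6, 3))
  dimnames(m3) <- list(rep("G", 3), c("c1", "c2"))
  out3 <- collapse_duplicate_genes(expression_study("s", m3))
  expect_equal(unname(out3$values["G", ]), c(3, 1))

  # idempotent, and identity when no duplicates exist
  expect_equal(collapse_duplicate_genes(out3)$values, out3$values)
  uniq <- expression_study("s", toy_matrix(4, 3))
  expect_equal(collapse_duplicate_genes(uniq)$values, uniq$values)
})

test_that("merging zero-fills absent genes and follows universe order", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("c1", "c2")))
  st <- expression_study("s1", m)
  merged <- merge_on_gene_universe(list(st), c("A", "B", "C"))
  expect_identical(rownames(merged$values), c("A", "B", "C"))
  expect_true(all(merged$values["C", ] == 0))

  # universe equal to the gene list: values unchanged up to row order
  perm <- merge_on_gene_universe(list(st), c("B", "A"))
  expect_equal(unname(perm$values), unname(m[c("B", "A"), ]))

  # disjoint gene sets give complementary zero blocks
  m2 <- matrix(5:8, 2, 2, dimnames = list(c("C", "D"), c("c1", "c2")))
  st2 <- expression_study("s2", m2)
  both <- merge_on_gene_universe(list(st, st2))
  expect_true(all(both$values[c("C", "D"), both$annotations$study_id ==
                                "s1"] == 0))
  expect_true(all(both$values[c("A", "B"), both$annotations$study_id ==
                                "s2"] == 0))
  expect_identical(colnames(both$values),
                   c("s1|c1", "s1|c2", "s2|c1", "s2|c2"))
})

test_that("merge result is invariant to study order up to columns", {
  sim <- generate_studies(synthetic_config(n_genes = 50, cells_per_type = 5,
                                           seed = 3))
  a <- merge_on_gene_universe(sim$studies,
                              rownames(sim$studies[[1]]$values),
                              metadata = sim$metadata)
  b <- merge_on_gene_universe(rev(sim$studies),
                              rownames(sim$studies[[1]]$values),
                              metadata = sim$metadata)
  cols <- colnames(a$values)
  expect_equal(a$values, b$values[, cols])
  expect_equal(a$annotations, b$annotations[cols, ])
})

test_that("low-coverage filter uses a strict threshold", {
  n_genes <- 1200
  vals <- matrix(0, n_genes, 3,
                 dimnames = list(sprintf("g%04d", 1:n_genes),
                                 c("c999", "c1000", "c1500")))
  vals[1:999, 1] <- 1
  vals[1:1000, 2] <- 1
  vals[1:1500 %% n_genes + 1, 3] <- 1
  merged <- toy_merged(vals, rep("s1", 3))
  kept <- filter_low_coverage_cells(merged, min_genes = 1000)
  expect_identical(kept$annotations$cell_id, c("c1000", "c1500"))

  # min_genes = 0 removes nothing
  expect_identical(ncol(filter_low_coverage_cells(merged, 0)$values), 3L)

  # removing everything reports the threshold and survivor counts
  expect_error(filter_low_coverage_cells(merged, n_genes + 1),
               "survivors per study")
})

test_that("unlabeled and missing-metadata cells are retained as NA", {
  m <- toy_matrix(4, 3)
  md <- data.frame(cell_id = c("c001", "c002"), study_id = "s1",
                   cell_type = c("T", ""), stringsAsFactors = FALSE)
  st <- expression_study("s1", m)
  merged <- merge_on_gene_universe(list(st), metadata = md)
  expect_identical(merged$annotations$cell_type, c("T", NA, NA))
})
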