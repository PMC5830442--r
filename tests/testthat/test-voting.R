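test_that("node degree sums all edge weights including the self-edge", {
  w <- matrix(c(1.0, 0.8, 0.2,
                0.8, 1.0, 0.5,
                0.2, 0.5, 1.0), 3, 3, byrow = TRUE)
  net <- manual_network(w)
  expect_equal(unname(node_degree(net)), c(2.0, 2.3, 1.7))

  const <- manual_network(matrix(0.25, 4, 4))
  expect_equal(unname(node_degree(const)), rep(4 * 0.25, 4))

  set.seed(2)
  m <- matrix(runif(16), 4, 4); m <- (m + t(m)) / 2
  expect_equal(unname(node_degree(manual_network(m))),
               apply(m, 1, sum))
})

test_that("neighbor voting is the degree-normalized label vote", {
  # first cell: self-weight 0.5 then 0.9, 0.7, 0.3, 0.1 to the others
  w <- diag(5) * 0 + 0.2
  w[1, ] <- c(0.5, 0.9, 0.7, 0.3, 0.1)
  w[, 1] <- w[1, ]
  diag(w) <- c(0.5, rep(1, 4))
  net <- manual_network(w)
  labels <- c(0, 1, 1, 0, 0)   # the scored cell's own label is hidden
  expect_equal(unname(neighbor_vote(net, labels)[1]), (0.9 + 0.7) / 2.5)

  expect_equal(unname(neighbor_vote(net, rep(1, 5))), rep(1, 5))
  expect_equal(unname(neighbor_vote(net, rep(0, 5))), rep(0, 5))
  expect_error(neighbor_vote(net, c(1, 0)), "length")
})

test_that("analytic AUROC reproduces the rank-sum formula cases", {
  expect_equal(analytic_auroc(c(1, 2, 3, 4), c(3, 4)), 1)    # ranks {3,4}
  expect_equal(analytic_auroc(c(3, 4, 1, 2), c(3, 4)), 0)    # ranks {1,2}
  expect_equal(analytic_auroc(c(3, 1, 4, 2), c(3, 4)), 0.75) # ranks {4,2}
  expect_true(is.na(analytic_auroc(c(1, 2), logical(2))))
  expect_true(is.na(analytic_auroc(c(1, 2), c(TRUE, TRUE))))
})

test_that("analytic AUROC equals the pairwise oracle and complements", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    scores <- sample(seq_len(10), n, replace = TRUE)  # heavy ties
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    a <- analytic_auroc(scores, pos)
    expect_equal(a, pairwise_auroc_oracle(scores, pos), tolerance = 1e-12)
    expect_equal(analytic_auroc(scores, !pos), 1 - a, tolerance = 1e-12)
  }
})

test_that("cross-dataset folds compose the exported primitives exactly", {
  sim <- generate_studies(synthetic_config(n_genes = 120,
                                           cells_per_type = 10, seed = 17))
  merged <- merge_on_gene_universe(sim$studies, metadata = sim$metadata)
  genes <- rownames(merged$values)[1:60]
  rep_out <- run_metaneighbor(merged, list(gs = genes))

  # oracle recomposition: training labels only (no leakage of test labels)
  net <- build_network(merged, genes)
  ann <- merged$annotations
  for (s in unique(ann$study_id)) {
    for (ct in c("type1", "type2")) {
      labels <- as.numeric(ann$cell_type == ct & ann$study_id != s)
      votes <- neighbor_vote(net, labels)
      test <- ann$study_id == s
      expected <- analytic_auroc(votes[test], ann$cell_type[test] == ct)
      got <- rep_out$folds$auroc[rep_out$folds$test_study == s &
                                   rep_out$folds$cell_type == ct]
      expect_equal(got, expected)
    }
  }
})

test_that("a test study without negatives yields a missing, excluded fold", {
  sim <- generate_studies(synthetic_config(n_genes = 100,
                                           cells_per_type = 8, seed = 23))
  md <- sim$metadata
  md$cell_type[md$study_id == "study3"] <- "type1"  # only positives there
  merged <- merge_on_gene_universe(sim$studies, metadata = md)
  rep_out <- run_metaneighbor(merged, list(gs = rownames(merged$values)),
                              cell_types = "type1")
  f <- rep_out$folds
  expect_true(is.na(f$auroc[f$test_study == "study3"]))
  expect_equal(rep_out$scores[1, "type1"],
               mean(f$auroc[f$test_study != "study3"]))
})

test_that("a single study is refused and unknown types are named", {
  sim <- generate_studies(synthetic_config(n_studies = 1, n_genes = 60,
                                           cells_per_type = 6, seed = 2))
  merged <- merge_on_gene_universe(sim$studies, metadata = sim$metadata)
  expect_error(run_metaneighbor(merged, list(gs = rownames(merged$values))),
               ">= 2 studies")

  sim2 <- generate_studies(synthetic_config(n_genes = 60,
                                            cells_per_type = 6, seed = 2))
  m2 <- merge_on_gene_universe(sim2$studies, metadata = sim2$metadata)
  expect_error(run_metaneighbor(m2, list(gs = rownames(m2$values)),
                                cell_types = "ghost"), "ghost")
})

test_that("reports print, summarize and export", {
  sim <- generate_studies(synthetic_config(n_genes = 80, cells_per_type = 6,
                                           seed = 31))
  merged <- merge_on_gene_universe(sim$studies, metadata = sim$metadata)
  rep_out <- run_metaneighbor(merged, list(a = rownames(merged$values)[1:40],
                                           b = rownames(merged$values)[41:80]))
  expect_output(print(rep_out), "metaneighbor_report")
  s <- summary(rep_out)
  expect_identical(s$cell_type, c("type1", "type2"))
  long <- withr::local_tempfile(fileext = ".tsv")
  wide <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep_out, long, wide)
  back <- read.table(long, header = TRUE, sep = "\t")
  expect_identical(nrow(back), nrow(rep_out$folds))
})
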