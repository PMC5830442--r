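test_that("perfectly corresponding synthetic types give identity blocks", {
  dj <- generate_disjoint_studies(n_studies = 2, cells_per_type = 15,
                                  seed = 12)
  md <- dj$metadata
  for (s in unique(md$study_id)) {   # study-specific label vocabularies
    i <- md$study_id == s
    md$cell_type[i] <- paste0(s, "_", md$cell_type[i])
  }
  merged <- merge_on_gene_universe(dj$studies, metadata = md)
  pam <- pairwise_auroc(merged, unlist(dj$markers), seed = 3)
  m <- pam$auroc
  expect_gt(m["study1|study1_typeA", "study2|study2_typeA"], 0.95)
  expect_gt(m["study1|study1_typeB", "study2|study2_typeB"], 0.95)
  expect_lt(m["study1|study1_typeA", "study2|study2_typeB"], 0.2)
  expect_true(isSymmetric(unname(m)))
  expect_equal(unname(diag(m)), rep(1, 4))
  # within-study entries are flagged as internally cross-validated
  expect_true(pam$within_study["study1|study1_typeA",
                               "study1|study1_typeB"])
  expect_false(pam$within_study["study1|study1_typeA",
                                "study2|study2_typeB"])

  groups <- identify_replicates(pam)
  expect_length(groups$groups, 2L)
  for (g in groups$groups) expect_length(g$studies, 2L)
})

test_that("reciprocal best hits require argmax in both directions", {
  m <- matrix(c(1.00, 0.70, 0.96, 0.60,
                0.70, 1.00, 0.55, 0.80,
                0.96, 0.55, 1.00, 0.65,
                0.60, 0.80, 0.65, 1.00), 4, 4, byrow = TRUE)
  nm <- c("A|a1", "A|a2", "B|b1", "B|b2")
  dimnames(m) <- list(nm, nm)
  pam <- manual_pairwise(m, c("A", "A", "B", "B"))
  rbh <- reciprocal_best_hits(pam)
  expect_identical(rbh$subtype_a, c("A|a1", "A|a2"))
  expect_identical(rbh$subtype_b, c("B|b1", "B|b2"))
  expect_false(any(rbh$tie))

  # a best hit that is not reciprocated disappears
  m2 <- m
  m2["A|a2", "B|b2"] <- 0.50   # b2's best in A becomes a1
  m2["B|b2", "A|a2"] <- 0.50
  rbh2 <- reciprocal_best_hits(manual_pairwise(m2, c("A", "A", "B", "B")))
  expect_identical(rbh2$subtype_a, "A|a1")

  # degenerate all-equal matrix: every pair co-maximal and tied
  m3 <- matrix(0.7, 4, 4, dimnames = dimnames(m))
  diag(m3) <- 1
  rbh3 <- reciprocal_best_hits(manual_pairwise(m3, c("A", "A", "B", "B")))
  expect_identical(nrow(rbh3), 4L)
  expect_true(all(rbh3$tie))
})

test_that("RBH output is invariant to subtype permutation", {
  set.seed(5)
  m <- matrix(runif(36, 0.3, 0.9), 6, 6)
  m <- (m + t(m)) / 2; diag(m) <- 1
  st <- rep(c("A", "B", "C"), each = 2)
  nm <- paste(st, paste0("t", 1:6), sep = "|")
  dimnames(m) <- list(nm, nm)
  rbh <- reciprocal_best_hits(manual_pairwise(m, st))
  perm <- sample(6)
  rbh_p <- reciprocal_best_hits(manual_pairwise(m[perm, perm], st[perm]))
  key <- function(d) sort(paste(pmin(d$subtype_a, d$subtype_b),
                                pmax(d$subtype_a, d$subtype_b)))
  expect_identical(key(rbh), key(rbh_p))
})

test_that("replicate groups are connected components of candidate edges", {
  # chain A1-B1, B1-C1 closes into one 3-study group
  nm <- c("A|1", "A|2", "B|1", "B|2", "C|1", "C|2")
  st <- rep(c("A", "B", "C"), each = 2)
  m <- matrix(0.55, 6, 6, dimnames = list(nm, nm))
  m["A|1", "B|1"] <- m["B|1", "A|1"] <- 0.97
  m["B|1", "C|1"] <- m["C|1", "B|1"] <- 0.96
  m["A|2", "B|2"] <- m["B|2", "A|2"] <- 0.70  # RBH but below threshold
  m["A|2", "C|2"] <- m["C|2", "A|2"] <- 0.60
  diag(m) <- 1
  pam <- manual_pairwise(m, st)
  groups <- identify_replicates(pam, threshold = 0.95)
  labels <- vapply(groups$groups, `[[`, "", "label")
  big <- groups$groups[[grep("A\\|1", labels)]]
  expect_setequal(big$members, c("A|1", "B|1", "C|1"))
  expect_setequal(big$studies, c("A", "B", "C"))

  # threshold above 1: only RBH edges remain usable
  g_rbh <- identify_replicates(pam, threshold = 1.01)
  expect_true(all(g_rbh$edges$rbh))

  # strict rule: RBH and threshold must both hold
  g_strict <- identify_replicates(pam, threshold = 0.95, strict = TRUE)
  expect_true(all(g_strict$edges$rbh & g_strict$edges$above_threshold))
})

test_that("lowering the threshold never removes a group member", {
  set.seed(13)
  m <- matrix(runif(64, 0.4, 1), 8, 8)
  m <- (m + t(m)) / 2; diag(m) <- 1
  st <- rep(c("A", "B"), each = 4)
  nm <- paste(st, paste0("t", 1:8), sep = "|")
  dimnames(m) <- list(nm, nm)
  pam <- manual_pairwise(m, st)
  grouped_at <- function(th) {
    sort(unlist(lapply(identify_replicates(pam, th)$groups,
                       `[[`, "members")))
  }
  for (th in c(0.95, 0.85, 0.75, 0.65)) {
    hi <- grouped_at(th)
    lo <- grouped_at(th - 0.1)
    expect_true(all(hi %in% lo))
  }
})

test_that("merged labels relabel members and feed back into voting", {
  dj <- generate_disjoint_studies(n_studies = 2, cells_per_type = 12,
                                  seed = 31)
  md <- dj$metadata
  for (s in unique(md$study_id)) {
    i <- md$study_id == s
    md$cell_type[i] <- paste0(s, "_", md$cell_type[i])
  }
  merged <- merge_on_gene_universe(dj$studies, metadata = md)
  pam <- pairwise_auroc(merged, unlist(dj$markers), seed = 3)
  groups <- identify_replicates(pam)
  relabeled <- merged_labels(groups, md)
  expect_identical(sort(unique(relabeled$cell_type)),
                   sort(vapply(groups$groups, `[[`, "", "label")))

  # empty group list leaves labels unchanged
  expect_identical(merged_labels(list(), md), md)

  # overlapping groups are refused
  overlap <- list(list(label = "x", members = c("study1|study1_typeA")),
                  list(label = "y", members = c("study1|study1_typeA")))
  expect_error(merged_labels(overlap, md), "overlap")

  # one AUROC per merged group, near-perfect for planted correspondence
  m2 <- merge_on_gene_universe(dj$studies, metadata = relabeled)
  rep_out <- run_metaneighbor(m2, list(mk = unlist(dj$markers)))
  expect_identical(ncol(rep_out$scores), length(groups$groups))
  expect_true(all(rep_out$scores > 0.95))
})
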