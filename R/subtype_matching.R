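subtype_key <- function(study_id, cell_type) paste(study_id, cell_type,
                                                   sep = "|")

#' All-vs-all pairwise subtype AUROCs
#'
#' For every ordered pair of study-qualified subtypes from different studies,
#' the train subtype's cells are used as voting positives and the test
#' subtype's cells are scored as positives against all other labeled cells of
#' the test subtype's own study. The reported entry is the mean of the two
#' directions (train->test and test->train), giving a symmetric matrix.
#' Within-study entries are filled by 2-fold cross-validation inside the
#' study (stratified by subtype, seeded) and flagged; the diagonal is defined
#' as 1.
#'
#' @param merged A `merged_experiment` with subtype labels in >= 2 studies.
#' @param gene_set Character vector of gene ids (typically a highly variable
#'   set computed on the compared studies).
#' @param within_study Fill within-study entries by internal CV
#'   (default TRUE).
#' @param seed Seed for the within-study fold split (default 1).
#' @param max_cells Passed to [build_network()].
#' @return Object of class `pairwise_auroc`: list with `auroc` (subtype x
#'   subtype matrix), `subtypes` (data.frame: subtype, study_id, cell_type)
#'   and `within_study` (logical matrix marking internally cross-validated
#'   entries).
#' @export
pairwise_auroc <- function(merged, gene_set, within_study = TRUE, seed = 1L,
                           max_cells = 50000L) {
  ann <- merged$annotations
  labeled <- !is.na(ann$cell_type)
  if (length(unique(ann$study_id[labeled])) < 2L)
    stop("pairwise matching requires labeled subtypes in >= 2 studies")
  key <- ifelse(labeled, subtype_key(ann$study_id, ann$cell_type), NA)
  tab <- unique(data.frame(subtype = key[labeled],
                           study_id = ann$study_id[labeled],
                           cell_type = ann$cell_type[labeled],
                           stringsAsFactors = FALSE))
  tab <- tab[order(tab$subtype), ]
  rownames(tab) <- NULL
  k <- nrow(tab)

  net <- build_network(merged, gene_set, max_cells = max_cells)
  deg <- node_degree(net)
  lab_mat <- sapply(tab$subtype, function(st) as.numeric(!is.na(key) &
                                                           key == st))
  votes <- (net$weights %*% lab_mat) / deg

  raw <- matrix(NA_real_, k, k, dimnames = list(tab$subtype, tab$subtype))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j || tab$study_id[i] == tab$study_id[j]) next
      test_cells <- labeled & ann$study_id == tab$study_id[j]
      raw[i, j] <- analytic_auroc(votes[test_cells, i],
                                  key[test_cells] == tab$subtype[j])
    }
  }
  m <- (raw + t(raw)) / 2
  ws <- outer(tab$study_id, tab$study_id, `==`)
  dimnames(ws) <- dimnames(m)

  if (within_study) {
    set.seed(seed)
    for (s in unique(tab$study_id)) {
      members <- which(tab$study_id == s)
      if (length(members) < 2L) next
      in_study <- which(labeled & ann$study_id == s)
      fold <- integer(length(key))
      for (st in tab$subtype[members]) {
        cells <- which(!is.na(key) & key == st)
        fold[cells[sample.int(length(cells))]] <- rep_len(1:2, length(cells))
      }
      acc <- array(NA_real_, c(length(members), length(members), 2L))
      for (f in 1:2) {
        train_lab <- sapply(tab$subtype[members], function(st)
          as.numeric(!is.na(key) & key == st & fold == (3L - f)))
        vf <- (net$weights %*% train_lab) / deg
        test_cells <- intersect(in_study, which(fold == f))
        for (a in seq_along(members)) {
          for (b in seq_along(members)) {
            if (a == b) next
            acc[a, b, f] <- analytic_auroc(
              vf[test_cells, a],
              key[test_cells] == tab$subtype[members[b]])
          }
        }
      }
      per_dir <- apply(acc, c(1, 2), mean, na.rm = TRUE)
      per_dir[is.nan(per_dir)] <- NA_real_
      m[members, members] <- (per_dir + t(per_dir)) / 2
    }
  }
  diag(m) <- 1
  structure(list(auroc = m, subtypes = tab, within_study = ws),
            class = "pairwise_auroc")
}

#' @export
print.pairwise_auroc <- function(x, ...) {
  cat(sprintf("<pairwise_auroc> %d subtype(s) across %d studies\n",
              nrow(x$subtypes), length(unique(x$subtypes$study_id))))
  invisible(x)
}

#' @export
plot.pairwise_auroc <- function(x, ...) {
  m <- x$auroc
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  zlim = c(0, 1), col = grDevices::hcl.colors(64, "YlOrRd",
                                                              rev = TRUE),
                  ...)
  graphics::axis(1, seq_len(n), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(n), rev(rownames(m)), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Reciprocal best matches between studies
#'
#' A cross-study pair (A, B) is reported when B is A's highest-scoring
#' subtype within B's study and A is B's highest-scoring subtype within A's
#' study. Co-maximal ties are all reported and flagged.
#'
#' @param matrix_ A `pairwise_auroc` object.
#' @return data.frame with columns subtype_a, subtype_b, score, tie.
#' @export
reciprocal_best_hits <- function(matrix_) {
  m <- matrix_$auroc
  st <- matrix_$subtypes$study_id
  out <- list()
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(m))) {
      if (j <= i || st[i] == st[j]) next
      in_j <- which(st == st[j])
      in_i <- which(st == st[i])
      best_ij <- max(m[i, in_j], na.rm = TRUE)
      best_ji <- max(m[j, in_i], na.rm = TRUE)
      if (isTRUE(m[i, j] == best_ij) && isTRUE(m[j, i] == best_ji)) {
        tie <- sum(m[i, in_j] == best_ij, na.rm = TRUE) > 1L ||
          sum(m[j, in_i] == best_ji, na.rm = TRUE) > 1L
        out[[length(out) + 1L]] <- data.frame(
          subtype_a = rownames(m)[i], subtype_b = rownames(m)[j],
          score = m[i, j], tie = tie, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(subtype_a = character(), subtype_b = character(),
                      score = numeric(), tie = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Minimal union-find for grouping candidate edges into components.
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Identify putatively replicated subtypes
#'
#' Candidate edges are reciprocal best matches plus cross-study pairs with an
#' AUROC at or above `threshold` (the union reading; `strict = TRUE` requires
#' a pair to be both an RBH and above threshold). Groups are the connected
#' components of the candidate-edge graph; singleton components are dropped.
#' Every group spans >= 2 studies by construction.
#'
#' @param matrix_ A `pairwise_auroc` object.
#' @param threshold AUROC threshold for candidate pairs (default 0.95).
#' @param strict Require RBH AND threshold rather than their union.
#' @return Object of class `replicate_groups`: list with `groups` (each a
#'   list with label, members, studies, auroc submatrix) and `edges` (the
#'   candidate pairs with provenance flags).
#' @export
identify_replicates <- function(matrix_, threshold = 0.95, strict = FALSE) {
  stopifnot(threshold >= 0.5)  # thresholds > 1 are allowed and vacuous
  m <- matrix_$auroc
  st <- matrix_$subtypes$study_id
  rbh <- reciprocal_best_hits(matrix_)
  rbh_key <- paste(rbh$subtype_a, rbh$subtype_b)
  edges <- list()
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(m))) {
      if (j <= i || st[i] == st[j]) next
      is_rbh <- paste(rownames(m)[i], rownames(m)[j]) %in% rbh_key
      above <- isTRUE(m[i, j] >= threshold)
      keep <- if (strict) is_rbh && above else is_rbh || above
      if (keep)
        edges[[length(edges) + 1L]] <- data.frame(
          subtype_a = rownames(m)[i], subtype_b = rownames(m)[j],
          score = m[i, j], rbh = is_rbh, above_threshold = above,
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(subtype_a = character(), subtype_b = character(),
               score = numeric(), rbh = logical(),
               above_threshold = logical(), stringsAsFactors = FALSE)
  parent <- seq_len(nrow(m))
  for (e in seq_len(nrow(edges))) {
    a <- uf_find(parent, match(edges$subtype_a[e], rownames(m)))
    b <- uf_find(parent, match(edges$subtype_b[e], rownames(m)))
    parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), 0L)
  groups <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    if (length(members) < 2L) next
    nm <- rownames(m)[members]
    groups[[length(groups) + 1L]] <- list(
      label = paste(nm, collapse = "+"),
      members = nm,
      studies = unique(st[members]),
      auroc = m[members, members, drop = FALSE])
  }
  structure(list(groups = groups, edges = edges, threshold = threshold,
                 strict = strict),
            class = "replicate_groups")
}

#' @export
print.replicate_groups <- function(x, ...) {
  cat(sprintf("<replicate_groups> %d group(s) (threshold %.2f, %s rule)\n",
              length(x$groups), x$threshold,
              if (x$strict) "strict" else "union"))
  for (g in x$groups)
    cat(" -", g$label, sprintf("(%d members, %d studies)\n",
                               length(g$members), length(g$studies)))
  invisible(x)
}

#' Relabel cells with merged replicate-group labels
#'
#' Cells belonging to a member subtype of any group receive the group label;
#' all other cells keep their original label. The result is suitable as
#' input to [run_metaneighbor()] or [meta_de()].
#'
#' @param groups A `replicate_groups` object (or list of group lists).
#' @param annotations Annotation data.frame (cell_id, study_id, cell_type).
#' @return The annotation data.frame with updated cell_type labels.
#' @export
merged_labels <- function(groups, annotations) {
  glist <- if (inherits(groups, "replicate_groups")) groups$groups else groups
  members <- unlist(lapply(glist, `[[`, "members"))
  if (anyDuplicated(members))
    stop("replicate groups overlap in membership: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  key <- subtype_key(annotations$study_id, annotations$cell_type)
  for (g in glist)
    annotations$cell_type[key %in% g$members] <- g$label
  annotations
}
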