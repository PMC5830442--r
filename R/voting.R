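#' Node degree of every cell
#'
#' Sum of each cell's edge weights, self-edge included. Used as the null
#' predictor in neighbor voting: hub cells that are generically similar to
#' everything are downweighted.
#'
#' @param network A `cell_network`.
#' @return Named numeric vector of strictly positive degrees.
#' @export
node_degree <- function(network) {
  rowSums(network$weights)
}

#' Neighbor-voting scores for a binary label vector
#'
#' Each cell's score is the weighted fraction of its neighbors (itself
#' included in the denominator) that carry the label:
#' `score = (W %*% labels) / degree`. Scores lie in [0, 1].
#'
#' @param network A `cell_network`.
#' @param labels Binary (0/1) vector, one entry per cell; hidden test cells
#'   carry 0 so they cannot vote for themselves.
#' @return Numeric score vector, one entry per cell.
#' @export
neighbor_vote <- function(network, labels) {
  labels <- as.numeric(labels)
  if (length(labels) != length(network$cell_ids))
    stop("label vector length (", length(labels),
         ") does not match network size (", length(network$cell_ids), ")")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  as.vector(network$weights %*% labels) / node_degree(network)
}

#' Analytic AUROC from rank sums
#'
#' Computes the area under the ROC curve from the rank sum of the positives,
#' equivalent to the Mann-Whitney U statistic scaled to [0, 1]:
#' `sum(ranks[pos]) / (N * N_neg) - (N + 1) / (2 * N_neg)`,
#' with scores ranked ascending and average ranks for ties. Equals the
#' probability that a positive outranks a negative (ties counting 1/2).
#'
#' @param scores Finite numeric prediction scores.
#' @param positives Logical vector the length of `scores`, or integer indices
#'   of the positive entries.
#' @return AUROC in [0, 1], or `NA` when there are no positives or no
#'   negatives (undefined by construction).
#' @export
analytic_auroc <- function(scores, positives) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  n <- length(scores)
  if (is.logical(positives)) {
    if (length(positives) != n)
      stop("logical 'positives' must match the length of 'scores'")
    pos <- positives
  } else {
    pos <- rep(FALSE, n)
    pos[positives] <- TRUE
  }
  n_pos <- sum(pos)
  n_neg <- n - n_pos
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  ranks <- rank(scores)
  sum(ranks[pos]) / (n_pos * n_neg) - (n_pos + 1) / (2 * n_neg)
}

#' Cross-dataset replicability scores by neighbor voting
#'
#' The core procedure. For each gene set, one standardized Spearman network is
#' built over all cells. Every study is then held out in turn
#' (leave-one-dataset-out): its labels are hidden, training positives are
#' pooled from all other studies, cells are scored by degree-normalized
#' neighbor voting, and an analytic AUROC is computed among the held-out
#' study's labeled cells only — comparative assessment of cells happens
#' within a dataset, but on training information strictly from outside it.
#' Per-type scores are reported as the mean AUROC across folds, excluding
#' folds where the AUROC is undefined (no positives or no negatives in the
#' test study, or a type absent from all training studies).
#'
#' @param merged A `merged_experiment` with >= 2 studies.
#' @param gene_sets A `gene_set_collection` (see [parse_gmt()]), a named list
#'   of character vectors, or a single character vector of gene ids.
#' @param cell_types Cell types to assess; default all labeled types, sorted.
#' @param max_cells Passed to [build_network()].
#' @return Object of class `metaneighbor_report`: list with `scores` (gene
#'   sets x cell types matrix of fold-mean AUROCs) and `folds` (long
#'   data.frame: gene_set, cell_type, test_study, auroc).
#' @export
run_metaneighbor <- function(merged, gene_sets, cell_types = NULL,
                             max_cells = 50000L) {
  ann <- merged$annotations
  studies <- sort(unique(ann$study_id))
  if (length(studies) < 2L)
    stop("cross-dataset validation requires >= 2 studies")
  sets <- as_gene_set_list(gene_sets)
  if (is.null(cell_types))
    cell_types <- sort(unique(ann$cell_type[!is.na(ann$cell_type)]))
  if (!length(cell_types)) stop("no labeled cell types to assess")
  absent <- cell_types[!cell_types %in% ann$cell_type]
  if (length(absent))
    stop("requested cell type(s) not labeled in any study: ",
         paste(absent, collapse = ", "))
  cell_types <- sort(cell_types)

  labeled <- !is.na(ann$cell_type)
  folds <- vector("list", length(sets))
  scores <- matrix(NA_real_, length(sets), length(cell_types),
                   dimnames = list(names(sets), cell_types))
  for (k in seq_along(sets)) {
    genes <- intersect(sets[[k]], rownames(merged$values))
    if (length(genes) < 2L) {
      warning("gene set '", names(sets)[k],
              "' has < 2 usable genes; skipped")
      next
    }
    net <- build_network(merged, genes, max_cells = max_cells)
    deg <- node_degree(net)
    rec <- expand.grid(test_study = studies, cell_type = cell_types,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rec$auroc <- NA_real_
    for (s in studies) {
      in_test <- ann$study_id == s
      train_lab <- matrix(0, nrow(ann), length(cell_types),
                          dimnames = list(NULL, cell_types))
      for (ct in cell_types)
        train_lab[labeled & !in_test & ann$cell_type == ct, ct] <- 1
      votes <- (net$weights %*% train_lab) / deg
      test_lab <- in_test & labeled
      for (ct in cell_types) {
        if (sum(train_lab[, ct]) == 0) next   # type absent from training
        auc <- analytic_auroc(votes[test_lab, ct],
                              ann$cell_type[test_lab] == ct)
        rec$auroc[rec$test_study == s & rec$cell_type == ct] <- auc
      }
    }
    rec$gene_set <- names(sets)[k]
    folds[[k]] <- rec[, c("gene_set", "cell_type", "test_study", "auroc")]
    means <- tapply(rec$auroc, rec$cell_type, mean, na.rm = TRUE)
    means[is.nan(means)] <- NA_real_
    scores[k, names(means)] <- means
  }
  structure(list(scores = scores, folds = do.call(rbind, folds),
                 cell_types = cell_types, studies = studies),
            class = "metaneighbor_report")
}

#' @export
print.metaneighbor_report <- function(x, ...) {
  cat(sprintf(
    "<metaneighbor_report> %d gene set(s) x %d cell type(s), %d studies\n",
    nrow(x$scores), ncol(x$scores), length(x$studies)))
  cat("fold-mean AUROCs (column means across gene sets):\n")
  print(round(colMeans(x$scores, na.rm = TRUE), 3))
  invisible(x)
}

#' @export
summary.metaneighbor_report <- function(object, ...) {
  s <- object$scores
  out <- data.frame(
    cell_type = colnames(s),
    mean_auroc = colMeans(s, na.rm = TRUE),
    sd_auroc = apply(s, 2L, stats::sd, na.rm = TRUE),
    n_gene_sets = colSums(!is.na(s)),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("summary.metaneighbor_report", "data.frame")
  out
}

#' @export
plot.metaneighbor_report <- function(x, ...) {
  graphics::boxplot(x$scores, ylab = "AUROC", ylim = c(0, 1),
                    las = 2, ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey40")
  invisible(x)
}

#' Export a report as long and wide TSV tables
#'
#' @param report A `metaneighbor_report`.
#' @param long_path,wide_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, long_path = NULL, wide_path = NULL) {
  if (!is.null(long_path))
    utils::write.table(report$folds, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(wide_path)) {
    tab <- data.frame(gene_set = rownames(report$scores), report$scores,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, wide_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(long_path, wide_path))
}
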