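#' Cell-cell Spearman similarity over a gene set
#'
#' Correlates every pair of cells across the genes of `gene_set` (intersected
#' with the measured universe), using average ranks for ties. A cell with zero
#' variance across the set has no defined correlation; its off-diagonal
#' entries are set to 0 with a warning so the network stays total and finite.
#'
#' @param merged A `merged_experiment`.
#' @param gene_set Character vector of gene ids.
#' @return Symmetric cells x cells matrix of Spearman correlations with unit
#'   diagonal.
#' @export
spearman_similarity <- function(merged, gene_set) {
  genes <- intersect(gene_set, rownames(merged$values))
  if (length(genes) < 2L)
    stop("gene set has fewer than 2 genes in the measured universe (",
         length(genes), " overlapping)")
  if (ncol(merged$values) < 2L) stop("at least 2 cells are required")
  x <- merged$values[genes, , drop = FALSE]
  r <- apply(x, 2L, rank)                       # per-cell gene ranks, avg ties
  zv <- apply(r, 2L, function(col) all(col == col[1L]))
  cc <- suppressWarnings(stats::cor(r))         # Pearson on ranks = Spearman
  if (any(zv)) {
    warning(sum(zv), " cell(s) with zero variance across the gene set; ",
            "their correlations are set to 0")
    cc[zv, ] <- 0
    cc[, zv] <- 0
  }
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  dimnames(cc) <- list(colnames(merged$values), colnames(merged$values))
  cc
}

#' Rank-standardize a similarity matrix to (0, 1]
#'
#' Every entry is replaced by its rank among all matrix entries (average ranks
#' for ties, self-edges included) divided by the maximum rank. This is a
#' monotone transform, keeps the matrix symmetric, and bounds all weights in
#' (0, 1] with the maximum attaining exactly 1.
#'
#' @param raw Square numeric matrix with finite entries.
#' @return An object of class `cell_network`: list with `cell_ids` and
#'   `weights` (cells x cells matrix in (0, 1]).
#' @export
rank_standardize <- function(raw) {
  raw <- as.matrix(raw)
  if (any(!is.finite(raw))) stop("similarity matrix has non-finite entries")
  r <- rank(raw)
  w <- matrix(r / max(r), nrow(raw), ncol(raw), dimnames = dimnames(raw))
  structure(list(cell_ids = colnames(raw), weights = w),
            class = "cell_network")
}

#' Build the standardized cell-cell network for a gene set
#'
#' Composition of [spearman_similarity()] and [rank_standardize()]. Because
#' Spearman works on within-cell gene ranks, the network is invariant to any
#' rank-preserving normalization of the expression values (log2, TPM, RPKM).
#' The network is dense, O(cells^2) in memory; inputs above `max_cells`
#' columns are refused.
#'
#' @inheritParams spearman_similarity
#' @param max_cells Refuse inputs with more cells than this (default 50000).
#' @return A `cell_network`.
#' @export
build_network <- function(merged, gene_set, max_cells = 50000L) {
  n <- ncol(merged$values)
  if (n > max_cells)
    stop("input has ", n, " cells; the dense network is limited to ",
         max_cells, " (raise max_cells explicitly to override)")
  rank_standardize(spearman_similarity(merged, gene_set))
}

#' @export
print.cell_network <- function(x, ...) {
  w <- x$weights
  cat(sprintf("<cell_network> %d cells; weights in [%.4g, %.4g]\n",
              length(x$cell_ids), min(w), max(w)))
  invisible(x)
}

#' Write / read a cell network as TSV
#'
#' Cell ids appear as both the header row and the first column.
#'
#' @param network A `cell_network`.
#' @param path Output (or input) path.
#' @return `write_network` returns the path invisibly; `read_network` a
#'   `cell_network`.
#' @export
write_network <- function(network, path) {
  tab <- data.frame(cell_id = network$cell_ids, network$weights,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           row.names = NULL, quote = "", comment.char = "")
  w <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(w) <- tab[[1L]]
  structure(list(cell_ids = rownames(w), weights = w), class = "cell_network")
}
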