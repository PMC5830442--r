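# Small in-code fixtures shared across test files.

# Build a merged experiment directly from a genes x cells matrix.
toy_merged <- function(values, study_ids, cell_types = NULL) {
  studies <- lapply(unique(study_ids), function(s) {
    expression_study(s, values[, study_ids == s, drop = FALSE])
  })
  md <- data.frame(
    cell_id = colnames(values), study_id = study_ids,
    cell_type = if (is.null(cell_types)) NA_character_ else cell_types,
    stringsAsFactors = FALSE)
  merge_on_gene_universe(studies, rownames(values), metadata = md)
}

# A deterministic non-negative matrix with gene/cell names.
toy_matrix <- function(n_genes, n_cells, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda = 5), n_genes, n_cells)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("c%03d", seq_len(n_cells)))
  m
}

# Wrap a raw symmetric weight matrix as a cell_network without standardizing.
manual_network <- function(weights) {
  ids <- colnames(weights)
  if (is.null(ids)) {
    ids <- paste0("cell", seq_len(ncol(weights)))
    dimnames(weights) <- list(ids, ids)
  }
  structure(list(cell_ids = ids, weights = weights), class = "cell_network")
}

# Brute-force AUROC: fraction of (positive, negative) pairs where the
# positive outranks the negative, ties counting one half.
pairwise_auroc_oracle <- function(scores, pos) {
  ps <- scores[pos]
  ns <- scores[!pos]
  if (!length(ps) || !length(ns)) return(NA_real_)
  cmp <- outer(ps, ns, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Wrap a score matrix as a pairwise_auroc object for matching tests.
manual_pairwise <- function(m, study_ids) {
  tab <- data.frame(subtype = rownames(m), study_id = study_ids,
                    cell_type = sub("^[^|]*\\|", "", rownames(m)),
                    stringsAsFactors = FALSE)
  ws <- outer(study_ids, study_ids, `==`)
  dimnames(ws) <- dimnames(m)
  structure(list(auroc = m, subtypes = tab, within_study = ws),
            class = "pairwise_auroc")
}
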