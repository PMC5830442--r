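#' Configuration for the synthetic multi-study generator
#'
#' Defaults emulate a modest cross-laboratory comparison: three studies
#' sharing two cell types, 50 cells per type per study, 500 genes with 50
#' markers per type, a two-fold (log2-scale) marker shift, lognormal
#' study-specific per-gene batch factors, negative-binomial counts and
#' independent dropout.
#'
#' @param n_studies Number of studies.
#' @param n_types Number of shared cell types.
#' @param cells_per_type Cells per type per study; scalar or per-type vector
#'   (to emulate incidences down to a few percent).
#' @param n_genes Number of genes.
#' @param n_marker_genes_per_type Markers per type (disjoint blocks);
#'   default one tenth of the genes split evenly over `2 * n_types` blocks,
#'   i.e. 50 per type for two types over 500 genes.
#' @param effect_size Log2-scale mean shift applied to a type's markers.
#' @param batch_sd SD of the per-study per-gene log-normal batch factor.
#' @param dropout_rate Probability an observed count is zeroed, in [0, 1).
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param seed Integer seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_studies = 3L, n_types = 2L,
                             cells_per_type = 50L, n_genes = 500L,
                             n_marker_genes_per_type =
                               max(1L, n_genes %/% (5L * n_types)),
                             effect_size = 2, batch_sd = 0.5,
                             dropout_rate = 0.2, dispersion = 0.5,
                             seed = 1L) {
  cells_per_type <- rep_len(as.integer(cells_per_type), n_types)
  stopifnot(n_studies >= 1, n_types >= 1, all(cells_per_type >= 1),
            n_genes >= 1, n_marker_genes_per_type >= 0,
            n_marker_genes_per_type * n_types <= n_genes,
            dropout_rate >= 0, dropout_rate < 1, dispersion >= 0)
  structure(list(n_studies = n_studies, n_types = n_types,
                 cells_per_type = cells_per_type, n_genes = n_genes,
                 n_marker_genes_per_type = n_marker_genes_per_type,
                 effect_size = effect_size, batch_sd = batch_sd,
                 dropout_rate = dropout_rate, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate synthetic multi-study single-cell expression
#'
#' Per-gene baseline means are drawn from a lognormal (heavy-tailed,
#' positive); each type's marker block is shifted up by `2^effect_size`;
#' each study multiplies every gene by its own lognormal batch factor;
#' counts are negative-binomial at the resulting mean, then thinned by
#' independent dropout. Ground-truth labels and the marker map are returned
#' alongside the data so tests never re-derive them.
#'
#' @param config A [synthetic_config()].
#' @return List with `studies` (list of [expression_study()]), `metadata`
#'   (data.frame: cell_id, study_id, cell_type) and `markers` (named list of
#'   marker gene ids per type).
#' @export
generate_studies <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  types <- sprintf("type%d", seq_len(config$n_types))
  base_mu <- stats::rlnorm(config$n_genes, meanlog = 1, sdlog = 1)
  m <- config$n_marker_genes_per_type
  markers <- stats::setNames(lapply(seq_len(config$n_types), function(k)
    genes[((k - 1L) * m + seq_len(m))]), types)
  type_mu <- matrix(base_mu, config$n_genes, config$n_types,
                    dimnames = list(genes, types))
  for (k in seq_len(config$n_types))
    type_mu[markers[[k]], k] <- type_mu[markers[[k]], k] *
      2^config$effect_size

  studies <- vector("list", config$n_studies)
  meta <- list()
  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  for (d in seq_len(config$n_studies)) {
    sid <- sprintf("study%d", d)
    batch <- stats::rlnorm(config$n_genes, meanlog = 0,
                           sdlog = config$batch_sd)
    cols <- list(); labels <- character(0)
    for (k in seq_len(config$n_types)) {
      nc <- config$cells_per_type[k]
      mu <- type_mu[, k] * batch
      cnt <- matrix(stats::rnbinom(config$n_genes * nc, mu = mu,
                                   size = size),
                    config$n_genes, nc)
      if (config$dropout_rate > 0)
        cnt <- cnt * matrix(stats::rbinom(length(cnt), 1L,
                                          1 - config$dropout_rate),
                            nrow(cnt), ncol(cnt))
      cols[[k]] <- cnt
      labels <- c(labels, rep(types[k], nc))
    }
    vals <- do.call(cbind, cols)
    dimnames(vals) <- list(genes,
                           sprintf("cell_%03d", seq_len(ncol(vals))))
    studies[[d]] <- expression_study(sid, vals)
    meta[[d]] <- data.frame(cell_id = colnames(vals), study_id = sid,
                            cell_type = labels, stringsAsFactors = FALSE)
  }
  list(studies = studies, metadata = do.call(rbind, meta),
       markers = markers)
}

#' Generate studies with disjointly supported cell types
#'
#' An idealized strong-signal construction: type A cells express only the
#' first marker block and type B cells only the second, with zero expression
#' off-support. Shared identically across studies (up to sampling noise), it
#' yields perfect cross-dataset discrimination and is useful as a positive
#' control.
#'
#' @param n_studies Number of studies (default 3).
#' @param cells_per_type Cells per type per study (default 30).
#' @param genes_per_type Genes in each type's expressed block (default 100).
#' @param mean_expr Mean count on the expressed block (default 20).
#' @param dispersion Negative-binomial dispersion (default 0.5).
#' @param seed Integer seed.
#' @return Same structure as [generate_studies()].
#' @export
generate_disjoint_studies <- function(n_studies = 3L, cells_per_type = 30L,
                                      genes_per_type = 100L, mean_expr = 20,
                                      dispersion = 0.5, seed = 1L) {
  set.seed(seed)
  n_genes <- 2L * genes_per_type
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  markers <- list(typeA = genes[seq_len(genes_per_type)],
                  typeB = genes[genes_per_type + seq_len(genes_per_type)])
  size <- if (dispersion > 0) 1 / dispersion else Inf
  studies <- vector("list", n_studies)
  meta <- list()
  for (d in seq_len(n_studies)) {
    sid <- sprintf("study%d", d)
    vals <- matrix(0, n_genes, 2L * cells_per_type)
    vals[seq_len(genes_per_type), seq_len(cells_per_type)] <-
      stats::rnbinom(genes_per_type * cells_per_type, mu = mean_expr,
                     size = size)
    vals[genes_per_type + seq_len(genes_per_type),
         cells_per_type + seq_len(cells_per_type)] <-
      stats::rnbinom(genes_per_type * cells_per_type, mu = mean_expr,
                     size = size)
    dimnames(vals) <- list(genes, sprintf("cell_%03d",
                                          seq_len(ncol(vals))))
    studies[[d]] <- expression_study(sid, vals)
    meta[[d]] <- data.frame(
      cell_id = colnames(vals), study_id = sid,
      cell_type = rep(c("typeA", "typeB"), each = cells_per_type),
      stringsAsFactors = FALSE)
  }
  list(studies = studies, metadata = do.call(rbind, meta),
       markers = markers)
}

#' Permute cell-type labels within each study
#'
#' Null harness for calibration: per-study label frequencies are preserved
#' exactly while any association between label and expression is destroyed.
#'
#' @param annotations data.frame with columns cell_id, study_id, cell_type.
#' @param seed Integer seed.
#' @return The annotation data.frame with permuted cell_type values.
#' @export
shuffle_labels <- function(annotations, seed) {
  set.seed(seed)
  for (s in unique(annotations$study_id)) {
    idx <- which(annotations$study_id == s)
    annotations$cell_type[idx] <-
      annotations$cell_type[idx[sample.int(length(idx))]]
  }
  annotations
}
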