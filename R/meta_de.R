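#' One-sided Wilcoxon rank-sum p-value
#'
#' Tests the alternative that `in_group` is stochastically greater than
#' `out_group`. The exact null distribution is enumerated when the combined
#' sample size is at most 20 and there are no ties; otherwise the normal
#' approximation with tie correction (and continuity correction) is used.
#'
#' @param in_group,out_group Non-empty numeric vectors.
#' @return p-value in (0, 1].
#' @export
wilcoxon_one_sided <- function(in_group, out_group) {
  if (!length(in_group) || !length(out_group))
    stop("both groups must be non-empty")
  n <- length(in_group) + length(out_group)
  ties <- anyDuplicated(c(in_group, out_group)) > 0L
  exact <- n <= 20L && !ties
  stats::wilcox.test(in_group, out_group, alternative = "greater",
                     exact = exact, correct = TRUE)$p.value
}

#' Combine p-values with Fisher's method
#'
#' `chi_square = -2 * sum(log(p))` follows a chi-square distribution with
#' `2k` degrees of freedom under the joint null. Zero p-values are clamped
#' to the smallest positive double, with a warning.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return List with `chi_square`, `df` and `meta_p`.
#' @export
fisher_combine <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (!length(pvalues)) stop("no p-values to combine")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  if (any(pvalues == 0)) {
    warning("p-value of 0 clamped to the smallest positive double")
    pvalues[pvalues == 0] <- .Machine$double.xmin
  }
  chi <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(chi_square = chi, df = df,
       meta_p = stats::pchisq(chi, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, monotone and capped at 1.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Meta-analytic differential expression across datasets
#'
#' For each requested cell type, every contributing dataset tests each gene
#' with a one-sided Wilcoxon rank-sum (type's cells vs all other labeled
#' cells of that dataset); per-dataset p-values are combined with Fisher's
#' method and adjusted by Benjamini-Hochberg across genes within the type.
#' Per-dataset log2 fold changes use means with a pseudocount:
#' `log2((mean_in + eps) / (mean_out + eps))`.
#'
#' @param merged A `merged_experiment` (labels may come from
#'   [merged_labels()]).
#' @param cell_types Types to test; default all labeled types present in
#'   >= 1 study.
#' @param eps Pseudocount on the expression scale (default 1).
#' @return Object of class `meta_de`: named list (one per cell type) of
#'   data.frames with columns gene, p.<study>, log2fc.<study>, chi_square,
#'   df, meta_p, fdr.
#' @export
meta_de <- function(merged, cell_types = NULL, eps = 1) {
  ann <- merged$annotations
  labeled <- !is.na(ann$cell_type)
  if (is.null(cell_types))
    cell_types <- sort(unique(ann$cell_type[labeled]))
  genes <- rownames(merged$values)
  out <- list()
  for (ct in cell_types) {
    studies <- sort(unique(ann$study_id[labeled & ann$cell_type == ct]))
    pmat <- matrix(NA_real_, length(genes), length(studies),
                   dimnames = list(genes, studies))
    fcmat <- pmat
    for (s in studies) {
      in_cells <- labeled & ann$study_id == s & ann$cell_type == ct
      out_cells <- labeled & ann$study_id == s & ann$cell_type != ct
      if (!any(out_cells)) next   # no within-study out-group: drop dataset
      xin <- merged$values[, in_cells, drop = FALSE]
      xout <- merged$values[, out_cells, drop = FALSE]
      fcmat[, s] <- log2((rowMeans(xin) + eps) / (rowMeans(xout) + eps))
      pmat[, s] <- vapply(seq_along(genes), function(g)
        wilcoxon_one_sided(xin[g, ], xout[g, ]), 0)
    }
    used <- colSums(!is.na(pmat)) > 0
    pmat <- pmat[, used, drop = FALSE]
    fcmat <- fcmat[, used, drop = FALSE]
    if (!ncol(pmat)) next
    comb <- lapply(seq_along(genes), function(g)
      fisher_combine(pmat[g, ]))
    df <- data.frame(gene = genes,
                     chi_square = vapply(comb, `[[`, 0, "chi_square"),
                     df = vapply(comb, `[[`, 0L, "df"),
                     meta_p = vapply(comb, `[[`, 0, "meta_p"),
                     stringsAsFactors = FALSE)
    df$fdr <- bh_adjust(df$meta_p)
    for (s in colnames(pmat)) {
      df[[paste0("p.", s)]] <- pmat[, s]
      df[[paste0("log2fc.", s)]] <- fcmat[, s]
    }
    out[[ct]] <- df
  }
  structure(list(tables = out, eps = eps), class = "meta_de")
}

#' @export
print.meta_de <- function(x, ...) {
  cat(sprintf("<meta_de> %d cell type(s); pseudocount eps = %g\n",
              length(x$tables), x$eps))
  for (ct in names(x$tables))
    cat(sprintf(" - %s: %d genes, %d at FDR < 0.001\n", ct,
                nrow(x$tables[[ct]]), sum(x$tables[[ct]]$fdr < 0.001)))
  invisible(x)
}

#' Select marker genes from a meta-analytic DE result
#'
#' Markers must reach `fdr < fdr_max` and exceed `min_log2fc` in every
#' contributing dataset; they are returned ranked by mean log2 fold change,
#' largest first.
#'
#' @param de A `meta_de` object.
#' @param cell_type Which type's table to filter; default the first.
#' @param fdr_max Meta-analytic FDR ceiling (default 0.001).
#' @param min_log2fc Per-dataset log2 fold-change floor (default 2).
#' @return data.frame of passing genes, ranked by mean log2 fold change.
#' @export
select_markers <- function(de, cell_type = NULL, fdr_max = 0.001,
                           min_log2fc = 2) {
  if (is.null(cell_type)) cell_type <- names(de$tables)[1L]
  tab <- de$tables[[cell_type]]
  if (is.null(tab)) stop("no DE table for cell type '", cell_type, "'")
  fc_cols <- grep("^log2fc\\.", names(tab), value = TRUE)
  fc <- as.matrix(tab[, fc_cols, drop = FALSE])
  pass <- tab$fdr < fdr_max & apply(fc > min_log2fc, 1L, all)
  out <- tab[pass, , drop = FALSE]
  out$mean_log2fc <- rowMeans(fc[pass, , drop = FALSE])
  out[order(-out$mean_log2fc), , drop = FALSE]
}

#' Export meta-DE tables as TSV, one file per cell type
#'
#' @param de A `meta_de` object.
#' @param dir Output directory.
#' @param fdr_max,min_log2fc Thresholds used to compute the `pass` flag
#'   column.
#' @return Invisibly, the written paths.
#' @export
write_meta_de <- function(de, dir, fdr_max = 0.001, min_log2fc = 2) {
  paths <- character(0)
  for (ct in names(de$tables)) {
    tab <- de$tables[[ct]]
    fc_cols <- grep("^log2fc\\.", names(tab), value = TRUE)
    tab$pass <- tab$fdr < fdr_max &
      apply(as.matrix(tab[, fc_cols, drop = FALSE]) > min_log2fc, 1L, all)
    p <- file.path(dir, paste0("meta_de_", gsub("[^A-Za-z0-9_.-]", "_", ct),
                               ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
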