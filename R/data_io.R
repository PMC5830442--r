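#' Construct an expression study
#'
#' Wraps one study's genes x cells expression matrix together with its
#' identifiers. Values may be in any rank-preserving unit (counts, TPM, RPKM,
#' log2 and so on); downstream scoring uses Spearman correlation, so only the
#' within-cell ordering of genes matters.
#'
#' @param study_id Single string naming the study.
#' @param values Numeric genes x cells matrix with gene ids as rownames and
#'   cell ids as colnames. All values must be finite and non-negative.
#' @return An object of class `expression_study` with fields `study_id` and
#'   `values`.
#' @export
expression_study <- function(study_id, values) {
  stopifnot(is.character(study_id), length(study_id) == 1L, nzchar(study_id))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must carry gene rownames and cell colnames")
  if (anyDuplicated(colnames(values)))
    stop("cell ids must be unique within study '", study_id, "'")
  if (any(!is.finite(values)))
    stop("non-finite expression value in study '", study_id, "'")
  if (any(values < 0))
    stop("negative expression value in study '", study_id, "'")
  structure(list(study_id = study_id, values = values),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> '%s': %d genes x %d cells\n",
              x$study_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read one study's expression matrix
#'
#' Dense format is a TSV/CSV with genes as rows: first column gene id, header
#' row of cell ids. Sparse format is a MatrixMarket coordinate file with two
#' sidecar text files of row (gene) and column (cell) names, one per line.
#'
#' @param expression_path Path to the expression file.
#' @param format `"dense"` or `"matrix_market"`.
#' @param study_id Study identifier to attach.
#' @param row_names_path,col_names_path Sidecar name files for
#'   `matrix_market`; defaults are `<path minus .mtx>_genes.txt` and
#'   `<path minus .mtx>_cells.txt`.
#' @param sep Field separator for the dense format (default tab).
#' @return An [expression_study()].
#' @export
load_study <- function(expression_path, format = c("dense", "matrix_market"),
                       study_id,
                       row_names_path = NULL, col_names_path = NULL,
                       sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(expression_path))
    stop("expression file not found: ", expression_path)
  if (format == "dense") {
    tab <- utils::read.table(expression_path, header = TRUE, sep = sep,
                             row.names = NULL, check.names = FALSE,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
    if (ncol(tab) < 2L)
      stop("dense expression file needs a gene id column plus >=1 cell: ",
           expression_path)
    genes <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals))) & !is.na(vals))
      stop("non-numeric expression entry in ", expression_path,
           if (length(bad)) paste0(" (entry ", bad[1L], ")") else "")
    }
    rownames(vals) <- genes
  } else {
    stem <- sub("\\.mtx$", "", expression_path)
    if (is.null(row_names_path)) row_names_path <- paste0(stem, "_genes.txt")
    if (is.null(col_names_path)) col_names_path <- paste0(stem, "_cells.txt")
    for (p in c(row_names_path, col_names_path))
      if (!file.exists(p)) stop("sidecar name file not found: ", p)
    m <- Matrix::readMM(expression_path)
    vals <- as.matrix(m)
    genes <- readLines(row_names_path)
    cells <- readLines(col_names_path)
    if (length(genes) != nrow(vals) || length(cells) != ncol(vals))
      stop("sidecar name counts (", length(genes), " genes, ", length(cells),
           " cells) do not match matrix shape ", nrow(vals), " x ", ncol(vals))
    dimnames(vals) <- list(genes, cells)
  }
  expression_study(study_id, vals)
}

#' Write one study's expression matrix
#'
#' Mirrors [load_study()]: dense TSV or MatrixMarket plus sidecar name files.
#'
#' @param study An [expression_study()].
#' @param expression_path Output path.
#' @param format `"dense"` or `"matrix_market"`.
#' @inheritParams load_study
#' @return Invisibly, the expression path.
#' @export
write_study <- function(study, expression_path,
                        format = c("dense", "matrix_market"),
                        row_names_path = NULL, col_names_path = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    tab <- data.frame(gene_id = rownames(study$values), study$values,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, expression_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    stem <- sub("\\.mtx$", "", expression_path)
    if (is.null(row_names_path)) row_names_path <- paste0(stem, "_genes.txt")
    if (is.null(col_names_path)) col_names_path <- paste0(stem, "_cells.txt")
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(study$values,
                                                           sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    expression_path)
    writeLines(rownames(study$values), row_names_path)
    writeLines(colnames(study$values), col_names_path)
  }
  invisible(expression_path)
}

#' Read a cell metadata table
#'
#' TSV with required columns `cell_id`, `study_id`, `cell_type`; an empty
#' `cell_type` string marks an unlabeled cell and is stored as `NA`.
#'
#' @param path Path to the metadata TSV.
#' @return data.frame with columns cell_id, study_id, cell_type.
#' @export
load_cell_metadata <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", colClasses = "character")
  need <- c("cell_id", "study_id", "cell_type")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("metadata is missing required column(s): ",
         paste(miss, collapse = ", "))
  tab <- tab[, need]
  tab$cell_type[!nzchar(tab$cell_type)] <- NA_character_
  if (anyDuplicated(tab[, c("study_id", "cell_id")]))
    stop("duplicated (study_id, cell_id) pair in metadata")
  tab
}

#' Average duplicated gene rows
#'
#' Rows sharing a gene id are replaced by their elementwise arithmetic mean,
#' keeping the order of first occurrence.
#'
#' @param study An [expression_study()].
#' @return An [expression_study()] with unique gene ids.
#' @export
collapse_duplicate_genes <- function(study) {
  g <- rownames(study$values)
  if (!anyDuplicated(g)) return(study)
  first <- !duplicated(g)
  sums <- rowsum(study$values, group = g, reorder = FALSE)
  counts <- as.vector(table(factor(g, levels = rownames(sums))))
  vals <- sums / counts
  vals <- vals[g[first], , drop = FALSE]
  expression_study(study$study_id, vals)
}

#' Merge studies onto a shared gene universe
#'
#' Rows follow `gene_universe` order; genes a study did not measure are
#' zero-filled for that study's cells. Cell ids are namespaced as
#' `"study_id|cell_id"` so they are globally unique. Cells without a metadata
#' row are retained unlabeled (`cell_type = NA`) and never used for training.
#'
#' @param studies List of [expression_study()] objects (duplicate gene ids
#'   are collapsed first).
#' @param gene_universe Ordered character vector of gene ids; default is the
#'   union of the studies' genes in order of first appearance.
#' @param metadata Optional data.frame with columns cell_id, study_id,
#'   cell_type (see [load_cell_metadata()]).
#' @return An object of class `merged_experiment`: list with `values`
#'   (genes x cells matrix) and `annotations` (data.frame with one row per
#'   column: cell_id, study_id, cell_type).
#' @export
merge_on_gene_universe <- function(studies, gene_universe = NULL,
                                   metadata = NULL) {
  if (!length(studies)) stop("at least one study is required")
  studies <- lapply(studies, collapse_duplicate_genes)
  ids <- vapply(studies, `[[`, "", "study_id")
  if (anyDuplicated(ids)) stop("duplicate study ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  if (is.null(gene_universe))
    gene_universe <- unique(unlist(lapply(studies,
                                          function(s) rownames(s$values))))
  if (!length(gene_universe)) stop("gene_universe must be non-empty")
  blocks <- lapply(studies, function(s) {
    out <- matrix(0, length(gene_universe), ncol(s$values),
                  dimnames = list(gene_universe,
                                  paste(s$study_id, colnames(s$values),
                                        sep = "|")))
    shared <- intersect(gene_universe, rownames(s$values))
    out[shared, ] <- s$values[shared, , drop = FALSE]
    out
  })
  values <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(values)))
    stop("duplicate namespaced cell ids after merge")
  ann <- data.frame(
    cell_id = unlist(lapply(studies, function(s) colnames(s$values))),
    study_id = rep(ids, vapply(studies, function(s) ncol(s$values), 0L)),
    cell_type = NA_character_,
    stringsAsFactors = FALSE)
  rownames(ann) <- colnames(values)
  if (!is.null(metadata)) {
    key <- paste(metadata$study_id, metadata$cell_id, sep = "|")
    hit <- match(rownames(ann), key)
    ann$cell_type <- ifelse(is.na(hit), NA_character_,
                            metadata$cell_type[hit])
    ann$cell_type[!is.na(ann$cell_type) & !nzchar(ann$cell_type)] <-
      NA_character_
  }
  structure(list(values = values, annotations = ann),
            class = "merged_experiment")
}

#' @export
print.merged_experiment <- function(x, ...) {
  ann <- x$annotations
  cat(sprintf("<merged_experiment> %d genes x %d cells from %d studies\n",
              nrow(x$values), ncol(x$values), length(unique(ann$study_id))))
  cat(" labeled cells:", sum(!is.na(ann$cell_type)), "of", nrow(ann), "\n")
  invisible(x)
}

#' Remove low-coverage cells
#'
#' Drops cells expressing strictly fewer than `min_genes` genes with
#' expression > 0, evaluated on the stored (untransformed) values.
#'
#' @param merged A `merged_experiment`.
#' @param min_genes Minimum number of detected genes to retain a cell
#'   (default 1000).
#' @return A filtered `merged_experiment`.
#' @export
filter_low_coverage_cells <- function(merged, min_genes = 1000L) {
  stopifnot(min_genes >= 0)
  detected <- colSums(merged$values > 0)
  keep <- detected >= min_genes
  if (!any(keep)) {
    per_study <- tapply(keep, merged$annotations$study_id, sum)
    stop("no cell expresses >= ", min_genes, " genes; survivors per study: ",
         paste(names(per_study), per_study, sep = "=", collapse = ", "))
  }
  structure(list(values = merged$values[, keep, drop = FALSE],
                 annotations = merged$annotations[keep, , drop = FALSE]),
            class = "merged_experiment")
}

#' Export a merged experiment as dense TSV plus metadata TSV
#'
#' @param merged A `merged_experiment`.
#' @param expression_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_merged_experiment <- function(merged, expression_path, metadata_path) {
  tab <- data.frame(gene_id = rownames(merged$values), merged$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- merged$annotations
  ann$cell_type[is.na(ann$cell_type)] <- ""
  utils::write.table(ann, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression_path, metadata_path))
}
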