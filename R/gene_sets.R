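#' Gene-set collections
#'
#' A named list of character gene-id vectors with a provenance tag
#' (`go_slim`, `random`, `cv_centile`, `hvg`, or `user`) and an optional
#' per-set description carried through to GMT output.
#'
#' @param sets Named list of character vectors; names unique, sets non-empty.
#' @param provenance One of the provenance tags above.
#' @param description Optional named character vector of set descriptions.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, provenance = "user",
                                description = NULL) {
  stopifnot(is.list(sets))
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
        any(!nzchar(names(sets))))
      stop("gene sets must carry unique non-empty names")
    if (any(!lengths(sets))) stop("gene sets must be non-empty")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(description)) {
    description <- rep(provenance, length(sets))
    names(description) <- names(sets)
  }
  structure(list(sets = sets, provenance = provenance,
                 description = description),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d set(s), provenance '%s'",
              length(x$sets), x$provenance))
  if (length(x$sets))
    cat(sprintf("; sizes %d-%d", min(lengths(x$sets)), max(lengths(x$sets))))
  cat("\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

# Accept a collection, a named list, or a single character vector anywhere a
# gene-set argument is taken.
as_gene_set_list <- function(gene_sets) {
  if (inherits(gene_sets, "gene_set_collection")) return(gene_sets$sets)
  if (is.character(gene_sets)) return(list(gene_set = unique(gene_sets)))
  if (is.list(gene_sets)) {
    if (is.null(names(gene_sets)))
      names(gene_sets) <- paste0("set_", seq_along(gene_sets))
    return(lapply(gene_sets, function(g) unique(as.character(g))))
  }
  stop("cannot interpret 'gene_sets' as a gene-set collection")
}

#' Parse a GMT gene-set file
#'
#' Tab-delimited, one set per line: name, description, member genes.
#' Duplicate genes within a line are dropped.
#'
#' @param path Path to the GMT file.
#' @param provenance Provenance tag for the collection (default `"user"`).
#' @return A [gene_set_collection()].
#' @export
parse_gmt <- function(path, provenance = "user") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection(list(), provenance))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 tab-separated fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  descr <- vapply(fields, `[[`, "", 2L)
  names(descr) <- names(sets)
  gene_set_collection(sets, provenance, descr)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets by size within a measured universe
#'
#' Each set is first intersected with `universe`, then retained iff its
#' remaining size is within `[min, max]` inclusive (defaults 20-1000, the
#' usual bounds for functional gene-set screens).
#'
#' @param sets A [gene_set_collection()].
#' @param universe Character vector of measured gene ids.
#' @param min,max Inclusive size bounds.
#' @return A filtered [gene_set_collection()] with intersected membership.
#' @export
filter_by_size <- function(sets, universe, min = 20L, max = 1000L) {
  stopifnot(min <= max)
  cut <- lapply(sets$sets, intersect, y = universe)
  keep <- lengths(cut) >= min & lengths(cut) <= max
  gene_set_collection(cut[keep], sets$provenance,
                      sets$description[names(cut)[keep]])
}

#' Random gene sets with a matched size distribution
#'
#' Draws `n_sets` sets of genes uniformly without replacement from `universe`,
#' with set sizes sampled from `template_sizes` — used as size-matched
#' controls for functional collections.
#'
#' @param template_sizes Integer vector of template set sizes.
#' @param universe Gene ids to draw from.
#' @param n_sets Number of sets to generate.
#' @param seed Integer seed; the same seed reproduces the same collection.
#' @return A [gene_set_collection()] with provenance `"random"`.
#' @export
random_sets_matched <- function(template_sizes, universe, n_sets, seed) {
  template_sizes <- as.integer(template_sizes)
  if (max(template_sizes) > length(universe))
    stop("largest template size (", max(template_sizes),
         ") exceeds universe size (", length(universe), ")")
  set.seed(seed)
  sizes <- sample(template_sizes, n_sets, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(universe, k))
  names(sets) <- sprintf("random_%04d", seq_len(n_sets))
  gene_set_collection(sets, "random")
}

#' Coefficient-of-variation centile gene sets
#'
#' Per study, each shared gene's coefficient of variation (sd/mean over
#' cells) is computed and ranked; ranks are averaged across studies and the
#' averaged ranking is partitioned into `n_bins` equal-size bins, low to high
#' CV, one gene set per bin. Genes with zero mean in any study are excluded
#' (their CV is undefined there). The top bin is flagged in its description:
#' the most variable centile tends to track technical noise and is typically
#' uninformative for cell identity.
#'
#' @param studies List of [expression_study()] objects.
#' @param n_bins Number of centile bins (default 100).
#' @return A [gene_set_collection()] with provenance `"cv_centile"`, sets
#'   named `cv_bin_001` (lowest CV) upward.
#' @export
cv_centile_sets <- function(studies, n_bins = 100L) {
  stopifnot(length(studies) >= 1L)
  shared <- Reduce(intersect, lapply(studies, function(s) rownames(s$values)))
  rank_mat <- sapply(studies, function(s) {
    x <- s$values[shared, , drop = FALSE]
    mu <- rowMeans(x)
    cv <- ifelse(mu > 0, apply(x, 1L, stats::sd) / mu, NA_real_)
    rank(cv, na.last = "keep")
  })
  ok <- stats::complete.cases(rank_mat)
  shared <- shared[ok]
  if (length(shared) < n_bins)
    stop("only ", length(shared), " shared genes with defined CV; need >= ",
         n_bins)
  avg <- rowMeans(rank_mat[ok, , drop = FALSE])
  ord <- order(avg, shared)                      # ties broken by gene id
  bin <- ceiling(seq_along(ord) * n_bins / length(ord))
  sets <- split(shared[ord], bin)
  names(sets) <- sprintf("cv_bin_%03d", seq_len(n_bins))
  descr <- rep("cv_centile", n_bins)
  descr[n_bins] <- "cv_centile top bin (typically uninformative)"
  names(descr) <- names(sets)
  gene_set_collection(sets, "cv_centile", descr)
}

#' Highly variable genes by expression-decile binning
#'
#' Per study, genes are split into `n_expr_bins` equal-count bins by mean
#' expression; within every bin except the most highly expressed one, the
#' `ceiling(top_fraction * bin size)` genes with the largest variability are
#' taken, and the per-study lists are the union over bins. Study lists are
#' combined by intersection (default) or by majority rule (kept if present in
#' strictly more than half of the studies) — the latter is the practicable
#' fallback when many studies make the intersection too stringent.
#'
#' @param studies List of [expression_study()] objects.
#' @param combine `"intersect"` or `"majority"`.
#' @param n_expr_bins Number of expression bins (default 10, i.e. deciles).
#' @param top_fraction Fraction of each bin taken as variable (default 0.25).
#' @param statistic Variability measure within bins: `"variance"` (default;
#'   binning by expression already controls the mean-variance trend) or
#'   `"cv"`.
#' @return Character vector of highly variable gene ids.
#' @export
select_hvg <- function(studies, combine = c("intersect", "majority"),
                       n_expr_bins = 10L, top_fraction = 0.25,
                       statistic = c("variance", "cv")) {
  combine <- match.arg(combine)
  statistic <- match.arg(statistic)
  stopifnot(length(studies) >= 1L, top_fraction > 0, top_fraction <= 1)
  per_study <- lapply(studies, function(s) {
    x <- s$values
    mu <- rowMeans(x)
    v <- apply(x, 1L, stats::var)
    stat <- if (statistic == "variance") v else ifelse(mu > 0, sqrt(v) / mu, 0)
    ord <- order(mu, rownames(x))                # ties broken by gene id
    bin <- ceiling(seq_along(ord) * n_expr_bins / length(ord))
    keep <- character(0)
    for (b in seq_len(n_expr_bins - 1L)) {       # drop the top-expression bin
      idx <- ord[bin == b]
      if (!length(idx)) next
      k <- ceiling(top_fraction * length(idx))
      top <- idx[order(-stat[idx], rownames(x)[idx])][seq_len(k)]
      keep <- c(keep, rownames(x)[top])
    }
    keep
  })
  hvg <- if (combine == "intersect") {
    Reduce(intersect, per_study)
  } else {
    counts <- table(unlist(lapply(per_study, unique)))
    names(counts)[counts > length(studies) / 2]
  }
  if (!length(hvg))
    stop("combined highly variable set is empty",
         if (combine == "intersect")
           "; consider combine = 'majority'" else "")
  sort(hvg)
}
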