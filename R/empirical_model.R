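round_half_up <- function(x) floor(x + 0.5)

#' Subsample cells to a target incidence
#'
#' Draws `round(r * n)` positives and `n - round(r * n)` negatives uniformly
#' without replacement, plus one held-out negative per positive, disjoint
#' from the selected cells. The held-out negatives later act as donors when
#' transcriptional subtlety is injected, so strict partitioning matters:
#' donor profiles must not also appear in the analyzed data.
#'
#' @param positives,negatives Character vectors of candidate cell ids.
#' @param r Target incidence of the positive type, in (0, 1].
#' @param n Total number of analyzed cells to select.
#' @param seed Integer seed.
#' @return List with `pos`, `neg` (selected cells) and `held_out`
#'   (donor negatives, same length as `pos`).
#' @export
subsample_incidence <- function(positives, negatives, r, n, seed) {
  stopifnot(r > 0, r <= 1, n >= 1)
  n_pos <- round_half_up(r * n)
  if (n_pos < 1) stop("r * n must be >= 1 (got ", r * n, ")")
  n_neg <- n - n_pos
  if (length(positives) < n_pos)
    stop("need ", n_pos, " positives, pool has ", length(positives))
  if (length(negatives) < n_neg + n_pos)
    stop("need ", n_neg, " negatives plus ", n_pos,
         " held-out donors, pool has ", length(negatives))
  set.seed(seed)
  pos <- positives[sample.int(length(positives), n_pos)]
  neg_all <- negatives[sample.int(length(negatives), n_neg + n_pos)]
  list(pos = pos, neg = neg_all[seq_len(n_neg)],
       held_out = neg_all[n_neg + seq_len(n_pos)])
}

#' Inject transcriptional subtlety into positive cells
#'
#' A single gene subset of size `round(s * n_genes)` is drawn (or supplied)
#' and applied to every positive: for those genes, each positive's values are
#' replaced by the values of its paired held-out negative donor. Each
#' modified cell is thus the discrete combination of two real cells, sampled
#' without replacement — at `s = 1` positives become exact copies of
#' donors and discrimination collapses to chance.
#'
#' @param values Genes x cells expression matrix containing both the
#'   positives and the donors.
#' @param positives Cell ids to modify (columns of `values`).
#' @param held_out Donor cell ids, paired with `positives` by position.
#' @param s Subtlety: fraction of the transcriptome swapped, in [0, 1].
#' @param seed Integer seed for drawing the gene subset (ignored when
#'   `gene_mask` is given).
#' @param gene_mask Optional integer vector of gene rows to swap; lets one
#'   mask be shared across datasets within a replicate.
#' @return List with `values` (modified matrix) and `gene_mask`.
#' @export
inject_subtlety <- function(values, positives, held_out, s, seed = NULL,
                            gene_mask = NULL) {
  stopifnot(s >= 0, s <= 1, length(positives) == length(held_out))
  if (is.null(gene_mask)) {
    n_swap <- round_half_up(s * nrow(values))
    if (!is.null(seed)) set.seed(seed)
    gene_mask <- sort(sample.int(nrow(values), n_swap))
  }
  if (length(gene_mask))
    values[gene_mask, positives] <- values[gene_mask, held_out]
  list(values = values, gene_mask = gene_mask)
}

#' Empirical model of cell-type rarity and subtlety
#'
#' Sweeps a grid of incidence (`r`) and subtlety (`s`) values. Per replicate
#' and dataset, cells are subsampled to the target incidence with donor
#' negatives held out, the same gene subset (drawn once per replicate from
#' the full universe and shared across datasets) is swapped from donors into
#' positives, datasets are merged, and cross-dataset neighbor voting scores
#' the positive type. Reported is the mean and SD of the positive type's
#' fold-mean AUROC over replicates.
#'
#' @param studies List of [expression_study()] objects (>= 2).
#' @param metadata Annotation data.frame labeling each cell as the positive
#'   type or not (columns cell_id, study_id, cell_type).
#' @param positive_type The cell-type label treated as the minority class.
#' @param r_grid,s_grid Numeric vectors of incidences and subtleties.
#' @param n_per_dataset Number of analyzed cells per dataset per replicate.
#' @param n_reps Replicates per grid point (default 100).
#' @param gene_set Character vector used for scoring when
#'   `gene_set_mode = "fixed"`.
#' @param gene_set_mode `"fixed"` (use `gene_set`), `"hvg_static"` (highly
#'   variable genes computed once on the full input studies) or
#'   `"hvg_varying"` (recomputed on each replicate's subsampled, modified
#'   data).
#' @param hvg_combine Combine rule for the HVG modes.
#' @param seed Master seed; replicate seeds are derived by a counter so any
#'   single replicate is reproducible in isolation.
#' @return Object of class `empirical_model`: list with `results` (long
#'   data.frame: r, s, rep, auroc) and `summary` (per grid point mean, sd,
#'   n).
#' @export
run_empirical_model <- function(studies, metadata, positive_type,
                                r_grid, s_grid, n_per_dataset,
                                n_reps = 100L,
                                gene_set = NULL,
                                gene_set_mode = c("fixed", "hvg_static",
                                                  "hvg_varying"),
                                hvg_combine = "intersect",
                                seed = 1L) {
  gene_set_mode <- match.arg(gene_set_mode)
  if (length(studies) < 2L)
    stop("the empirical model needs >= 2 datasets for cross-validation")
  if (gene_set_mode == "fixed" && is.null(gene_set))
    stop("gene_set must be supplied when gene_set_mode = 'fixed'")
  if (gene_set_mode == "hvg_static")
    gene_set <- select_hvg(studies, combine = hvg_combine)
  universe <- rownames(studies[[1L]]$values)

  grid <- expand.grid(r = r_grid, s = s_grid, KEEP.OUT.ATTRS = FALSE)
  res <- list()
  counter <- 0L
  for (g in seq_len(nrow(grid))) {
    r <- grid$r[g]; s <- grid$s[g]
    for (rep_i in seq_len(n_reps)) {
      counter <- counter + 1L
      rep_seed <- (seed + 7919L * counter) %% .Machine$integer.max
      set.seed(rep_seed)
      n_swap <- round_half_up(s * length(universe))
      gene_mask <- sort(sample.int(length(universe), n_swap))
      mod_studies <- vector("list", length(studies))
      meta_rows <- list()
      for (d in seq_along(studies)) {
        st <- studies[[d]]
        md <- metadata[metadata$study_id == st$study_id, ]
        pos_pool <- md$cell_id[!is.na(md$cell_type) &
                                 md$cell_type == positive_type]
        neg_pool <- md$cell_id[!is.na(md$cell_type) &
                                 md$cell_type != positive_type]
        sel <- subsample_incidence(pos_pool, neg_pool, r, n_per_dataset,
                                   seed = rep_seed + d)
        stopifnot(!any(sel$held_out %in% c(sel$pos, sel$neg)))
        inj <- inject_subtlety(st$values, sel$pos, sel$held_out, s,
                               gene_mask = gene_mask)
        keep <- c(sel$pos, sel$neg)
        mod_studies[[d]] <- expression_study(st$study_id,
                                             inj$values[, keep,
                                                        drop = FALSE])
        meta_rows[[d]] <- data.frame(
          cell_id = keep, study_id = st$study_id,
          cell_type = c(rep(positive_type, length(sel$pos)),
                        rep("negative_class", length(sel$neg))),
          stringsAsFactors = FALSE)
      }
      md_all <- do.call(rbind, meta_rows)
      merged <- merge_on_gene_universe(mod_studies, universe,
                                       metadata = md_all)
      gs <- if (gene_set_mode == "hvg_varying")
        select_hvg(mod_studies, combine = hvg_combine) else gene_set
      rep_out <- run_metaneighbor(merged, list(model_set = gs),
                                  cell_types = positive_type)
      res[[counter]] <- data.frame(r = r, s = s, rep = rep_i,
                                   auroc = rep_out$scores[1L, positive_type])
    }
  }
  results <- do.call(rbind, res)
  agg <- stats::aggregate(auroc ~ r + s, data = results,
                          FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                              sd = stats::sd(v, na.rm = TRUE),
                                              n = sum(!is.na(v))))
  summary_df <- data.frame(r = agg$r, s = agg$s,
                           mean_auroc = agg$auroc[, "mean"],
                           sd_auroc = agg$auroc[, "sd"],
                           n = agg$auroc[, "n"])
  structure(list(results = results, summary = summary_df,
                 positive_type = positive_type, n_reps = n_reps,
                 gene_set_mode = gene_set_mode, seed = seed),
            class = "empirical_model")
}

#' @export
print.empirical_model <- function(x, ...) {
  cat(sprintf(
    "<empirical_model> positive type '%s', %d replicates per grid point\n",
    x$positive_type, x$n_reps))
  print(transform(x$summary, mean_auroc = round(mean_auroc, 3),
                  sd_auroc = round(sd_auroc, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.empirical_model <- function(x, ...) {
  s <- x$summary
  rs <- sort(unique(s$r))
  cols <- grDevices::hcl.colors(max(2L, length(rs)), "Dark 3")
  graphics::plot(NULL, xlim = range(s$s), ylim = c(0.4, 1),
                 xlab = "subtlety (fraction of transcriptome swapped)",
                 ylab = "mean AUROC", ...)
  for (i in seq_along(rs)) {
    sub <- s[s$r == rs[i], ]
    sub <- sub[order(sub$s), ]
    graphics::lines(sub$s, sub$mean_auroc, col = cols[i], type = "b",
                    pch = 16)
  }
  graphics::abline(h = 0.5, lty = 2, col = "grey40")
  graphics::legend("bottomleft", legend = paste0("incidence ", rs),
                   col = cols[seq_along(rs)], lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Export empirical-model results as TSV
#'
#' @param model An `empirical_model`.
#' @param long_path,summary_path Output paths; either may be `NULL`.
#' @return Invisibly, the written paths.
#' @export
write_empirical_model <- function(model, long_path = NULL,
                                  summary_path = NULL) {
  if (!is.null(long_path))
    utils::write.table(model$results, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.table(model$summary, summary_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(c(long_path, summary_path))
}
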