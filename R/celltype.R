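#' Single-cell quality-control filter
#'
#' Applies the fixed QC order used for droplet single-cell data: first
#' cells with library size below 2500 UMIs are removed, then cells whose
#' mitochondrial transcript ratio exceeds 0.5, and only then genes
#' detected (UMI > 0) in fewer than three of the remaining cells.
#'
#' @param counts integer matrix, genes in rows, cells in columns.
#' @param mito_genes character vector of mitochondrial gene ids, or a
#'   regular expression prefix such as `"^mt-"` when `mito_prefix = TRUE`.
#' @param min_library minimum cell library size kept (default 2500; cells
#'   strictly below are removed).
#' @param max_mito_ratio maximum mitochondrial ratio kept (default 0.5;
#'   cells strictly above are removed).
#' @param min_cells minimum number of expressing cells for a gene to be
#'   kept (default 3).
#' @param mito_prefix treat `mito_genes` as a regex on row names.
#' @return the filtered matrix, with attributes `removed_cells` and
#'   `removed_genes`.
#' @export
cell_qc_filter <- function(counts, mito_genes, min_library = 2500,
                           max_mito_ratio = 0.5, min_cells = 3L,
                           mito_prefix = FALSE) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (mito_prefix) mito_genes <- grep(mito_genes, rownames(counts),
                                      value = TRUE)
  lib <- colSums(counts)
  mito <- if (length(mito_genes)) {
    colSums(counts[rownames(counts) %in% mito_genes, , drop = FALSE]) /
      pmax(lib, 1)
  } else rep(0, ncol(counts))
  keep_cells <- lib >= min_library & mito <= max_mito_ratio
  if (!any(keep_cells)) stop("all cells removed by QC")
  out <- counts[, keep_cells, drop = FALSE]
  detected <- rowSums(out > 0)
  keep_genes <- detected >= min_cells
  res <- out[keep_genes, , drop = FALSE]
  attr(res, "removed_cells") <- colnames(counts)[!keep_cells]
  attr(res, "removed_genes") <- rownames(counts)[!keep_genes]
  res
}

#' Cluster marker statistics (cluster vs all other cells)
#'
#' For each gene and cluster: mean log-normalized expression in the
#' cluster, log2 fold change versus all other cells with an epsilon guard
#' for zero means, and a two-sided Wilcoxon rank-sum p-value.
#'
#' @param matrix numeric matrix (genes x cells), typically log-normalized.
#' @param labels vector of cluster labels, one per cell.
#' @param eps regularizer added to both means in the fold change
#'   (default 1e-9).
#' @return data.frame with `gene_id`, `cluster_id`, `avg_expr`, `log2fc`,
#'   `p`; singleton clusters are skipped with a warning.
#' @export
marker_stats <- function(matrix, labels, eps = 1e-9) {
  stopifnot(ncol(matrix) == length(labels))
  labels <- as.character(labels)
  clusters <- unique(labels)
  if (length(clusters) < 2L) stop("need at least two clusters")
  small <- clusters[vapply(clusters, function(cl) sum(labels == cl) < 3L,
                           logical(1))]
  if (length(small)) {
    warning("skipping cluster(s) with < 3 cells: ",
            paste(small, collapse = ", "))
    clusters <- setdiff(clusters, small)
  }
  rows <- lapply(clusters, function(cl) {
    inc <- labels == cl
    mean_in <- rowMeans(matrix[, inc, drop = FALSE])
    mean_out <- rowMeans(matrix[, !inc, drop = FALSE])
    p <- vapply(seq_len(nrow(matrix)), function(i) {
      xi <- matrix[i, inc]; yi <- matrix[i, !inc]
      if (length(unique(c(xi, yi))) == 1L) return(1)
      suppressWarnings(stats::wilcox.test(xi, yi)$p.value)
    }, numeric(1))
    data.frame(
      gene_id = rownames(matrix), cluster_id = cl,
      avg_expr = mean_in,
      log2fc = log2((mean_in + eps) / (mean_out + eps)),
      p = p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign network genes to cell types from marker statistics
#'
#' Primary rule: a gene belongs to the cluster(s) where its cluster-vs-rest
#' fold change exceeds `fc_min` and p-value is below `alpha`; among several
#' qualifying clusters the one with the highest average expression wins.
#' Fallback (when no cluster qualifies): the cluster with strictly maximal
#' average expression; exact ties leave the gene unassigned.
#'
#' @param network_genes character vector of gene ids to assign.
#' @param markers marker table ([marker_stats()] or
#'   [simulate_marker_table()]).
#' @param fc_min log2 fold-change threshold (default 0.25, strict).
#' @param alpha p-value threshold (default 0.05, strict).
#' @param fallback_requires_fc if `TRUE`, the fallback cluster must also
#'   pass the fold-change/p rule (default `FALSE`).
#' @return data.frame with `gene_id`, `cell_type` (`NA` when unassigned),
#'   `rule` (`primary_fc_p`, `fallback_max_avg`, or `unassigned`).
#' @export
assign_cell_types <- function(network_genes, markers, fc_min = 0.25,
                              alpha = 0.05, fallback_requires_fc = FALSE) {
  out <- data.frame(gene_id = network_genes, cell_type = NA_character_,
                    rule = "unassigned", stringsAsFactors = FALSE)
  for (k in seq_along(network_genes)) {
    mk <- markers[markers$gene_id == network_genes[k], , drop = FALSE]
    if (!nrow(mk)) next
    qual <- mk$log2fc > fc_min & mk$p < alpha
    if (any(qual)) {
      cand <- mk[qual, , drop = FALSE]
      out$cell_type[k] <- cand$cluster_id[which.max(cand$avg_expr)]
      out$rule[k] <- "primary_fc_p"
    } else {
      if (fallback_requires_fc) next
      mx <- max(mk$avg_expr)
      top <- mk$cluster_id[mk$avg_expr == mx]
      if (length(top) == 1L) {
        out$cell_type[k] <- top
        out$rule[k] <- "fallback_max_avg"
      }
    }
  }
  out
}

#' Enrichment of a gene subset in a cell type
#'
#' Two-by-two Fisher's exact test of membership in a gene subset against
#' assignment to a cell type (default: the myeloid cluster), over the
#' assignment universe.
#'
#' @param assignments data.frame from [assign_cell_types()].
#' @param gene_subset character vector of genes (e.g. treatment-improved,
#'   microbiota-dependent genes).
#' @param cell_type cluster label tested for enrichment.
#' @param alternative passed to [stats::fisher.test()] (default
#'   two-sided).
#' @return list with `p`, `odds_ratio`, `table` (the 2x2 table).
#' @export
myeloid_enrichment <- function(assignments, gene_subset,
                               cell_type = "myeloid",
                               alternative = "two.sided") {
  in_subset <- assignments$gene_id %in% gene_subset
  is_type <- !is.na(assignments$cell_type) &
    assignments$cell_type == cell_type
  tab <- table(factor(in_subset, c(TRUE, FALSE)),
               factor(is_type, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin; enrichment p set to 1")
    return(list(p = 1, odds_ratio = NA_real_, table = tab))
  }
  ft <- stats::fisher.test(tab, alternative = alternative)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}
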