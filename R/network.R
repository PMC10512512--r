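#' Per-group Spearman correlations for all feature pairs
#'
#' Computes Spearman's rho and a two-sided p-value for every unordered
#' feature pair within each study group separately. The p-value uses the
#' t approximation `t = r * sqrt((n-2)/(1-r^2))` on the rank correlation,
#' which handles ties naturally. Pairs involving a constant vector in some
#' group get `NA` for that group and retain the remaining groups.
#'
#' @param table a normalized [omics_table()] restricted to the
#'   network-eligible features.
#' @param min_n minimum samples per group (default 4).
#' @return data.frame with columns `node_i`, `node_j` and, per group `g`,
#'   `rho.<g>`, `p.<g>`, `n.<g>`.
#' @export
spearman_per_group <- function(table, min_n = 4L) {
  stopifnot(inherits(table, "omics_table"))
  m <- table$matrix
  if (nrow(m) < 2L) stop("need at least two features")
  groups <- unique(table$sample_meta$group)
  ut <- which(upper.tri(diag(nrow(m))), arr.ind = TRUE)
  out <- data.frame(
    node_i = rownames(m)[ut[, 1]],
    node_j = rownames(m)[ut[, 2]],
    stringsAsFactors = FALSE
  )
  for (g in groups) {
    sel <- table$sample_meta$group == g
    n <- sum(sel)
    if (n < min_n) stop("group ", g, " has fewer than ", min_n, " samples")
    rk <- t(apply(m[, sel, drop = FALSE], 1, rank))
    sds <- apply(rk, 1, stats::sd)
    rk[sds == 0, ] <- NA  # constant in this group: rho undefined
    if (any(sds == 0))
      warning(sum(sds == 0), " feature(s) constant in group ", g)
    cm <- suppressWarnings(stats::cor(t(rk)))
    r <- cm[ut]
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    out[[paste0("rho.", g)]] <- r
    out[[paste0("p.", g)]] <- pmin(p, 1)
    out[[paste0("n.", g)]] <- ifelse(is.na(r), NA_integer_, n)
  }
  out
}

#' Fisher-z fixed-effect meta-analysis of correlations
#'
#' Pools per-group Spearman correlations on the z scale
#' (`z = atanh(rho)`, variance `1/(n-3)`) with inverse-variance weights,
#' and tests the pooled z against zero (two-sided normal test). With one
#' group this reduces to the single-group `z * sqrt(n-3)` test.
#'
#' @param rho matrix (edges x groups) or vector of correlations; `NA`
#'   entries (undefined groups) are skipped.
#' @param n matching matrix/vector of per-group sample sizes.
#' @return data.frame with `combined_z` (pooled z), `combined_r`
#'   (back-transformed), `z_stat`, `combined_p`, `sign`.
#' @export
fisher_z_meta <- function(rho, n) {
  if (is.null(dim(rho))) { rho <- rbind(rho); n <- rbind(n) }
  rho <- pmin(pmax(rho, -(1 - 1e-6)), 1 - 1e-6)  # |rho| = 1 -> atanh finite
  z <- atanh(rho)
  w <- n - 3
  w[is.na(z)] <- NA
  sw <- rowSums(w, na.rm = TRUE)
  if (any(sw <= 0)) stop("need at least one group with n >= 4 and defined rho")
  pooled <- rowSums(w * z, na.rm = TRUE) / sw
  stat <- pooled * sqrt(sw)
  p <- 2 * stats::pnorm(-abs(stat))
  data.frame(
    combined_z = pooled,
    combined_r = tanh(pooled),
    z_stat = stat,
    combined_p = pmin(p, 1),
    sign = sign(pooled)
  )
}

# internal: data-type pair class label for an edge, e.g. "asv|gene_adipose".
# genes carry their tissue so per-tissue thresholds are possible.
.node_class <- function(feature_meta) {
  ifelse(feature_meta$data_type == "gene",
         paste0("gene_", feature_meta$tissue),
         feature_meta$data_type)
}

.pair_class <- function(class_i, class_j) {
  paste(pmin(class_i, class_j), pmax(class_i, class_j), sep = "|")
}

#' Full edge statistics table
#'
#' Runs [spearman_per_group()] and [fisher_z_meta()] and annotates each
#' pair with its data-type pair class and a BH FDR computed separately
#' within each pair class (micro-micro, micro-gene, gene-phenotype, ...).
#'
#' @inheritParams spearman_per_group
#' @return data.frame of per-edge statistics (`node_i`, `node_j`,
#'   per-group `rho.*`/`p.*`/`n.*`, `combined_z`, `combined_r`,
#'   `combined_p`, `sign`, `pair_class`, `fdr`).
#' @export
edge_stats <- function(table, min_n = 4L) {
  st <- spearman_per_group(table, min_n = min_n)
  rho <- as.matrix(st[, grep("^rho\\.", names(st)), drop = FALSE])
  n <- as.matrix(st[, grep("^n\\.", names(st)), drop = FALSE])
  meta <- fisher_z_meta(rho, n)
  st <- cbind(st, meta)
  cls <- .node_class(table$feature_meta)
  names(cls) <- table$feature_meta$feature_id
  st$pair_class <- .pair_class(cls[st$node_i], cls[st$node_j])
  st$fdr <- bh_fdr(st$combined_p, st$pair_class)
  st
}

#' Filter edges on per-group and combined p-values and sign consistency
#'
#' An edge is kept iff (i) every defined per-group p-value is at most
#' `p_individual_max`, (ii) its combined p-value is at most the threshold
#' for its data-type pair class (`p_combined`, or `p_relaxed` for the
#' classes in `relaxed_pairs`), (iii) its FDR (within pair class) is at
#' most `fdr_max` when given, and (iv) all defined per-group correlations
#' share one sign. Failures are labeled `removed_p` or
#' `removed_sign_inconsistent`.
#'
#' @param stats edge table from [edge_stats()].
#' @param p_individual_max maximum allowed per-group p (default 0.5).
#' @param p_combined combined-p threshold (default 0.05).
#' @param relaxed_pairs character vector of pair classes that get the
#'   relaxed threshold; defaults to the bile acid-adipose, bile acid-liver
#'   and microbiota-ileum pairs.
#' @param p_relaxed threshold for relaxed pairs (default 0.1).
#' @param fdr_max optional FDR threshold within pair class.
#' @param within_omic_factor multiplier (< 1 tightens) applied to
#'   `p_combined` and `fdr_max` for within-omic pair classes (same data
#'   type and tissue); default 1 (no extra stringency).
#' @return `stats` with a `status` column (`kept` / `removed_p` /
#'   `removed_sign_inconsistent`).
#' @export
filter_edges <- function(stats, p_individual_max = 0.5, p_combined = 0.05,
                         relaxed_pairs = default_relaxed_pairs(),
                         p_relaxed = 0.1, fdr_max = NULL,
                         within_omic_factor = 1) {
  pmat <- as.matrix(stats[, grep("^p\\.", names(stats)), drop = FALSE])
  rmat <- as.matrix(stats[, grep("^rho\\.", names(stats)), drop = FALSE])
  max_p_ok <- apply(pmat, 1, function(p) all(p[!is.na(p)] <= p_individual_max))
  halves <- strsplit(stats$pair_class, "|", fixed = TRUE)
  within <- vapply(halves, function(h) h[1] == h[2], logical(1))
  thr <- ifelse(stats$pair_class %in% relaxed_pairs, p_relaxed, p_combined)
  thr[within] <- thr[within] * within_omic_factor
  comb_ok <- stats$combined_p <= thr
  if (!is.null(fdr_max)) {
    fthr <- rep(fdr_max, nrow(stats))
    fthr[within] <- fthr[within] * within_omic_factor
    comb_ok <- comb_ok & stats$fdr <= fthr
  }
  sign_ok <- apply(rmat, 1, function(r) {
    r <- r[!is.na(r) & r != 0]
    length(r) == 0L || all(r > 0) || all(r < 0)
  })
  stats$status <- ifelse(!sign_ok, "removed_sign_inconsistent",
                  ifelse(!max_p_ok | !comb_ok, "removed_p", "kept"))
  stats
}

#' Default relaxed data-type pair classes
#'
#' The pair classes whose combined-p threshold is relaxed to 0.1:
#' bile acids vs adipose genes, bile acids vs liver genes, and microbiota
#' (ASVs) vs ileum genes.
#' @return character vector of pair-class labels.
#' @export
default_relaxed_pairs <- function() {
  c(.pair_class("bile_acid", "gene_adipose"),
    .pair_class("bile_acid", "gene_liver"),
    .pair_class("asv", "gene_ileum"))
}

#' Remove unexpected correlations
#'
#' An edge's expected sign is the product of its two nodes' disease-vs-
#' control fold-change signs; edges whose observed correlation sign
#' contradicts it violate the correlation inequalities and are removed.
#' Edges touching a node with direction 0 are exempt and flagged.
#'
#' @param edges edge table with a `status` column ([filter_edges()]).
#' @param disease_signs named vector (feature_id -> -1/0/+1) of disease
#'   fold-change signs.
#' @return list: `edges` (with `expected_sign` and updated `status`:
#'   mismatches among kept edges become `removed_unexpected`) and `puc`,
#'   the proportion of unexpected correlations among previously-kept edges.
#' @export
prune_unexpected <- function(edges, disease_signs) {
  si <- disease_signs[edges$node_i]
  sj <- disease_signs[edges$node_j]
  if (anyNA(si) || anyNA(sj))
    stop("disease_signs missing for some edge nodes")
  expected <- unname(si * sj)
  edges$expected_sign <- ifelse(expected == 0, NA_real_, expected)
  exempt <- expected == 0
  kept <- edges$status == "kept"
  unexpected <- kept & !exempt & edges$sign != expected
  edges$status[unexpected] <- "removed_unexpected"
  denom <- sum(kept)
  list(edges = edges,
       puc = if (denom) sum(unexpected) / denom else NA_real_,
       exempt_edges = sum(kept & exempt))
}

#' Sparsity deviation from the complete graph
#'
#' Compares the observed edge:node ratio to that of the complete graph on
#' the same nodes, `(n-1)/2`:
#' `deviation = |observed - expected| / expected`.
#'
#' @param n_nodes,n_edges network size.
#' @return the deviation statistic (0 for a complete graph, 1 for an empty
#'   edge set).
#' @export
sparsity_deviation <- function(n_nodes, n_edges) {
  if (n_nodes < 2L) stop("need at least 2 nodes")
  expected <- (n_nodes - 1) / 2
  observed <- n_edges / n_nodes
  abs(observed - expected) / expected
}

#' Expected negative:positive sign ratio of the complete graph
#'
#' On a noise-free complete graph obeying the correlation inequalities,
#' every edge's sign is the product of its endpoints' disease fold-change
#' signs; the expected negative:positive ratio follows by pair counting
#' (nodes with direction 0 are excluded).
#'
#' @param disease_signs vector of -1/0/+1 per node.
#' @return list with `n_neg`, `n_pos`, `ratio` (may be `Inf` when no
#'   positive pairs exist, `NaN` when the graph is empty).
#' @export
expected_sign_ratio <- function(disease_signs) {
  s <- disease_signs[disease_signs != 0]
  up <- sum(s > 0); dn <- sum(s < 0)
  n_pos <- choose(up, 2) + choose(dn, 2)
  n_neg <- up * dn
  list(n_neg = n_neg, n_pos = n_pos, ratio = n_neg / n_pos)
}

#' Choose statistical thresholds by the sign-ratio criterion
#'
#' Scans a grid of (FDR, combined-p) thresholds; for each candidate the
#' edges are re-filtered and the kept-edge negative:positive sign ratio is
#' compared to the expected ratio of the noise-free complete graph
#' ([expected_sign_ratio()]). The candidate minimizing the absolute
#' difference wins; ties break toward the more stringent candidate (lower
#' FDR, then lower combined p). Within-omic pair classes are filtered at
#' `within_omic_factor` times the candidate thresholds so they are never
#' less stringent than between-omic classes.
#'
#' @param stats edge table from [edge_stats()].
#' @param disease_signs named vector of disease fold-change signs.
#' @param fdr_grid candidate FDR thresholds (default 0.01, 0.05, 0.1, 0.2).
#' @param p_grid candidate combined-p thresholds (default 0.01, 0.05, 0.1).
#' @param within_omic_factor stringency multiplier for within-omic classes
#'   (default 0.5).
#' @param ... passed to [filter_edges()] (e.g. `p_individual_max`,
#'   `relaxed_pairs`).
#' @return list: `fdr_max`, `p_combined`, `edges` (filtered at the chosen
#'   thresholds), `grid` (per-candidate diagnostics), `quality`
#'   (a `network_quality` list, see [network_quality()]).
#' @export
select_thresholds <- function(stats, disease_signs,
                              fdr_grid = c(0.01, 0.05, 0.1, 0.2),
                              p_grid = c(0.01, 0.05, 0.1),
                              within_omic_factor = 0.5, ...) {
  exp_ratio <- expected_sign_ratio(disease_signs)$ratio
  grid <- expand.grid(fdr_max = sort(fdr_grid), p_combined = sort(p_grid))
  grid$n_kept <- NA_integer_
  grid$obs_ratio <- NA_real_
  grid$dist <- NA_real_
  results <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    f <- filter_edges(stats, p_combined = grid$p_combined[k],
                      fdr_max = grid$fdr_max[k],
                      p_relaxed = min(2 * grid$p_combined[k], 0.5),
                      within_omic_factor = within_omic_factor, ...)
    pr <- prune_unexpected(f, disease_signs)
    kept <- pr$edges[pr$edges$status == "kept", , drop = FALSE]
    n_neg <- sum(kept$sign < 0); n_pos <- sum(kept$sign > 0)
    grid$n_kept[k] <- nrow(kept)
    grid$obs_ratio[k] <- if (n_pos) n_neg / n_pos else Inf
    grid$dist[k] <- if (is.finite(grid$obs_ratio[k]) && is.finite(exp_ratio))
      abs(grid$obs_ratio[k] - exp_ratio) else Inf
    results[[k]] <- pr
  }
  ok <- is.finite(grid$dist)
  if (!any(ok)) stop("no candidate threshold yields a finite sign ratio")
  # minimal distance; ties toward stringency: lower fdr, then lower p
  ord <- order(!ok, grid$dist, grid$fdr_max, grid$p_combined)
  best <- ord[1]
  pr <- results[[best]]
  kept <- pr$edges[pr$edges$status == "kept", , drop = FALSE]
  nodes <- unique(c(kept$node_i, kept$node_j))
  qual <- network_quality(
    n_nodes = length(nodes), n_edges = nrow(kept),
    neg_pos_ratio_observed = grid$obs_ratio[best],
    neg_pos_ratio_expected = exp_ratio, puc = pr$puc
  )
  list(fdr_max = grid$fdr_max[best], p_combined = grid$p_combined[best],
       edges = pr$edges, grid = grid, quality = qual)
}

#' Network quality summary
#'
#' @param n_nodes,n_edges network size.
#' @param neg_pos_ratio_observed,neg_pos_ratio_expected sign ratios.
#' @param puc proportion of unexpected correlations before pruning.
#' @return a `network_quality` list including the sparsity `deviation`.
#' @export
network_quality <- function(n_nodes, n_edges, neg_pos_ratio_observed,
                            neg_pos_ratio_expected, puc) {
  structure(list(
    n_nodes = n_nodes, n_edges = n_edges,
    deviation = if (n_nodes >= 2) sparsity_deviation(n_nodes, n_edges)
                else NA_real_,
    neg_pos_ratio_observed = neg_pos_ratio_observed,
    neg_pos_ratio_expected = neg_pos_ratio_expected,
    puc = puc
  ), class = "network_quality")
}

#' @export
print.network_quality <- function(x, ...) {
  cat(sprintf(
    paste0("network_quality: %d nodes, %d edges\n",
           "  sparsity deviation   %.4f\n",
           "  neg:pos observed     %.4f (expected %.4f)\n",
           "  unexpected fraction  %.4f\n"),
    x$n_nodes, x$n_edges, x$deviation,
    x$neg_pos_ratio_observed, x$neg_pos_ratio_expected, x$puc
  ))
  invisible(x)
}

#' Assemble the transkingdom network graph
#'
#' Builds an undirected igraph object from the kept edges, deduplicating
#' pairs and attaching node attributes (data type, tissue, disease
#' fold-change sign, treatment-effect category) and edge attributes (sign,
#' combined rho/p). Eligible features without any kept edge are reported
#' separately, not included in the graph.
#'
#' @param edges edge table (only rows with `status == "kept"` are used).
#' @param node_attrs data.frame with `feature_id`, `data_type`, `tissue`,
#'   `disease_direction`, `category` (from [classify_treatment_effect()]).
#' @return list: `graph` (igraph), `isolated` (eligible features absent
#'   from the graph), `summary` (node counts per data type x category).
#' @export
assemble_network <- function(edges, node_attrs) {
  kept <- edges[edges$status == "kept", , drop = FALSE]
  if (!nrow(kept))
    stop("no kept edges; consider relaxing thresholds")
  key <- .pair_class(kept$node_i, kept$node_j)
  kept <- kept[!duplicated(key), , drop = FALSE]
  kept <- kept[kept$node_i != kept$node_j, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    kept[, c("node_i", "node_j", "sign", "combined_r", "combined_p")],
    directed = FALSE
  )
  idx <- match(igraph::V(g)$name, node_attrs$feature_id)
  if (anyNA(idx)) stop("edge nodes missing from node_attrs")
  igraph::V(g)$data_type <- node_attrs$data_type[idx]
  igraph::V(g)$tissue <- as.character(node_attrs$tissue[idx])
  igraph::V(g)$disease_direction <- node_attrs$disease_direction[idx]
  igraph::V(g)$category <- node_attrs$category[idx]
  isolated <- setdiff(node_attrs$feature_id, igraph::V(g)$name)
  summ <- as.data.frame(table(
    data_type = igraph::V(g)$data_type,
    category = igraph::V(g)$category
  ))
  list(graph = g, isolated = isolated, summary = summ)
}

#' Export a network to GraphML and SIF
#'
#' @param graph an igraph object (from [assemble_network()]).
#' @param prefix output path prefix; writes `<prefix>.graphml` and
#'   `<prefix>.sif` (tab-separated `node  sign  node` lines).
#' @return the prefix, invisibly.
#' @export
write_network <- function(graph, prefix) {
  igraph::write_graph(graph, paste0(prefix, ".graphml"), format = "graphml")
  el <- igraph::as_edgelist(graph)
  sif <- data.frame(a = el[, 1],
                    rel = ifelse(igraph::E(graph)$sign > 0, "pos", "neg"),
                    b = el[, 2])
  utils::write.table(sif, paste0(prefix, ".sif"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
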