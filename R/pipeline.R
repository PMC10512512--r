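#' Simple two-group differential statistics
#'
#' Per-feature log2 fold change and two-tailed Mann-Whitney p for one
#' comparison (used e.g. for the germ-free vs SPF contrast).
#'
#' @param table a normalized [omics_table()].
#' @param group1,group2 group labels; the fold change is group1 over
#'   group2.
#' @return data.frame with `feature_id`, `log2fc`, `mw_p`, `direction`.
#' @export
two_group_stats <- function(table, group1, group2) {
  stopifnot(inherits(table, "omics_table"))
  m <- table$matrix
  g1 <- table$sample_meta$group == group1
  g2 <- table$sample_meta$group == group2
  if (!any(g1) || !any(g2)) stop("group labels not found")
  log_scale <- table$normalized_state == "log2"
  res <- t(vapply(seq_len(nrow(m)), function(i) {
    x <- m[i, g1]; y <- m[i, g2]
    lfc <- if (log_scale) mean(x) - mean(y)
           else if (mean(x) > 0 && mean(y) > 0) log2(mean(x) / mean(y))
           else sign(mean(x) - mean(y)) * Inf
    c(lfc, mann_whitney(x, y)$p)
  }, numeric(2)))
  data.frame(feature_id = rownames(m), log2fc = res[, 1], mw_p = res[, 2],
             direction = sign(res[, 1]), stringsAsFactors = FALSE)
}

#' Run the full transkingdom analysis pipeline on a synthetic study
#'
#' Executes the stage chain simulate -> normalize -> differential ->
#' treatment-effect classification -> network reconstruction -> BiBC with
#' random-network null -> cell-type assignment -> microbiota-dependence
#' quadrants, writing plain-text artifacts (TSV / JSON / GraphML / SIF)
#' for every stage so each can be rerun standalone. The BiBC stage
#' restricts the node universe to microbiota, adipose-tissue genes and
#' phenotypes, mirroring the reference analysis of causal microbes acting
#' on host phenotypes through adipose tissue.
#'
#' @param config a [sim_config()]; its seed drives every stage.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file artifacts.
#' @param n_null number of random networks in the BiBC null
#'   (default 1000).
#' @param select_thresholds_grid if `TRUE`, network thresholds are chosen
#'   by the sign-ratio criterion over the default grid; otherwise the
#'   default thresholds (combined p 0.05, relaxed 0.1) are used directly.
#' @param alpha_disease,alpha_treat,fdr_max differential thresholds, see
#'   [classify_treatment_effect()].
#' @param edge_fdr_max FDR ceiling applied to edges within each data-type
#'   pair class (default 0.2, the top of the threshold-selection grid;
#'   `NULL` disables the gate).
#' @return (invisibly) a list with the per-stage results: `truth`,
#'   `differential`, `classification`, `edges`, `network`, `quality`,
#'   `bibc`, `null`, `null_p`, `assignments`, `quadrants`, `summary`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         n_null = 1000L, select_thresholds_grid = FALSE,
                         alpha_disease = 0.05, alpha_treat = 0.05,
                         fdr_max = 0.1, edge_fdr_max = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  art <- function(name) if (is.null(out_dir)) NULL else
    file.path(out_dir, name)

  # stage 1: simulate -----------------------------------------------------
  sim <- simulate_study(config)
  truth <- sim$truth
  if (!is.null(out_dir)) {
    for (nm in names(sim$tables))
      write_omics_tsv(sim$tables[[nm]], art(paste0("raw_", nm)))
    jsonlite::write_json(unclass(truth), art("truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(unclass(config), art("config.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # stage 2: normalize ----------------------------------------------------
  norm <- normalize_study(sim$tables)

  # stage 3: differential + classification --------------------------------
  combined <- bind_tables(norm)
  diff <- differential_stats(combined, groups = stats::setNames(
    config$groups, c("control", "disease", "treatment_a", "treatment_b")))
  cls <- classify_treatment_effect(diff, alpha_disease = alpha_disease,
                                   alpha_treat = alpha_treat,
                                   fdr_max = fdr_max)
  if (!is.null(out_dir)) {
    utils::write.table(diff, art("differential.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cls, art("classification.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # stage 4: network on the microbiota-adipose-phenotype universe ---------
  eligible <- cls[cls$eligible &
                  (cls$data_type %in% c("asv", "phenotype") |
                   (cls$data_type == "gene" & cls$tissue == "adipose")), ]
  if (nrow(eligible) < 2L) stop("fewer than two eligible network nodes")
  sub <- subset_table(combined, features = eligible$feature_id)
  stats_tab <- edge_stats(sub)
  signs <- stats::setNames(eligible$disease_direction, eligible$feature_id)
  if (select_thresholds_grid) {
    selected <- select_thresholds(stats_tab, signs)
    edges <- selected$edges
    quality <- selected$quality
  } else {
    edges <- filter_edges(stats_tab, fdr_max = edge_fdr_max)
    pruned <- prune_unexpected(edges, signs)
    edges <- pruned$edges
    kept <- edges[edges$status == "kept", ]
    nodes <- unique(c(kept$node_i, kept$node_j))
    quality <- network_quality(
      n_nodes = length(nodes), n_edges = nrow(kept),
      neg_pos_ratio_observed = if (sum(kept$sign > 0))
        sum(kept$sign < 0) / sum(kept$sign > 0) else Inf,
      neg_pos_ratio_expected = expected_sign_ratio(signs)$ratio,
      puc = pruned$puc
    )
  }
  net <- assemble_network(edges, eligible)
  if (!is.null(out_dir)) {
    utils::write.table(edges, art("edges.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_network(net$graph, art("network"))
    jsonlite::write_json(unclass(quality), art("network_quality.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # stage 5: BiBC + random-network null -----------------------------------
  node_types <- igraph::V(net$graph)$data_type
  src <- igraph::V(net$graph)$name[node_types == "asv"]
  tgt <- igraph::V(net$graph)$name[node_types == "phenotype"]
  if (!length(src) || !length(tgt))
    stop("network lacks ASV or phenotype nodes; cannot compute BiBC")
  report <- bibc(net$graph, source = src, target = tgt)
  top <- report[1, ]
  nul <- random_null(
    n_networks = n_null, n_nodes = igraph::vcount(net$graph),
    n_edges = igraph::ecount(net$graph),
    source_idx = match(src, igraph::V(net$graph)$name),
    target_idx = match(tgt, igraph::V(net$graph)$name),
    seed = config$seed + 3L
  )
  sig <- null_significance(nul, observed = top$bibc_raw)
  if (!is.null(out_dir))
    utils::write.table(report, art("bibc.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)

  # stage 6: cell-type assignment -----------------------------------------
  markers <- simulate_marker_table(config, truth)
  net_genes <- igraph::V(net$graph)$name[node_types == "gene"]
  assignments <- assign_cell_types(net_genes, markers)
  if (!is.null(out_dir))
    utils::write.table(assignments, art("cell_types.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  # stage 7: microbiota-dependence quadrants ------------------------------
  gf <- simulate_gf_spf(config, truth)
  gf_norm <- log2_pseudo(quantile_normalize(cpm(gf)))
  micro_fc <- two_group_stats(gf_norm, "SPF", "GF")
  treat_fc <- diff[diff$comparison == "treatment_b_vs_disease" &
                   diff$data_type == "gene" & diff$tissue == "adipose", ]
  quadrants <- classify_quadrants(treat_fc, micro_fc)
  if (!is.null(out_dir))
    utils::write.table(quadrants, art("quadrants.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  # summary ----------------------------------------------------------------
  asv_report <- report[report$node %in% src, ]
  summary <- list(
    seed = config$seed,
    n_eligible = nrow(eligible),
    n_nodes = igraph::vcount(net$graph),
    n_edges = igraph::ecount(net$graph),
    nodes_by_type = as.list(table(node_types)),
    categories = as.list(table(eligible$category)),
    top_bibc_node = top$node,
    top_bibc_value = top$bibc_raw,
    top_asv = asv_report$node[1],
    causal_asv = truth$causal_node,
    # a top rank only counts when the node actually carries traffic: on a
    # disconnected source/target split every BiBC is zero and rank ties are
    # broken lexically, which must not read as a recovery
    causal_asv_is_top = length(truth$causal_node) == 1 &&
      identical(asv_report$node[1], truth$causal_node) &&
      asv_report$bibc_raw[1] > 0,
    bibc_degenerate = top$bibc_raw == 0,
    null_p = sig$p,
    null_log10_p = sig$log10_p,
    null_exceedance = sig$exceedance,
    cell_type_counts = as.list(table(assignments$cell_type)),
    quadrant_fractions = as.list(attr(quadrants, "fractions")),
    puc = quality$puc,
    sparsity_deviation = quality$deviation
  )
  if (!is.null(out_dir))
    jsonlite::write_json(summary, art("summary.json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(list(truth = truth, differential = diff, classification = cls,
                 edges = edges, network = net, quality = quality,
                 bibc = report, null = nul, null_p = sig$p,
                 null_significance = sig, assignments = assignments,
                 quadrants = quadrants, summary = summary))
}
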