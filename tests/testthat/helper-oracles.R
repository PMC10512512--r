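# Independent oracles used to cross-check the package implementations.

# Brute-force bipartite betweenness: enumerate every shortest path for every
# source-target pair with igraph::all_shortest_paths and count pass-through
# fractions per interior node. Independent of the package's BFS counting.
brute_bibc <- function(graph, source, target) {
  nodes <- igraph::V(graph)$name
  acc <- stats::setNames(numeric(length(nodes)), nodes)
  for (s in source) {
    asp <- igraph::all_shortest_paths(graph, from = s, to = target)$res
    for (t in target) {
      paths <- Filter(function(p) igraph::as_ids(p)[length(p)] == t, asp)
      if (!length(paths)) next
      for (p in paths) {
        ids <- igraph::as_ids(p)
        interior <- setdiff(ids, c(s, t))
        acc[interior] <- acc[interior] + 1 / length(paths)
      }
    }
  }
  acc
}

# random connected G(n, p) graph with named vertices
random_connected_graph <- function(n, p = 0.25) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}

# Benjamini-Hochberg step-up written out directly, as an independent check
# on bh_fdr (which delegates to p.adjust within strata).
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# survival function of the chi-squared distribution with 4 df in closed
# form: P(X > x) = exp(-x/2) * (1 + x/2)
chisq4_tail <- function(x) exp(-x / 2) * (1 + x / 2)

# small raw count table with four groups, for normalization tests
toy_count_table <- function(seed = 1, n_feat = 12, n_per_group = 4) {
  set.seed(seed)
  groups <- rep(c("control", "disease", "treatment_a", "treatment_b"),
                each = n_per_group)
  m <- matrix(rnbinom(n_feat * length(groups), mu = 50, size = 10),
              n_feat, length(groups),
              dimnames = list(sprintf("f%02d", seq_len(n_feat)),
                              sprintf("s%02d", seq_along(groups))))
  omics_table(m, data_type = "gene", tissue = "adipose", group = groups)
}

# tiny single-cell count matrix exercising the QC boundaries:
# 5 cells with library sizes 2499 / 2500 / 3000 (mito ratio 0.51) / 3000 /
# 3000; gene g1 detected in exactly the 3 surviving cells
qc_matrix <- function() {
  genes <- c("mt-1", paste0("g", 1:5))
  m <- matrix(0L, length(genes), 5,
              dimnames = list(genes,
                              c("small", "boundary", "mito", "ok1", "ok2")))
  m["g1", "small"] <- 2499L
  m["g1", "boundary"] <- 2500L
  m["mt-1", "mito"] <- 1530L; m["g1", "mito"] <- 1470L  # ratio 0.51
  m["g1", "ok1"] <- 1000L; m["g2", "ok1"] <- 1000L; m["g3", "ok1"] <- 1000L
  m["g1", "ok2"] <- 1500L; m["g2", "ok2"] <- 1000L; m["g4", "ok2"] <- 500L
  m
}

# minimal edge-stats-shaped data.frame for filter/prune tests
make_edges <- function(node_i, node_j, rho, p, combined_p, sign,
                       pair_class = "asv|asv", fdr = combined_p) {
  k <- length(node_i)
  data.frame(
    node_i = node_i, node_j = node_j,
    rho.g1 = rho[, 1], rho.g2 = rho[, 2],
    rho.g3 = rho[, 3], rho.g4 = rho[, 4],
    p.g1 = p[, 1], p.g2 = p[, 2], p.g3 = p[, 3], p.g4 = p[, 4],
    n.g1 = 10L, n.g2 = 10L, n.g3 = 10L, n.g4 = 10L,
    combined_p = combined_p, sign = sign,
    pair_class = rep_len(pair_class, k), fdr = fdr,
    stringsAsFactors = FALSE
  )
}
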