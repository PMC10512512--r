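#' Bipartite betweenness centrality
#'
#' For every unordered pair (s, t) with s in `source`, t in `target` and a
#' connecting path, each node v not in {s, t} accrues the fraction of
#' shortest unweighted s-t paths passing through v. The pair sum is the
#' node's raw BiBC; it measures how much of the shortest-path "traffic"
#' between the two omic layers is funneled through the node, i.e. its
#' bottleneck-ness. Source and target nodes themselves can accrue BiBC for
#' pairs they do not belong to.
#'
#' @param graph an igraph object (undirected; edge signs/weights ignored)
#'   or the `$graph` element of [assemble_network()].
#' @param source,target disjoint non-empty character vectors of node names
#'   (e.g. all ASVs and all phenotypes).
#' @return data.frame (class `bibc_report`) with one row per node:
#'   `node`, `bibc_raw`, `bibc_normalized` (raw divided by
#'   |source| * |target|), `bibc_scaled01` (min-max within the report),
#'   `rank` (1 = highest), and the group sizes as attributes.
#' @export
bibc <- function(graph, source, target) {
  if (is.list(graph) && !igraph::is_igraph(graph)) graph <- graph$graph
  stopifnot(igraph::is_igraph(graph))
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(graph)))
  if (!length(source) || !length(target)) stop("empty node group")
  if (length(intersect(source, target))) stop("source and target overlap")
  si <- match(source, nodes); ti <- match(target, nodes)
  if (anyNA(si) || anyNA(ti)) stop("group nodes absent from graph")
  el <- igraph::as_edgelist(graph, names = FALSE)
  raw <- bibc_core(length(nodes), as.integer(el[, 1] - 1L),
                   as.integer(el[, 2] - 1L), as.integer(si - 1L),
                   as.integer(ti - 1L))
  rng <- range(raw)
  scaled <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1])
            else rep(0, length(raw))
  out <- data.frame(
    node = nodes,
    bibc_raw = raw,
    bibc_normalized = raw / (length(source) * length(target)),
    bibc_scaled01 = scaled,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$bibc_raw, out$node), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_source") <- length(source)
  attr(out, "n_target") <- length(target)
  class(out) <- c("bibc_report", "data.frame")
  out
}

#' Erdos-Renyi random-network null ensemble for the maximum BiBC
#'
#' Draws `n_networks` G(n, m) graphs (uniform over edge sets of exactly
#' `n_edges` edges on the observed node set), computes BiBC with the same
#' source/target memberships as the real network, and records the maximum
#' node BiBC of each draw.
#'
#' @param n_networks number of random networks (the reference analysis
#'   uses 10,000).
#' @param n_nodes,n_edges size of each random network (matched to the
#'   observed network).
#' @param source_idx,target_idx integer node indices (1-based into the
#'   node set) of the two groups, carried over from the real network.
#' @param seed RNG seed; identical seeds give identical ensembles.
#' @return object of class `null_ensemble`: list with `max_bibc`
#'   (length `n_networks`), and the generating parameters.
#' @export
random_null <- function(n_networks, n_nodes, n_edges, source_idx,
                        target_idx, seed = 1L) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2)
    stop("n_edges exceeds the complete graph")
  if (length(intersect(source_idx, target_idx)))
    stop("source and target overlap")
  set.seed(seed)
  s0 <- as.integer(source_idx - 1L); t0 <- as.integer(target_idx - 1L)
  max_bibc <- vapply(seq_len(n_networks), function(k) {
    g <- igraph::sample_gnm(n_nodes, n_edges)
    el <- igraph::as_edgelist(g, names = FALSE)
    max(bibc_core(n_nodes, as.integer(el[, 1] - 1L),
                  as.integer(el[, 2] - 1L), s0, t0))
  }, numeric(1))
  structure(list(
    n_networks = n_networks, n_nodes = n_nodes, n_edges = n_edges,
    source_idx = source_idx, target_idx = target_idx, seed = seed,
    max_bibc = max_bibc
  ), class = "null_ensemble")
}

#' One-sample Wilcoxon signed-rank test on the log scale
#'
#' Tests values against a location `mu`. Exact distribution (by convolution
#' over rank inclusion) for n <= 25 without zeros/ties; otherwise normal
#' approximation with continuity and tie correction, evaluated on the log
#' scale so extreme p-values (far below 1e-15) keep their magnitude.
#'
#' @param x numeric values.
#' @param mu null location.
#' @return list with `p` (may underflow to 0 for astronomically small
#'   values), `log10_p`, `V` (signed-rank statistic), `method`.
#' @export
wilcoxon_signed_rank <- function(x, mu) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(list(p = 1, log10_p = 0, V = NA_real_,
                      method = "degenerate"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25L && !ties) {
    # exact: distribution of V is the convolution of Bernoulli(1/2) * rank
    probs <- 1
    for (k in seq_len(n)) {
      shifted <- c(rep(0, k), probs)
      probs <- (c(probs, rep(0, k)) + shifted) / 2
    }
    # probs[v + 1] = P(V = v), v = 0..n(n+1)/2
    lower <- sum(probs[seq_len(V + 1)])
    upper <- sum(probs[(V + 1):length(probs)])
    p <- min(1, 2 * min(lower, upper))
    return(list(p = p, log10_p = log10(p), V = V, method = "exact"))
  }
  mu_v <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                sum(tie_tab^3 - tie_tab) / 48)
  z <- (V - mu_v - sign(V - mu_v) * 0.5) / sigma
  log_p <- stats::pnorm(-abs(z), log.p = TRUE) + log(2)
  log_p <- min(log_p, 0)
  list(p = exp(log_p), log10_p = log_p / log(10), V = V,
       method = "normal_approx")
}

#' Significance of an observed BiBC against the random-network null
#'
#' Pools the null maximum-BiBC values with the observed value, min-max
#' scales the pooled set to [0, 1], and runs a two-sided one-sample
#' Wilcoxon signed-rank test of the scaled null values against the scaled
#' observed value. Also reports the empirical exceedance fraction (share
#' of null values at or above the observed).
#'
#' @param ensemble a `null_ensemble` from [random_null()], or a numeric
#'   vector of null maxima.
#' @param observed the observed BiBC value (same raw scale as the null).
#' @return list: `p`, `log10_p`, `exceedance`, `scaled_observed`,
#'   `scaled_null`.
#' @export
null_significance <- function(ensemble, observed) {
  nulls <- if (inherits(ensemble, "null_ensemble")) ensemble$max_bibc
           else as.numeric(ensemble)
  if (!length(nulls)) stop("empty null ensemble")
  pooled <- c(nulls, observed)
  rng <- range(pooled)
  if (rng[2] == rng[1]) {
    warning("degenerate scaling: observed equals all null values")
    return(list(p = 1, log10_p = 0, exceedance = 1,
                scaled_observed = 0, scaled_null = rep(0, length(nulls))))
  }
  scaled <- (pooled - rng[1]) / (rng[2] - rng[1])
  scaled_null <- scaled[seq_along(nulls)]
  scaled_obs <- scaled[length(scaled)]
  wt <- wilcoxon_signed_rank(scaled_null, mu = scaled_obs)
  list(p = wt$p, log10_p = wt$log10_p,
       exceedance = mean(nulls >= observed),
       scaled_observed = scaled_obs, scaled_null = scaled_null)
}
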