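path_graph <- function(edges) {
  igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
}

test_that("BiBC on a single path credits only the interior node", {
  g <- path_graph(cbind(c("A", "B"), c("B", "C")))
  rep <- bibc(g, source = "A", target = "C")
  expect_equal(rep$bibc_raw[rep$node == "B"], 1)
  expect_equal(rep$bibc_raw[rep$node == "A"], 0)
  expect_equal(rep$bibc_raw[rep$node == "C"], 0)
  expect_equal(rep$rank[rep$node == "B"], 1)
})

test_that("BiBC splits evenly over parallel shortest paths", {
  g <- path_graph(cbind(c("s", "s", "v1", "v2"), c("v1", "v2", "t", "t")))
  rep <- bibc(g, source = "s", target = "t")
  expect_equal(rep$bibc_raw[rep$node == "v1"], 0.5)
  expect_equal(rep$bibc_raw[rep$node == "v2"], 0.5)
})

test_that("BiBC equals brute-force shortest-path enumeration", {
  set.seed(31)
  for (k in 1:40) {
    n <- sample(6:18, 1)
    g <- random_connected_graph(n, p = runif(1, 0.15, 0.4))
    nodes <- igraph::V(g)$name
    src <- sample(nodes, sample(1:3, 1))
    tgt <- sample(setdiff(nodes, src), sample(1:3, 1))
    rep <- bibc(g, src, tgt)
    oracle <- brute_bibc(g, src, tgt)
    expect_equal(setNames(rep$bibc_raw, rep$node)[names(oracle)], oracle,
                 tolerance = 1e-12)
  }
})

test_that("BiBC is symmetric in source and target and handles
           disconnection", {
  set.seed(32)
  g <- random_connected_graph(12, 0.25)
  nodes <- igraph::V(g)$name
  src <- nodes[1:3]; tgt <- nodes[10:12]
  a <- bibc(g, src, tgt); b <- bibc(g, tgt, src)
  av <- setNames(a$bibc_raw, a$node)
  bv <- setNames(b$bibc_raw, b$node)[names(av)]
  expect_equal(av, bv)
  # disconnected pair contributes nothing
  g2 <- igraph::make_graph(~ A - B, C - D)
  rep <- bibc(g2, "A", c("B", "D"))
  expect_equal(sum(rep$bibc_raw), 0)
})

test_that("per-pair pass-through fractions sum to path length minus one", {
  set.seed(33)
  for (k in 1:10) {
    g <- random_connected_graph(10, 0.3)
    nodes <- igraph::V(g)$name
    s <- nodes[1]; t <- nodes[10]
    rep <- bibc(g, s, t)
    d <- igraph::distances(g, s, t)[1, 1]
    expect_equal(sum(rep$bibc_raw), d - 1, tolerance = 1e-12)
  }
})

test_that("normalized BiBC divides by the number of group pairs", {
  g <- path_graph(cbind(c("a1", "a2", "m"), c("m", "m", "t1")))
  rep <- bibc(g, c("a1", "a2"), "t1")
  expect_equal(rep$bibc_normalized, rep$bibc_raw / (2 * 1))
  expect_true(all(rep$bibc_normalized >= 0 & rep$bibc_normalized <= 1))
})

test_that("bibc validates its node groups", {
  g <- path_graph(cbind("A", "B"))
  expect_error(bibc(g, "A", "A"), "overlap")
  expect_error(bibc(g, character(0), "B"), "empty")
  expect_error(bibc(g, "A", "Z"), "absent")
})

test_that("G(n,m) null ensembles have exact edge counts and are
           reproducible", {
  nul <- random_null(25, n_nodes = 20, n_edges = 40,
                     source_idx = 1:4, target_idx = 15:20, seed = 5)
  expect_length(nul$max_bibc, 25)
  nul2 <- random_null(25, 20, 40, 1:4, 15:20, seed = 5)
  expect_identical(nul$max_bibc, nul2$max_bibc)
  # complete graphs: all shortest paths are direct edges, max BiBC constant
  m_full <- choose(10, 2)
  nulc <- random_null(5, 10, m_full, 1:3, 8:10, seed = 1)
  expect_equal(diff(range(nulc$max_bibc)), 0)
  expect_error(random_null(2, 5, 11, 1, 5), "exceeds")
})

test_that("signed-rank test matches the exact distribution on small
           samples", {
  # 10 values all below the reference: V = 0, exact p = 2 / 2^10
  out <- wilcoxon_signed_rank(seq(0.1, 0.9, length.out = 10), mu = 1)
  expect_equal(out$p, 2 / 2^10)
  expect_equal(out$method, "exact")
  # agreement with stats::wilcox.test where the latter is exact
  set.seed(41)
  for (k in 1:10) {
    x <- round(rnorm(sample(6:20, 1)), 4)
    mu <- round(rnorm(1), 4)
    if (any(x == mu) || anyDuplicated(abs(x - mu))) next
    ours <- wilcoxon_signed_rank(x, mu)
    ref <- wilcox.test(x, mu = mu, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  # observed at the centre of a symmetric sample: p close to 1
  out2 <- wilcoxon_signed_rank(c(1:10, 20 - (1:10)), mu = 10)
  expect_gt(out2$p, 0.9)
})

test_that("log-scale tail resolves p-values far below 1e-15", {
  nulls <- seq(0.001, 0.9, length.out = 10000)
  out <- wilcoxon_signed_rank(nulls, mu = 1)
  expect_equal(out$method, "normal_approx")
  expect_lt(out$log10_p, -15)
  expect_lt(out$p, 1e-15)
})

test_that("null significance scales jointly and reports exceedance", {
  nulls <- runif(500, 0, 0.5)
  sig <- null_significance(nulls, observed = 1)
  expect_equal(sig$scaled_observed, 1)
  expect_equal(sig$exceedance, 0)
  expect_lt(sig$p, 1e-10)
  # observed at the centre of a symmetric null: no evidence either way
  sym <- c(seq(0.1, 0.45, length.out = 100), seq(0.55, 0.9, length.out = 100))
  sig2 <- null_significance(sym, observed = 0.5)
  expect_gt(sig2$p, 0.9)
  expect_warning(sig3 <- null_significance(rep(2, 10), observed = 2),
                 "degenerate")
  expect_equal(sig3$p, 1)
})
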