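spearman_table <- function(m, group) {
  omics_table(m, "gene", tissue = "adipose", group = group,
              normalized_state = "log2")
}

test_that("per-group Spearman matches the classical rank formula", {
  m <- rbind(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5),
             z = c(5, 4, 3, 2, 1))
  colnames(m) <- paste0("s", 1:5)
  st <- spearman_per_group(spearman_table(m, rep("g1", 5)))
  # 1 - 6 * sum(d^2) / (n(n^2-1)) with sum(d^2) = 4
  expect_equal(st$rho.g1[st$node_i == "x" & st$node_j == "y"], 0.8)
  expect_equal(st$rho.g1[st$node_i == "x" & st$node_j == "z"], -1)
  expect_equal(st$rho.g1[st$node_i == "y" & st$node_j == "z"], -0.8)
})

test_that("per-group Spearman agrees with cor.test's t approximation", {
  set.seed(2)
  m <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:10)))
  st <- spearman_per_group(spearman_table(m, rep("g1", 10)))
  for (k in sample(nrow(st), 5)) {
    ct <- cor.test(m[st$node_i[k], ], m[st$node_j[k], ],
                   method = "spearman", exact = FALSE)
    expect_equal(st$rho.g1[k], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(st$p.g1[k], ct$p.value, tolerance = 1e-10)
  }
})

test_that("constant features lose their group but keep the others", {
  m <- rbind(a = c(1, 1, 1, 1, 5, 6, 7, 8),
             b = c(4, 3, 2, 1, 8, 7, 6, 5))
  colnames(m) <- paste0("s", 1:8)
  expect_warning(
    st <- spearman_per_group(spearman_table(m, rep(c("g1", "g2"), each = 4))),
    "constant"
  )
  expect_true(is.na(st$rho.g1))
  expect_equal(st$rho.g2, -1)
})

test_that("Fisher-z pooling reproduces closed-form and metafor results", {
  # identical inputs return the input correlation
  out <- fisher_z_meta(rbind(c(0.5, 0.5, 0.5)), rbind(c(10, 10, 10)))
  expect_equal(out$combined_r, 0.5, tolerance = 1e-12)
  # two groups rho 0.5, n = 10: z = atanh(0.5), stat = z * sqrt(14)
  out2 <- fisher_z_meta(rbind(c(0.5, 0.5)), rbind(c(10, 10)))
  expect_equal(out2$combined_z, atanh(0.5), tolerance = 1e-12)
  expect_equal(out2$z_stat, atanh(0.5) * sqrt(14), tolerance = 1e-12)
  expect_equal(out2$combined_p, 2 * pnorm(-atanh(0.5) * sqrt(14)),
               tolerance = 1e-12)
  expect_equal(round(out2$combined_p, 3), 0.04)
  # opposite correlations cancel
  out3 <- fisher_z_meta(rbind(c(0.6, -0.6)), rbind(c(12, 12)))
  expect_equal(out3$combined_z, 0)
  expect_equal(out3$combined_p, 1)
  # |rho| = 1 is clamped to a finite z
  out4 <- fisher_z_meta(rbind(c(1, 0.5)), rbind(c(10, 10)))
  expect_true(is.finite(out4$combined_z))
  # independent fixed-effect oracle
  skip_if_not_installed("metafor")
  rho <- c(0.3, 0.55, -0.2, 0.4); n <- c(10, 9, 12, 10)
  ours <- fisher_z_meta(rbind(rho), rbind(n))
  fe <- metafor::rma(yi = atanh(rho), vi = 1 / (n - 3), method = "FE")
  expect_equal(ours$combined_z, unname(fe$beta[1]), tolerance = 1e-8)
  expect_equal(ours$combined_p, fe$pval, tolerance = 1e-8)
})

test_that("single-group meta-analysis reduces to the z*sqrt(n-3) test", {
  out <- fisher_z_meta(rbind(0.45), rbind(14))
  expect_equal(out$z_stat, atanh(0.45) * sqrt(11))
  expect_equal(out$combined_p, 2 * pnorm(-abs(atanh(0.45) * sqrt(11))))
})

test_that("edge filters enforce max-p, pair-class thresholds and sign
           consistency", {
  rho_ok <- matrix(0.6, 3, 4)
  rho_ok[3, 3] <- -0.5  # one group disagrees in sign
  p <- matrix(0.01, 3, 4)
  p[2, 1] <- 0.6        # violates the max-p 0.5 rule
  e <- make_edges(c("a", "b", "c"), c("b", "c", "a"),
                  rho = rho_ok, p = p,
                  combined_p = c(0.001, 0.001, 0.001), sign = c(1, 1, 1))
  f <- filter_edges(e)
  expect_equal(f$status, c("kept", "removed_p", "removed_sign_inconsistent"))

  # relaxed pair class keeps combined p 0.08
  e2 <- make_edges("ba_01", "gene_a", rho = matrix(0.5, 1, 4),
                   p = matrix(0.2, 1, 4), combined_p = 0.08, sign = 1,
                   pair_class = "bile_acid|gene_adipose")
  expect_equal(filter_edges(e2)$status, "kept")
  e2$pair_class <- "gene_adipose|gene_adipose"
  expect_equal(filter_edges(e2)$status, "removed_p")
})

test_that("unexpected-correlation pruning follows the expected-sign rule", {
  e <- make_edges(c("up1", "up1", "up2"), c("up2", "dn1", "dn1"),
                  rho = matrix(0.5, 3, 4), p = matrix(0.01, 3, 4),
                  combined_p = rep(0.001, 3), sign = c(1, 1, -1))
  e$status <- "kept"
  signs <- c(up1 = 1, up2 = 1, dn1 = -1)
  pr <- prune_unexpected(e, signs)
  expect_equal(pr$edges$status,
               c("kept", "removed_unexpected", "kept"))
  expect_equal(pr$puc, 1 / 3)

  # symmetric in node order
  e_sw <- e; e_sw$node_i <- e$node_j; e_sw$node_j <- e$node_i
  expect_equal(prune_unexpected(e_sw, signs)$puc, pr$puc)

  # direction-0 nodes are exempt
  signs0 <- c(up1 = 1, up2 = 0, dn1 = -1)
  pr0 <- prune_unexpected(e, signs0)
  expect_equal(pr0$edges$status[1], "kept")
  expect_equal(pr0$edges$status[3], "kept")
})

test_that("sign-randomized edges lose about half to pruning, planted lose
           none", {
  set.seed(9)
  n <- 2000
  ids <- sprintf("n%03d", 1:120)
  node_signs <- setNames(sample(c(-1, 1), 120, TRUE), ids)
  pairs <- t(replicate(n, sample(ids, 2)))
  e <- make_edges(pairs[, 1], pairs[, 2], rho = matrix(0.5, n, 4),
                  p = matrix(0.01, n, 4), combined_p = rep(0.001, n),
                  sign = sample(c(-1, 1), n, TRUE))
  e$status <- "kept"
  frac <- 1 - sum(prune_unexpected(e, node_signs)$edges$status == "kept") / n
  expect_gt(frac, 0.45); expect_lt(frac, 0.55)
  # planted edges: sign equals the product of endpoint signs
  e$sign <- unname(node_signs[pairs[, 1]] * node_signs[pairs[, 2]])
  expect_equal(prune_unexpected(e, node_signs)$puc, 0)
})

test_that("sparsity deviation matches the complete-graph formula", {
  for (n in c(2, 5, 17)) {
    expect_equal(sparsity_deviation(n, choose(n, 2)), 0)
  }
  expect_equal(sparsity_deviation(4, 3), 0.5)  # tree: |0.75 - 1.5| / 1.5
  expect_equal(sparsity_deviation(10, 0), 1)
  expect_error(sparsity_deviation(1, 0), "2 nodes")
})

test_that("expected sign ratio counts pairs combinatorially", {
  # all nodes up: no negative pairs expected
  expect_equal(expected_sign_ratio(rep(1, 6))$ratio, 0)
  # half and half on 2k nodes: k^2 negative pairs, 2*choose(k,2) positive
  s <- c(rep(1, 4), rep(-1, 4))
  er <- expected_sign_ratio(s)
  expect_equal(er$n_neg, 16)
  expect_equal(er$n_pos, 2 * choose(4, 2))
  expect_equal(er$ratio, 16 / 12)
  # zeros are excluded
  expect_equal(expected_sign_ratio(c(s, 0, 0))$ratio, 16 / 12)
})

test_that("threshold selection prefers stringency on clean planted data", {
  # noise-free construction: planted edges have tiny p everywhere and signs
  # equal to endpoint products; observed ratio equals expected at every
  # candidate, so the most stringent grid point must win
  ids <- sprintf("n%02d", 1:10)
  signs <- setNames(rep(c(1, -1), 5), ids)
  cmb <- t(combn(ids, 2))
  e <- make_edges(cmb[, 1], cmb[, 2],
                  rho = matrix(0.9, nrow(cmb), 4) *
                        (signs[cmb[, 1]] * signs[cmb[, 2]]),
                  p = matrix(1e-6, nrow(cmb), 4),
                  combined_p = rep(1e-9, nrow(cmb)),
                  sign = unname(signs[cmb[, 1]] * signs[cmb[, 2]]))
  e$fdr <- e$combined_p
  sel <- select_thresholds(e, signs)
  expect_equal(sel$fdr_max, 0.01)
  expect_equal(sel$p_combined, 0.01)
  expect_equal(sel$quality$puc, 0)
  expect_equal(sel$quality$neg_pos_ratio_observed,
               sel$quality$neg_pos_ratio_expected)
  expect_true(all(sel$edges$status == "kept"))
})

test_that("network assembly dedupes edges and attaches attributes", {
  e <- make_edges(c("A", "B", "A"), c("B", "C", "B"),
                  rho = matrix(0.5, 3, 4), p = matrix(0.01, 3, 4),
                  combined_p = rep(0.001, 3), sign = c(1, -1, 1))
  e$status <- "kept"
  e$combined_r <- 0.5
  attrs <- data.frame(feature_id = c("A", "B", "C", "D"),
                      data_type = c("asv", "gene", "phenotype", "gene"),
                      tissue = NA, disease_direction = c(1, 1, -1, 1),
                      category = "B_improved", stringsAsFactors = FALSE)
  net <- assemble_network(e, attrs)
  expect_equal(igraph::vcount(net$graph), 3)
  expect_equal(igraph::ecount(net$graph), 2)  # duplicate A-B collapsed
  expect_equal(net$isolated, "D")
  expect_setequal(igraph::V(net$graph)$data_type,
                  c("asv", "gene", "phenotype"))
  e$status <- "removed_p"
  expect_error(assemble_network(e, attrs), "no kept edges")
})

test_that("network exports write GraphML and SIF files", {
  e <- make_edges(c("A", "B"), c("B", "C"), rho = matrix(0.5, 2, 4),
                  p = matrix(0.01, 2, 4), combined_p = rep(0.001, 2),
                  sign = c(1, -1))
  e$status <- "kept"; e$combined_r <- 0.5
  attrs <- data.frame(feature_id = c("A", "B", "C"), data_type = "gene",
                      tissue = "adipose", disease_direction = 1,
                      category = "neither", stringsAsFactors = FALSE)
  net <- assemble_network(e, attrs)
  prefix <- file.path(tempdir(), "tkna_net")
  write_network(net$graph, prefix)
  expect_true(file.exists(paste0(prefix, ".graphml")))
  sif <- read.table(paste0(prefix, ".sif"), sep = "\t")
  expect_equal(nrow(sif), 2)
  expect_setequal(sif$V2, c("pos", "neg"))
})

test_that("planted edges survive the default filters at study conditions", {
  # retention bound fixed by pilot: the four-group screening keeps most but
  # not all planted edges under default noise
  ret <- vapply(1:3, function(seed) {
    sim <- simulate_study(sim_config(seed = seed))
    tr <- sim$truth
    norm <- normalize_study(sim$tables)
    combined <- bind_tables(norm)
    diff <- differential_stats(combined)
    cls <- classify_treatment_effect(diff)
    el <- cls[cls$eligible, ]
    sub <- subset_table(combined, features = el$feature_id)
    f <- suppressWarnings(filter_edges(edge_stats(sub)))
    pr <- prune_unexpected(f, setNames(el$disease_direction, el$feature_id))
    kept <- pr$edges[pr$edges$status == "kept", ]
    pe <- tr$planted_edges
    pe <- pe[pe$node_i %in% el$feature_id & pe$node_j %in% el$feature_id, ]
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mean(key(pe$node_i, pe$node_j) %in% key(kept$node_i, kept$node_j))
  }, numeric(1))
  expect_gt(mean(ret), 0.5)
})
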