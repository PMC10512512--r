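test_that("cpm forces columns to one million and preserves proportions", {
  m <- matrix(c(1, 1, 2, 3, 3, 6), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  ot <- omics_table(m, "gene", tissue = "adipose", group = c("g1", "g1"))
  out <- cpm(ot)
  expect_equal(out$matrix[, 1], c(a = 250000, b = 250000, c = 500000))
  expect_equal(unname(colSums(out$matrix)), c(1e6, 1e6))
  # direct arithmetic oracle: value / colsum * 1e6
  expect_equal(out$matrix, sweep(m, 2, colSums(m), "/") * 1e6)
  expect_equal(out$normalized_state, "cpm")
})

test_that("cpm is idempotent and leaves already-scaled columns unchanged", {
  ot <- toy_count_table()
  once <- cpm(ot)
  twice <- cpm(once)
  expect_equal(once$matrix, twice$matrix)
})

test_that("cpm rejects all-zero samples by name and negative input", {
  m <- matrix(c(1, 2, 0, 0), 2, 2,
              dimnames = list(c("a", "b"), c("ok", "empty")))
  ot <- omics_table(m, "gene", tissue = "x", group = c("g", "g"))
  expect_error(cpm(ot), "empty")
})

test_that("quantile normalization equalizes column distributions", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  ot <- omics_table(m, "gene", tissue = "x", group = c("g", "g"))
  out <- quantile_normalize(ot)
  # sorted-mean oracle by hand: reference = ((1+4)/2, (2+5)/2, (3+6)/2)
  expect_equal(unname(out$matrix[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$matrix[, 2]), c(2.5, 3.5, 4.5))

  # identical columns are unchanged
  m2 <- cbind(s1 = c(3, 1, 7), s2 = c(3, 1, 7))
  rownames(m2) <- c("a", "b", "c")
  ot2 <- omics_table(m2, "gene", tissue = "x", group = c("g", "g"))
  expect_equal(quantile_normalize(ot2)$matrix, m2)

  # post-condition on tie-free data: all columns share one sorted multiset
  # (with ties, the span-averaging rule intentionally departs from strict
  # multiset equality)
  set.seed(3)
  m3 <- matrix(rlnorm(60), 12, 5,
               dimnames = list(sprintf("f%02d", 1:12), sprintf("s%d", 1:5)))
  ot3 <- omics_table(m3, "gene", tissue = "x", group = rep("g", 5))
  q3 <- quantile_normalize(ot3)$matrix
  sorted <- apply(q3, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))

  # idempotence
  ot3q <- quantile_normalize(ot3)
  expect_equal(quantile_normalize(ot3q)$matrix, q3)
})

test_that("quantile normalization matches limma on tie-free data and averages
           reference values over tie spans", {
  skip_if_not_installed("limma")
  set.seed(11)
  m <- matrix(rnorm(60), 12, 5,
              dimnames = list(sprintf("f%02d", 1:12), sprintf("s%d", 1:5)))
  ot <- omics_table(abs(m), "gene", tissue = "x", group = rep("g", 5),
                    normalized_state = "cpm")
  ours <- quantile_normalize(ot)$matrix
  ref <- limma::normalizeQuantiles(abs(m))
  expect_equal(unname(ours), unname(as.matrix(ref)), tolerance = 1e-10)

  # tie rule: tied values get the mean of the reference values they span
  mt <- cbind(s1 = c(1, 1, 5), s2 = c(2, 4, 6))
  rownames(mt) <- c("a", "b", "c")
  ott <- omics_table(mt, "gene", tissue = "x", group = c("g", "g"))
  qt <- quantile_normalize(ott)$matrix
  refv <- unname(rowMeans(apply(mt, 2, sort)))  # (1.5, 2.5, 5.5)
  expect_equal(unname(qt[, 1]),
               c(mean(refv[1:2]), mean(refv[1:2]), refv[3]))
})

test_that("log2_pseudo maps 0 to 0, 1 to 1, 7 to 3 and rejects negatives", {
  m <- matrix(c(0, 1, 7, 3), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  ot <- omics_table(m, "gene", tissue = "x", group = c("g", "g"),
                    normalized_state = "cpm")
  out <- log2_pseudo(ot)
  expect_equal(unname(out$matrix), matrix(c(0, 1, 3, 2), 2, 2))
  ot$matrix[1, 1] <- -1
  expect_error(log2_pseudo(ot), "non-negative")
})

test_that("median_normalize divides rows by their median and flags zeros", {
  m <- rbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(0, 0, 1))
  colnames(m) <- c("s1", "s2", "s3")
  ot <- omics_table(m, "phenotype", group = rep("g", 3))
  expect_warning(out <- median_normalize(ot), "zero median")
  expect_equal(unname(out$matrix["a", ]), c(0.5, 1, 1.5))
  expect_equal(unname(out$matrix["b", ]), c(1, 1, 1))
  expect_equal(unname(out$matrix["c", ]), c(0, 0, 1))  # unscaled
  expect_equal(attr(out, "zero_median_features"), "c")
})

test_that("qPCR relative expression follows the 2^-dCT rule", {
  ct <- rbind(Polr2c = c(20, 22), geneA = c(20, 23), geneB = c(18, 24))
  colnames(ct) <- c("s1", "s2")
  rel <- qpcr_relative_expression(ct, "Polr2c")
  expect_equal(rel["geneA", ], c(s1 = 1, s2 = 0.5))
  expect_equal(rel["geneB", ], c(s1 = 4, s2 = 0.25))
  expect_error(qpcr_relative_expression(ct, "Gapdh"), "not found")
})

test_that("rank statistics are invariant to the cpm and log2 steps", {
  ot <- toy_count_table(seed = 5)
  before <- cpm(ot)
  after <- log2_pseudo(before)
  g <- ot$sample_meta$group
  for (i in c(1, 5, 9)) {
    p1 <- mann_whitney(before$matrix[i, g == "control"],
                       before$matrix[i, g == "disease"])$p
    p2 <- mann_whitney(after$matrix[i, g == "control"],
                       after$matrix[i, g == "disease"])$p
    expect_equal(p1, p2)
  }
})

test_that("normalization state only moves forward", {
  ot <- toy_count_table()
  lg <- log2_pseudo(cpm(ot))
  expect_error(quantile_normalize(lg), "forward")
  md <- suppressWarnings(median_normalize(toy_count_table()))
  expect_error(cpm(md), "forward|median")
})

test_that("omics_table validates inputs and supports subset and bind", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(omics_table(m, "gene", group = c("g", "g")), "duplicate")
  ot <- toy_count_table()
  sub <- subset_table(ot, features = c("f01", "f03"),
                      samples = c("s01", "s02"))
  expect_equal(dim(sub), c(2L, 2L))
  expect_equal(sub$feature_meta$feature_id, c("f01", "f03"))
  other <- toy_count_table(seed = 9)
  rownames(other$matrix) <- sprintf("g%02d", seq_len(nrow(other$matrix)))
  other$feature_meta$feature_id <- rownames(other$matrix)
  both <- bind_tables(ot, other)
  expect_equal(nrow(both$matrix), 24)
  expect_error(bind_tables(ot, ot), "duplicate")
})

test_that("omics TSV round trip preserves the table", {
  ot <- toy_count_table(seed = 7)
  prefix <- file.path(tempdir(), "tkna_test")
  write_omics_tsv(ot, prefix)
  back <- read_omics_tsv(prefix)
  expect_equal(back$matrix, ot$matrix)
  expect_equal(back$feature_meta, ot$feature_meta)
  expect_equal(back$sample_meta, ot$sample_meta)
})
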