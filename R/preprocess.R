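#' Counts-per-million normalization
#'
#' Relativizes each sample (column) to a library size of one million, so
#' that within-sample proportions are preserved exactly.
#'
#' @param table an [omics_table()] of raw non-negative counts.
#' @return the table with each column scaled to sum to 1e6 and
#'   `normalized_state = "cpm"`.
#' @export
cpm <- function(table) {
  stopifnot(inherits(table, "omics_table"))
  m <- table$matrix
  if (any(m < 0)) stop("cpm requires non-negative values")
  cs <- colSums(m)
  if (any(cs == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(m)[cs == 0], collapse = ", "))
  }
  table$matrix <- sweep(m, 2, cs, "/") * 1e6
  if (table$normalized_state != "cpm") table <- .advance_state(table, "cpm")
  table
}

#' Quantile normalization
#'
#' Forces every sample column onto the common reference distribution given
#' by the row-wise mean of the sorted columns. Ranks within each column are
#' preserved; tied values receive the mean of the reference values spanned
#' by the tied rank range.
#'
#' @param table an [omics_table()].
#' @return the table quantile-normalized, `normalized_state = "quantile"`.
#' @export
quantile_normalize <- function(table) {
  stopifnot(inherits(table, "omics_table"))
  m <- table$matrix
  if (ncol(m) < 2L) {
    warning("single sample: quantile normalization is the identity")
    return(.advance_state(table, "quantile"))
  }
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    rmin <- rank(v, ties.method = "min")
    rmax <- rank(v, ties.method = "max")
    # tied values share the mean of the reference values across their rank span
    out[, j] <- vapply(seq_along(v), function(i) {
      mean(ref[rmin[i]:rmax[i]])
    }, numeric(1))
  }
  table$matrix <- out
  .advance_state(table, "quantile")
}

#' log2 transform with pseudocount 1
#'
#' `x -> log2(x + 1)`: zeros map to zero, value 1 maps to 1.
#'
#' @param table an [omics_table()] with non-negative values.
#' @return the table log2-transformed, `normalized_state = "log2"`.
#' @export
log2_pseudo <- function(table) {
  stopifnot(inherits(table, "omics_table"))
  if (any(table$matrix < 0)) stop("log2_pseudo requires non-negative values")
  table$matrix <- log2(table$matrix + 1)
  .advance_state(table, "log2")
}

#' Median normalization across all samples
#'
#' Divides each feature row by its median across all samples (the
#' convention for bile-acid concentrations and phenotype measurements).
#' Rows whose median is zero are left unscaled and flagged.
#'
#' @param table an [omics_table()].
#' @return the table median-normalized, with an attribute
#'   `zero_median_features` listing any unscaled rows;
#'   `normalized_state = "median"`.
#' @export
median_normalize <- function(table) {
  stopifnot(inherits(table, "omics_table"))
  m <- table$matrix
  med <- apply(m, 1, stats::median)
  zero <- med == 0
  scale <- ifelse(zero, 1, med)
  table$matrix <- m / scale
  table <- .advance_state(table, "median")
  attr(table, "zero_median_features") <- rownames(m)[zero]
  if (any(zero))
    warning(sum(zero), " feature(s) with zero median left unscaled")
  table
}

#' Standard normalization chain for a study
#'
#' Applies the chain appropriate to each data type: count tables (genes,
#' ASVs) get CPM -> quantile -> log2(+1); continuous tables (bile acids,
#' phenotypes) are median-normalized across all samples. Each table is
#' normalized independently; no cross-table normalization is performed.
#'
#' @param tables named list of raw `omics_table`s (as from
#'   [simulate_study()]).
#' @return named list of normalized tables.
#' @export
normalize_study <- function(tables) {
  lapply(tables, function(t) {
    if (all(t$feature_meta$data_type %in% c("gene", "asv"))) {
      log2_pseudo(quantile_normalize(cpm(t)))
    } else {
      median_normalize(t)
    }
  })
}

#' qPCR relative expression via the 2^-dCT method
#'
#' Normalizes raw cycle-threshold (CT) values to a housekeeping gene per
#' sample (delta-CT), then converts to relative expression
#' `2^-(CT_gene - CT_housekeeping)`. The housekeeping row itself maps to 1
#' in every sample.
#'
#' @param ct numeric matrix of CT values, genes in rows, samples in columns.
#' @param housekeeping row name of the housekeeping gene (e.g., "Polr2c").
#' @param median_normalize if `TRUE`, relative expression is additionally
#'   divided by each gene's median across samples.
#' @return matrix of relative expression values (housekeeping row dropped).
#' @export
qpcr_relative_expression <- function(ct, housekeeping,
                                     median_normalize = FALSE) {
  if (!housekeeping %in% rownames(ct))
    stop("housekeeping gene '", housekeeping, "' not found")
  hk <- ct[housekeeping, ]
  if (anyNA(ct) || any(!is.finite(ct)))
    stop("CT values must be finite")
  rel <- 2^-(sweep(ct, 2, hk, "-"))
  rel <- rel[setdiff(rownames(ct), housekeeping), , drop = FALSE]
  if (median_normalize) {
    med <- apply(rel, 1, stats::median)
    rel <- rel / ifelse(med == 0, 1, med)
  }
  rel
}
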