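#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Thin, checked wrapper used for all two-group comparisons in the
#' pipeline: exact distribution for small samples without ties, normal
#' approximation with tie correction otherwise.
#'
#' @param x,y numeric sample vectors (>= 3 observations each).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with elements `p` and `U` (the rank-sum statistic for `x`).
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  if (length(x) < 3L || length(y) < 3L)
    stop("mann_whitney requires >= 3 observations per group")
  if (length(unique(c(x, y))) == 1L) {
    return(list(p = 1, U = length(x) * length(y) / 2))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = NULL,
                       correct = TRUE)
  )
  list(p = min(1, wt$p.value), U = unname(wt$statistic))
}

#' Fisher's combined probability
#'
#' Combines independent p-values via `X2 = -2 * sum(log(p))` against a
#' chi-squared distribution with `2k` degrees of freedom. A single p-value
#' is returned unchanged (the k = 1 case is exact).
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return the combined p-value.
#' @export
fisher_combine <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (!length(pvals)) return(NA_real_)
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  if (any(pvals == 0)) {
    warning("p-value of 0 clamped to smallest positive double")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  x2 <- -2 * sum(log(pvals))
  stats::pchisq(x2, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR within strata
#'
#' BH step-up adjustment applied independently within each stratum
#' (in the pipeline: data type x tissue), so that e.g. adipose genes and
#' ASVs never share one correction.
#'
#' @param pvals numeric vector of p-values.
#' @param stratum vector (or data.frame of columns pasted together) of
#'   stratum labels, same length as `pvals`.
#' @return vector of FDR values aligned with `pvals`.
#' @export
bh_fdr <- function(pvals, stratum) {
  if (is.data.frame(stratum))
    stratum <- do.call(paste, c(stratum, sep = "\r"))
  stopifnot(length(stratum) == length(pvals))
  out <- rep(NA_real_, length(pvals))
  for (s in split(seq_along(pvals), stratum)) {
    out[s] <- stats::p.adjust(pvals[s], method = "BH")
  }
  out
}

#' Per-feature differential statistics for the three study comparisons
#'
#' For every feature, computes the log2 fold change, two-tailed
#' Mann-Whitney p, Fisher-combined p (degenerate to the Mann-Whitney p in a
#' single-cohort design) and stratified BH FDR for each of the three
#' comparisons: disease vs control, treatment_a vs disease, treatment_b vs
#' disease.
#'
#' Fold changes are computed on the table's normalized scale: for
#' log2-scale tables (`normalized_state == "log2"`) as the difference of
#' group means; otherwise as `log2(mean_1 / mean_2)` of group means.
#'
#' @param table a normalized [omics_table()] containing the four groups.
#' @param groups named character vector mapping roles to group labels,
#'   `c(control=, disease=, treatment_a=, treatment_b=)`.
#' @param cohort optional vector of cohort/batch labels per sample; when
#'   present, Mann-Whitney tests are run per cohort and combined with
#'   Fisher's method.
#' @return data.frame with one row per feature x comparison: `feature_id`,
#'   `data_type`, `tissue`, `comparison`, `log2fc`, `mw_p`, `combined_p`,
#'   `fdr`, `direction`.
#' @export
differential_stats <- function(table, groups = default_groups(),
                               cohort = NULL) {
  stopifnot(inherits(table, "omics_table"))
  m <- table$matrix
  grp <- table$sample_meta$group
  comparisons <- list(
    disease_vs_control = c(groups[["disease"]], groups[["control"]]),
    treatment_a_vs_disease = c(groups[["treatment_a"]], groups[["disease"]]),
    treatment_b_vs_disease = c(groups[["treatment_b"]], groups[["disease"]])
  )
  log_scale <- table$normalized_state == "log2"
  if (is.null(cohort)) cohort <- rep("cohort1", ncol(m))
  rows <- lapply(names(comparisons), function(cmp) {
    g1 <- grp == comparisons[[cmp]][1]
    g2 <- grp == comparisons[[cmp]][2]
    if (!any(g1) || !any(g2)) return(NULL)
    single_cohort <- length(unique(cohort)) == 1L
    res <- t(vapply(seq_len(nrow(m)), function(i) {
      x <- m[i, g1]; y <- m[i, g2]
      mw <- mann_whitney(x, y)$p
      per_cohort <- if (single_cohort) mw else vapply(unique(cohort), function(ch) {
        xi <- m[i, g1 & cohort == ch]; yi <- m[i, g2 & cohort == ch]
        if (length(xi) < 3L || length(yi) < 3L) return(NA_real_)
        mann_whitney(xi, yi)$p
      }, numeric(1))
      p_comb <- fisher_combine(per_cohort)
      lfc <- if (log_scale) mean(x) - mean(y) else {
        if (mean(y) == 0 || mean(x) == 0) {
          # log2 of a zero group mean is undefined; fall back to the sign of
          # the mean difference with an infinite magnitude convention
          sign(mean(x) - mean(y)) * Inf
        } else log2(mean(x) / mean(y))
      }
      c(lfc, mw, p_comb)
    }, numeric(3)))
    data.frame(
      feature_id = rownames(m),
      data_type = table$feature_meta$data_type,
      tissue = table$feature_meta$tissue,
      comparison = cmp,
      log2fc = res[, 1],
      mw_p = res[, 2],
      combined_p = res[, 3],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$mw_p,
                    paste(out$data_type, out$tissue, out$comparison))
  out$direction <- sign(out$log2fc)
  rownames(out) <- NULL
  out
}

#' Default role-to-group mapping for the four-group study design
#'
#' `control` is the low-fat control diet arm, `disease` the high-fat diet
#' arm, and `treatment_a`/`treatment_b` the two supplement arms.
#' @return named character vector.
#' @export
default_groups <- function() {
  c(control = "control", disease = "disease",
    treatment_a = "treatment_a", treatment_b = "treatment_b")
}

#' Four-way treatment-effect classification
#'
#' A feature is network-eligible when its disease-vs-control comparison is
#' significant (p below `alpha_disease` and FDR below `fdr_max`) with a
#' non-zero direction. An eligible feature is "improved" by a treatment
#' when the treatment-vs-disease comparison is significant at `alpha_treat`
#' AND its fold-change direction is opposite to the disease direction.
#' Features are then categorized as improved by treatment a only, b only,
#' both, or neither.
#'
#' @param diff data.frame from [differential_stats()].
#' @param alpha_disease p-value threshold for the disease comparison
#'   (default 0.05).
#' @param alpha_treat p-value threshold for the treatment comparisons
#'   (default 0.05).
#' @param fdr_max FDR threshold for the disease comparison (default 0.1).
#' @return data.frame: `feature_id`, `data_type`, `tissue`, `eligible`,
#'   `disease_direction`, `improved_a`, `improved_b`, `category` in
#'   `{A_improved, B_improved, AB_improved, neither}`.
#' @export
classify_treatment_effect <- function(diff, alpha_disease = 0.05,
                                      alpha_treat = 0.05, fdr_max = 0.1) {
  dd <- diff[diff$comparison == "disease_vs_control", , drop = FALSE]
  w <- dd[, c("feature_id", "data_type", "tissue")]
  get <- function(col, cmp) {
    rows <- diff[diff$comparison == cmp, , drop = FALSE]
    if (!nrow(rows)) return(rep(NA_real_, nrow(w)))
    rows[[col]][match(w$feature_id, rows$feature_id)]
  }
  p_d <- get("mw_p", "disease_vs_control")
  fdr_d <- get("fdr", "disease_vs_control")
  dir_d <- sign(get("log2fc", "disease_vs_control"))
  if (!nrow(w)) stop("disease_vs_control comparison missing")
  eligible <- !is.na(p_d) & p_d < alpha_disease & fdr_d <= fdr_max & dir_d != 0
  improved <- function(cmp) {
    p_t <- get("mw_p", cmp)
    dir_t <- sign(get("log2fc", cmp))
    if (all(is.na(p_t)))
      warning("comparison ", cmp, " missing; treated as not improved")
    !is.na(p_t) & p_t < alpha_treat & dir_t == -dir_d & eligible
  }
  ia <- improved("treatment_a_vs_disease")
  ib <- improved("treatment_b_vs_disease")
  category <- ifelse(ia & ib, "AB_improved",
              ifelse(ia, "A_improved",
              ifelse(ib, "B_improved", "neither")))
  data.frame(
    feature_id = w$feature_id,
    data_type = w$data_type,
    tissue = w$tissue,
    eligible = eligible,
    disease_direction = dir_d,
    improved_a = ia,
    improved_b = ib,
    category = category,
    stringsAsFactors = FALSE
  )
}
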