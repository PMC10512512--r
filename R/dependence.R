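#' Microbiota-dependence quadrant classification
#'
#' Crosses each gene's treatment fold change (treatment_b vs disease) with
#' its microbiota fold change (SPF vs germ-free). Genes significant on
#' both axes are `dependent_reversed` when the two fold changes have
#' opposite signs (the treatment undoes what the microbiota imposes) and
#' `dependent_concordant` when they agree; everything else is
#' `independent`.
#'
#' @param treatment_fc data.frame with `feature_id`, `log2fc`, `mw_p`
#'   (e.g. the treatment_b_vs_disease rows of [differential_stats()]).
#' @param microbiota_fc data.frame with `feature_id`, `log2fc`, `mw_p`
#'   from the GF/SPF comparison.
#' @param alpha significance threshold applied to both axes
#'   (default 0.05, strict).
#' @param require_significance if `FALSE`, the microbiota axis is gated on
#'   sign only (alternative reading of "microbiota-dependent").
#' @return data.frame with `gene_id`, `fc_treatment`, `fc_microbiota`,
#'   `p_treatment`, `p_microbiota`, `quadrant`; attribute `dropped` counts
#'   genes present on only one axis; attribute `fractions` holds the
#'   quadrant shares among treatment-significant genes.
#' @export
classify_quadrants <- function(treatment_fc, microbiota_fc, alpha = 0.05,
                               require_significance = TRUE) {
  shared <- intersect(treatment_fc$feature_id, microbiota_fc$feature_id)
  dropped <- length(union(treatment_fc$feature_id,
                          microbiota_fc$feature_id)) - length(shared)
  ti <- match(shared, treatment_fc$feature_id)
  mi <- match(shared, microbiota_fc$feature_id)
  ft <- treatment_fc$log2fc[ti]; pt <- treatment_fc$mw_p[ti]
  fm <- microbiota_fc$log2fc[mi]; pm <- microbiota_fc$mw_p[mi]
  sig_t <- pt < alpha & ft != 0
  sig_m <- if (require_significance) pm < alpha & fm != 0 else fm != 0
  quadrant <- ifelse(sig_t & sig_m & sign(ft) == -sign(fm),
                     "dependent_reversed",
              ifelse(sig_t & sig_m & sign(ft) == sign(fm),
                     "dependent_concordant", "independent"))
  out <- data.frame(
    gene_id = shared, fc_treatment = ft, fc_microbiota = fm,
    p_treatment = pt, p_microbiota = pm, quadrant = quadrant,
    stringsAsFactors = FALSE
  )
  attr(out, "dropped") <- dropped
  n_sig_t <- sum(sig_t)
  attr(out, "fractions") <- c(
    dependent_reversed = sum(quadrant == "dependent_reversed") /
      max(n_sig_t, 1),
    dependent_concordant = sum(quadrant == "dependent_concordant") /
      max(n_sig_t, 1)
  )
  out
}

#' Overlap of a gene set with a signature
#'
#' Fisher's exact (hypergeometric) test of the overlap between a gene set
#' and a reference signature within a stated universe. Signature members
#' outside the universe are reported and dropped.
#'
#' @param genes character vector (e.g. treatment-improved network genes).
#' @param signature character vector (e.g. an insulin-resistance
#'   macrophage signature).
#' @param universe character vector containing `genes`.
#' @param sided `"one"` (enrichment only, default) or `"two"`.
#' @return list with `n_genes`, `n_signature`, `n_universe`,
#'   `intersection` (member ids), `p`, `odds_ratio`.
#' @export
signature_overlap <- function(genes, signature, universe,
                              sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(signature, universe)
  if (length(outside))
    warning(length(outside), " signature gene(s) outside universe dropped")
  signature <- intersect(signature, universe)
  genes <- intersect(genes, universe)
  hit <- intersect(genes, signature)
  tab <- matrix(c(
    length(hit),
    length(setdiff(genes, signature)),
    length(setdiff(signature, genes)),
    length(universe) - length(union(genes, signature))
  ), 2, 2)
  ft <- stats::fisher.test(tab, alternative = if (sided == "one") "greater"
                                              else "two.sided")
  list(n_genes = length(genes), n_signature = length(signature),
       n_universe = length(universe), intersection = hit,
       p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' In vivo / in vitro concordance classification
#'
#' Labels genes whose response to a microbial stimulus is concordant
#' across two macrophage cell lines (same fold-change sign, each at
#' individual p strictly below `individual_alpha`) and opposite in sign to
#' the in vivo treatment effect - i.e. the microbe induces what the
#' treatment suppresses.
#'
#' @param in_vivo_fc data.frame with `feature_id`, `log2fc`, `mw_p` for
#'   the in vivo treatment comparison.
#' @param in_vitro_fc_by_line named list of data.frames (`feature_id`,
#'   `log2fc`, `p`), one per cell line.
#' @param individual_alpha per-line p threshold (default 0.1, strict).
#' @param in_vivo_alpha p threshold on the in vivo effect (default 0.05).
#' @return data.frame with per-line fold changes and a `classification`
#'   column: `concordant_reversed`, `concordant_same_direction`, or
#'   `not_concordant`.
#' @export
concordance_xy <- function(in_vivo_fc, in_vitro_fc_by_line,
                           individual_alpha = 0.1, in_vivo_alpha = 0.05) {
  if (!length(in_vitro_fc_by_line)) stop("no cell lines supplied")
  if (length(in_vitro_fc_by_line) < 2L)
    warning("single cell line: concordance computed on available lines")
  shared <- Reduce(intersect, c(list(in_vivo_fc$feature_id),
                                lapply(in_vitro_fc_by_line, `[[`,
                                       "feature_id")))
  vv <- in_vivo_fc[match(shared, in_vivo_fc$feature_id), ]
  out <- data.frame(gene_id = shared, fc_in_vivo = vv$log2fc,
                    p_in_vivo = vv$mw_p, stringsAsFactors = FALSE)
  sig <- matrix(NA, length(shared), length(in_vitro_fc_by_line))
  sgn <- matrix(NA_real_, length(shared), length(in_vitro_fc_by_line))
  for (k in seq_along(in_vitro_fc_by_line)) {
    line <- in_vitro_fc_by_line[[k]]
    li <- match(shared, line$feature_id)
    out[[paste0("fc_", names(in_vitro_fc_by_line)[k])]] <- line$log2fc[li]
    sig[, k] <- line$p[li] < individual_alpha
    sgn[, k] <- sign(line$log2fc[li])
  }
  lines_agree <- apply(sgn, 1, function(s) length(unique(s)) == 1L &&
                                            s[1] != 0) &
    apply(sig, 1, all)
  vivo_sig <- vv$mw_p < in_vivo_alpha & vv$log2fc != 0
  out$classification <- ifelse(
    lines_agree & vivo_sig & sign(vv$log2fc) == -sgn[, 1],
    "concordant_reversed",
    ifelse(lines_agree & vivo_sig, "concordant_same_direction",
           "not_concordant")
  )
  out
}
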