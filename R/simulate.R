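#' Configuration for the synthetic multi-omic study
#'
#' Defines the study design emulated by [simulate_study()]: four diet/
#' treatment groups (control low-fat diet, disease high-fat diet, and two
#' supplement arms on the disease background), gene counts for three
#' tissues, microbial ASV counts, bile-acid concentrations and metabolic
#' phenotypes, with planted disease effects, treatment reversals, and a
#' latent causal chain microbe -> adipose genes -> phenotypes.
#'
#' @param n_per_group samples per group (default 10, the analyzed cohort
#'   size).
#' @param groups ordered group labels; position 1 = control, 2 = disease,
#'   3/4 = the two treatments.
#' @param n_genes_per_tissue named counts for the three tissues.
#' @param n_asvs,n_bile_acids,n_phenotypes feature counts per omic.
#' @param frac_disease_affected fraction of features shifted by disease.
#' @param frac_reversed_by_a,frac_reversed_by_b,frac_reversed_by_both
#'   fractions of affected features reversed by each treatment (must sum
#'   to at most 1). Defaults mirror a study where treatment b reverses
#'   most affected features, both together some, and treatment a few.
#' @param effect_size_log2 planted |log2 fold change| of disease effects.
#' @param nb_dispersion negative-binomial dispersion (1/size) for count
#'   features.
#' @param noise_sd log2-scale Gaussian noise sd for all features.
#' @param causal_chain_strength latent-scale correlation planted among the
#'   causal ASV, its mediating adipose genes, and the target phenotypes,
#'   within every group.
#' @param module_cor_strength latent-scale correlation of the background
#'   co-regulation modules (microbial community; host disease module).
#' @param causal_coupling latent-scale correlation strength of the causal
#'   ASV's own two-factor loading (at least `causal_chain_strength`).
#' @param causal_bloom multiplier on `effect_size_log2` for the causal
#'   ASV's disease shift (the bottleneck taxon blooms strongly).
#' @param n_chain_genes,n_target_phenotypes size of the planted chain.
#' @param seed RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 10L,
                       groups = c("control", "disease",
                                  "treatment_a", "treatment_b"),
                       n_genes_per_tissue = c(adipose = 200L, liver = 40L,
                                              ileum = 40L),
                       n_asvs = 50L,
                       n_bile_acids = 27L,
                       n_phenotypes = 10L,
                       frac_disease_affected = 0.4,
                       frac_reversed_by_a = 0.05,
                       frac_reversed_by_b = 0.5,
                       frac_reversed_by_both = 0.1,
                       effect_size_log2 = 2,
                       nb_dispersion = 0.02,
                       noise_sd = 0.25,
                       causal_chain_strength = 0.9,
                       module_cor_strength = 0.9,
                       causal_coupling = 0.97,
                       causal_bloom = 1.5,
                       n_chain_genes = 12L,
                       n_target_phenotypes = 3L,
                       seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(frac_disease_affected, frac_reversed_by_a, frac_reversed_by_b,
             frac_reversed_by_both, causal_chain_strength,
             module_cor_strength, causal_coupling)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions and correlation strengths must lie in [0, 1]")
  if (frac_reversed_by_a + frac_reversed_by_b + frac_reversed_by_both > 1)
    stop("reversal fractions sum above 1: infeasible configuration")
  if (n_per_group < 3L)
    stop("n_per_group must be >= 3 (rank tests degenerate below)")
  if (!is.finite(effect_size_log2)) stop("effect size must be finite")
  if (length(groups) != 4L) stop("exactly four group labels required")
  structure(cfg, class = "sim_config")
}

# latent loading giving correlation `strength` between two features with
# loading b and residual log-scale noise `noise_sd`: r = b^2 / (b^2 + sd^2)
.loading <- function(strength, noise_sd) {
  noise_sd * sqrt(strength / (1 - strength))
}

#' Simulate the multi-omic study with planted ground truth
#'
#' Generates one feature-by-sample table per data type. Counts (genes,
#' ASVs) are negative binomial around log-normal group means; bile acids
#' and phenotypes are log-normal. A configurable fraction of features is
#' shifted by +/- `effect_size_log2` in the disease group (persisting in
#' the treatment arms, which share the disease background), and subsets of
#' those are reversed back to control level in treatment arm a, b, or
#' both. Three per-sample latent factors plant within-group correlation
#' structure: a microbial community factor over affected ASVs, a host
#' disease module over affected adipose genes and bile acids, and the
#' causal chain linking one "bottleneck" ASV to its mediating adipose
#' genes and the affected phenotypes (systemic phenotypes are downstream
#' endpoints of the chain). The community and chain factors meet only in
#' the causal ASV, which makes it the planted topological bottleneck
#' between microbiota and phenotypes.
#'
#' @param config a [sim_config()].
#' @return list with `tables` (named list of raw `omics_table`s: adipose,
#'   liver, ileum, asv, bile_acid, phenotype) and `truth`
#'   (class `synthetic_truth`): affected features with directions and
#'   reversal assignment, planted four-way category labels, the causal
#'   ASV, chain members, target phenotypes, planted signed edges, seed.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  grp_roles <- c("control", "disease", "treatment_a", "treatment_b")
  groups <- rep(config$groups, each = config$n_per_group)
  n_samp <- length(groups)
  samples <- sprintf("s%02d", seq_len(n_samp))

  tissues <- names(config$n_genes_per_tissue)
  feat <- rbind(
    do.call(rbind, lapply(tissues, function(ts) {
      n <- config$n_genes_per_tissue[[ts]]
      if (n == 0L) return(NULL)
      data.frame(feature_id = sprintf("gene_%s_%03d", ts, seq_len(n)),
                 data_type = "gene", tissue = ts, stringsAsFactors = FALSE)
    })),
    data.frame(feature_id = sprintf("asv_%03d", seq_len(config$n_asvs)),
               data_type = "asv", tissue = NA, stringsAsFactors = FALSE),
    data.frame(feature_id = sprintf("ba_%02d", seq_len(config$n_bile_acids)),
               data_type = "bile_acid", tissue = NA, stringsAsFactors = FALSE),
    data.frame(feature_id = sprintf("pheno_%02d", seq_len(config$n_phenotypes)),
               data_type = "phenotype", tissue = NA, stringsAsFactors = FALSE)
  )
  nf <- nrow(feat)

  # --- plant disease effects -------------------------------------------------
  direction <- integer(nf)
  type_key <- ifelse(feat$data_type == "gene",
                     paste0("gene_", feat$tissue), feat$data_type)
  affected <- logical(nf)
  for (k in unique(type_key)) {
    idx <- which(type_key == k)
    n_aff <- round(config$frac_disease_affected * length(idx))
    hit <- sample(idx, n_aff)
    affected[hit] <- TRUE
    # balanced up/down shifts: on the relative-abundance scale the library
    # renormalization would otherwise swamp one-sided planted effects
    direction[hit] <- sample(rep(c(-1L, 1L), length.out = n_aff))
  }

  # --- causal chain membership ----------------------------------------------
  has_chain <- config$frac_disease_affected > 0 &&
    config$n_asvs >= 1L && config$n_genes_per_tissue[["adipose"]] >=
      config$n_chain_genes && config$n_phenotypes >= config$n_target_phenotypes
  causal_node <- chain_members <- target_phenotypes <- character(0)
  if (has_chain) {
    asv_idx <- which(feat$data_type == "asv")
    adi_idx <- which(type_key == "gene_adipose")
    phe_idx <- which(feat$data_type == "phenotype")
    ci <- asv_idx[1]
    gi <- adi_idx[seq_len(config$n_chain_genes)]
    forced_pi <- phe_idx[seq_len(config$n_target_phenotypes)]
    # chain members are forcibly disease-affected; the causal microbe blooms
    # (+1) in disease, like the bottleneck taxon it emulates
    new_pi <- forced_pi[!affected[forced_pi]]
    affected[c(ci, gi, forced_pi)] <- TRUE
    direction[ci] <- 1L
    direction[gi] <- sample(c(-1L, 1L), length(gi), replace = TRUE)
    direction[new_pi] <- sample(c(-1L, 1L), length(new_pi), replace = TRUE)
    # every disease-affected phenotype is a downstream endpoint of the chain:
    # systemic phenotypes respond to the causal microbe, not independently
    pi <- which(affected & feat$data_type == "phenotype")
    causal_node <- feat$feature_id[ci]
    chain_members <- feat$feature_id[gi]
    target_phenotypes <- feat$feature_id[pi]
  }

  # --- reversal assignment ---------------------------------------------------
  reversed_by <- rep("none", nf)
  if (has_chain) reversed_by[affected & feat$feature_id %in%
                             c(causal_node, chain_members,
                               target_phenotypes)] <- "b"
  free <- which(affected & reversed_by == "none")
  n_free <- length(free)
  if (n_free) {
    n_a <- round(config$frac_reversed_by_a * n_free)
    n_b <- round(config$frac_reversed_by_b * n_free)
    n_ab <- round(config$frac_reversed_by_both * n_free)
    pool <- sample(free)
    take <- function(n) {
      out <- utils::head(pool, n); pool <<- utils::tail(pool, -n); out
    }
    reversed_by[take(n_a)] <- "a"
    reversed_by[take(n_b)] <- "b"
    reversed_by[take(n_ab)] <- "both"
  }

  # --- latent factors and loadings ------------------------------------------
  # three per-sample latent factors, made exactly orthogonal (and centered,
  # unit-variance) within every group: at n = 10 per group the realized
  # correlation of independently drawn factors fluctuates by about 1/3,
  # which would leak transitive community-host correlations through the
  # causal node and blur the planted conditional-independence structure
  fac <- matrix(stats::rnorm(n_samp * 3L), n_samp, 3L)
  if (config$n_per_group > 4L) {
    for (grp_lab in unique(groups)) {
      sel <- groups == grp_lab
      block <- scale(fac[sel, , drop = FALSE], center = TRUE, scale = FALSE)
      dec <- qr(block)
      if (dec$rank == 3L) {
        q <- qr.Q(dec)
        # keep each factor's original orientation within the group
        ss <- sign(colSums(q * block)); ss[ss == 0] <- 1
        fac[sel, ] <- sweep(q, 2, ss / apply(q, 2, stats::sd), "*")
      }
    }
  }
  u <- fac[, 1]  # causal chain
  v <- fac[, 2]  # microbial community module
  w <- fac[, 3]  # host disease module
  b_u <- .loading(config$causal_chain_strength, config$noise_sd)
  b_m <- .loading(config$module_cor_strength, config$noise_sd)
  load_u <- load_v <- load_w <- numeric(nf)
  if (has_chain) {
    ci <- match(causal_node, feat$feature_id)
    gi <- match(chain_members, feat$feature_id)
    pi <- match(target_phenotypes, feat$feature_id)
    # the causal microbe straddles the community and chain factors at full
    # strength (u + v)/sqrt(2), making it the sole articulation point
    # between the microbial community and the host chain
    load_u[c(gi, pi)] <- b_u * direction[c(gi, pi)]
    b_c <- .loading(max(config$causal_chain_strength,
                        config$causal_coupling), config$noise_sd)
    load_u[ci] <- b_c * direction[ci] / sqrt(2)
    load_v[ci] <- b_c * direction[ci] / sqrt(2)
    comm <- setdiff(which(affected & feat$data_type == "asv"), ci)
    load_v[comm] <- b_m * direction[comm]
    host <- setdiff(
      which(affected & (type_key == "gene_adipose" |
                        feat$data_type == "bile_acid")),
      c(ci, gi)
    )
    load_w[host] <- b_m * direction[host]
  }

  # --- group mean shifts -----------------------------------------------------
  role_of <- stats::setNames(grp_roles, config$groups)
  shift <- matrix(0, nf, n_samp)
  eff <- config$effect_size_log2 * direction
  if (has_chain) {
    # the bottleneck taxon blooms strongly under the disease diet; the
    # larger shift also keeps its rank-test power high despite the extra
    # variance its two-factor loading carries
    eff[match(causal_node, feat$feature_id)] <-
      config$causal_bloom * config$effect_size_log2 *
        direction[match(causal_node, feat$feature_id)]
  }
  for (j in seq_len(n_samp)) {
    role <- role_of[[groups[j]]]
    on <- switch(role,
      control = FALSE,
      disease = affected,
      treatment_a = affected & !reversed_by %in% c("a", "both"),
      treatment_b = affected & !reversed_by %in% c("b", "both")
    )
    shift[, j] <- ifelse(on, eff, 0)
  }

  # --- assemble log2-scale latent means and draw observations ---------------
  # wide log2 abundance ranges, as in real transcriptomes/16S libraries;
  # they also keep shifted features interleaved with static ones so that
  # quantile normalization has rank crossings to preserve signal through
  base <- ifelse(feat$data_type == "gene", stats::runif(nf, 3, 12),
          ifelse(feat$data_type == "asv", stats::runif(nf, 3, 11),
                 stats::runif(nf, 1, 5)))
  if (has_chain) {
    # chain members sit mid-range: a shifted feature already at the edge of
    # the abundance distribution saturates the quantile-normalization grid
    # (it keeps the top/bottom rank in every group), which would erase the
    # very effects the chain is meant to carry
    base[match(causal_node, feat$feature_id)] <- stats::runif(1, 5.5, 6.5)
    base[match(chain_members, feat$feature_id)] <-
      stats::runif(length(chain_members), 6.5, 8)
  }
  latent <- base + shift +
    outer(load_u, u) + outer(load_v, v) + outer(load_w, w) +
    matrix(stats::rnorm(nf * n_samp, sd = config$noise_sd), nf, n_samp)
  is_count <- feat$data_type %in% c("gene", "asv")
  vals <- matrix(0, nf, n_samp, dimnames = list(feat$feature_id, samples))
  vals[is_count, ] <- matrix(
    stats::rnbinom(sum(is_count) * n_samp, mu = 2^latent[is_count, ],
                   size = 1 / config$nb_dispersion),
    sum(is_count), n_samp
  )
  vals[!is_count, ] <- 2^latent[!is_count, ]

  tables <- list(
    adipose = which(type_key == "gene_adipose"),
    liver = which(type_key == "gene_liver"),
    ileum = which(type_key == "gene_ileum"),
    asv = which(feat$data_type == "asv"),
    bile_acid = which(feat$data_type == "bile_acid"),
    phenotype = which(feat$data_type == "phenotype")
  )
  tables <- tables[vapply(tables, length, 1L) > 0]
  tables <- lapply(tables, function(idx) {
    omics_table(vals[idx, , drop = FALSE],
                data_type = feat$data_type[idx],
                tissue = feat$tissue[idx], group = groups)
  })

  # --- truth record ----------------------------------------------------------
  category <- ifelse(!affected, "neither",
              ifelse(reversed_by == "a", "A_improved",
              ifelse(reversed_by == "b", "B_improved",
              ifelse(reversed_by == "both", "AB_improved", "neither"))))
  pair_edges <- function(ids, dirs, module) {
    if (length(ids) < 2) return(NULL)
    p <- utils::combn(seq_along(ids), 2)
    data.frame(node_i = ids[p[1, ]], node_j = ids[p[2, ]],
               sign = dirs[p[1, ]] * dirs[p[2, ]], module = module,
               stringsAsFactors = FALSE)
  }
  u_ids <- c(causal_node, chain_members, target_phenotypes)
  v_ids <- feat$feature_id[load_v != 0 | feat$feature_id == causal_node]
  w_ids <- feat$feature_id[load_w != 0]
  dirs <- stats::setNames(direction, feat$feature_id)
  planted_edges <- rbind(
    pair_edges(u_ids, dirs[u_ids], "chain"),
    pair_edges(v_ids, dirs[v_ids], "community"),
    pair_edges(w_ids, dirs[w_ids], "host_module")
  )
  truth <- structure(list(
    affected_features = data.frame(
      feature_id = feat$feature_id[affected],
      data_type = feat$data_type[affected],
      direction = direction[affected],
      reversed_by = reversed_by[affected],
      stringsAsFactors = FALSE
    ),
    category_labels = data.frame(
      feature_id = feat$feature_id, category = category,
      stringsAsFactors = FALSE
    ),
    causal_node = causal_node,
    chain_members = chain_members,
    target_phenotypes = target_phenotypes,
    planted_edges = planted_edges,
    seed = config$seed
  ), class = "synthetic_truth")
  list(tables = tables, truth = truth)
}

#' Simulate a germ-free vs SPF expression table
#'
#' Two-group (GF, SPF) adipose gene expression counts in which the chain
#' members are shifted in SPF relative to GF with sign opposite to their
#' planted treatment-b effect: the microbiota pushes these genes in the
#' disease direction, and the treatment reverses it, which makes them
#' "microbiota-dependent in the opposing direction".
#'
#' @param config the [sim_config()] used for the study.
#' @param truth the matching `synthetic_truth`.
#' @return an `omics_table` of raw counts with groups `GF` and `SPF`.
#' @export
simulate_gf_spf <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "synthetic_truth"))
  set.seed(config$seed + 1L)
  n_genes <- config$n_genes_per_tissue[["adipose"]]
  ids <- sprintf("gene_adipose_%03d", seq_len(n_genes))
  groups <- rep(c("GF", "SPF"), each = config$n_per_group)
  samples <- sprintf("gf%02d", seq_along(groups))
  base <- stats::runif(n_genes, 4, 9)
  shift <- numeric(n_genes)
  if (length(truth$chain_members)) {
    gi <- match(truth$chain_members, ids)
    dir_disease <- truth$affected_features$direction[
      match(truth$chain_members, truth$affected_features$feature_id)]
    # treatment-b log2FC is -dir_disease; SPF/GF effect is its opposite
    shift[gi] <- config$effect_size_log2 * dir_disease
  }
  latent <- base + outer(shift, as.numeric(groups == "SPF")) +
    matrix(stats::rnorm(n_genes * length(groups), sd = config$noise_sd),
           n_genes, length(groups))
  m <- matrix(
    stats::rnbinom(length(latent), mu = 2^latent,
                   size = 1 / config$nb_dispersion),
    n_genes, length(groups), dimnames = list(ids, samples)
  )
  omics_table(m, data_type = "gene", tissue = "adipose", group = groups)
}

#' Simulate a single-cell cluster marker table
#'
#' Per-gene, per-cluster marker statistics (mean expression, log2 fold
#' change cluster vs all other cells, rank-test p) for the adipose genes,
#' with the chain members planted as markers of the myeloid cluster
#' (log2FC > 0.25 and p < 0.05 by construction, and maximal average
#' expression there). A share of the remaining genes are markers of random
#' clusters; the rest qualify nowhere.
#'
#' @param config the [sim_config()] used for the study.
#' @param truth the matching `synthetic_truth`.
#' @param clusters cluster labels (first is used for planted markers only
#'   if it is `"myeloid"`, which the default guarantees).
#' @return data.frame with `gene_id`, `cluster_id`, `avg_expr`, `log2fc`,
#'   `p`.
#' @export
simulate_marker_table <- function(config, truth,
                                  clusters = c("myeloid", "adipocyte",
                                               "endothelial", "tcell",
                                               "stromal")) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "synthetic_truth"))
  set.seed(config$seed + 2L)
  n_genes <- config$n_genes_per_tissue[["adipose"]]
  ids <- sprintf("gene_adipose_%03d", seq_len(n_genes))
  nc <- length(clusters)
  out <- expand.grid(gene_id = ids, cluster_id = clusters,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$avg_expr <- stats::runif(nrow(out), 0.1, 1)
  out$log2fc <- stats::rnorm(nrow(out), 0, 0.08)
  out$p <- stats::runif(nrow(out), 0.1, 1)
  set_row <- function(gene, cluster, avg, fc, p) {
    i <- out$gene_id == gene & out$cluster_id == cluster
    out$avg_expr[i] <<- avg; out$log2fc[i] <<- fc; out$p[i] <<- p
  }
  # random genuine markers among the non-chain genes
  others <- setdiff(ids, truth$chain_members)
  marked <- sample(others, round(0.5 * length(others)))
  for (gene in marked) {
    cl <- sample(clusters, 1)
    set_row(gene, cl, stats::runif(1, 2, 5), stats::runif(1, 0.5, 2),
            stats::runif(1, 1e-6, 0.01))
  }
  for (gene in truth$chain_members) {
    set_row(gene, "myeloid", stats::runif(1, 3, 6),
            stats::runif(1, 0.5, 1.5), stats::runif(1, 1e-8, 1e-3))
  }
  out
}
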