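#' Feature-by-sample omics table
#'
#' The basic container used throughout the package: a numeric feature x
#' sample matrix plus feature metadata (data type, tissue) and sample
#' metadata (group label). The `normalized_state` field records how far the
#' table has moved along the normalization chain
#' raw -> cpm -> quantile -> log2 (counts) or raw -> median (continuous),
#' and transitions are only allowed forward.
#'
#' @param matrix numeric matrix, features in rows, samples in columns; both
#'   dimnames must be set.
#' @param data_type one of `"gene"`, `"asv"`, `"bile_acid"`, `"phenotype"`,
#'   recycled across features, or a vector of per-feature types.
#' @param tissue tissue label for genes (`NA` for other data types);
#'   recycled.
#' @param group factor or character vector of group labels, one per sample.
#' @param normalized_state one of `"raw"`, `"cpm"`, `"quantile"`, `"log2"`,
#'   `"median"`.
#' @return an object of class `omics_table`: a list with elements `matrix`,
#'   `feature_meta` (data.frame: feature_id, data_type, tissue),
#'   `sample_meta` (data.frame: sample_id, group) and `normalized_state`.
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ot <- omics_table(m, "gene", tissue = "adipose",
#'                   group = rep(c("control", "disease"), each = 2))
#' ot
#' @export
omics_table <- function(matrix, data_type, tissue = NA_character_, group,
                        normalized_state = "raw") {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("`matrix` must have row (feature) and column (sample) names")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate feature ids in table")
  if (length(group) != ncol(matrix))
    stop("`group` must have one label per sample")
  data_type <- rep_len(as.character(data_type), nrow(matrix))
  bad <- setdiff(unique(data_type), c("gene", "asv", "bile_acid", "phenotype"))
  if (length(bad))
    stop("unknown data_type: ", paste(bad, collapse = ", "))
  state_levels <- c("raw", "cpm", "quantile", "log2", "median")
  normalized_state <- match.arg(normalized_state, state_levels)
  if (normalized_state == "raw" && any(matrix < 0))
    stop("raw tables must be non-negative")
  structure(list(
    matrix = matrix,
    feature_meta = data.frame(
      feature_id = rownames(matrix),
      data_type = data_type,
      tissue = rep_len(as.character(tissue), nrow(matrix)),
      stringsAsFactors = FALSE
    ),
    sample_meta = data.frame(
      sample_id = colnames(matrix),
      group = as.character(group),
      stringsAsFactors = FALSE
    ),
    normalized_state = normalized_state
  ), class = "omics_table")
}

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf(
    "omics_table: %d features x %d samples [%s]\n",
    nrow(x$matrix), ncol(x$matrix), x$normalized_state
  ))
  tt <- table(x$feature_meta$data_type)
  cat("  data types:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  gg <- table(x$sample_meta$group)
  cat("  groups:    ", paste(sprintf("%s=%d", names(gg), gg), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.omics_table <- function(x) dim(x$matrix)

# internal: advance the normalization state, enforcing forward-only moves
.advance_state <- function(table, to) {
  order <- c(raw = 1L, cpm = 2L, quantile = 3L, log2 = 4L, median = 5L)
  # median normalization is a separate branch for continuous data: raw -> median
  if (to == "median") {
    if (!table$normalized_state %in% c("raw", "median"))
      stop("median normalization applies to raw continuous tables, got state '",
           table$normalized_state, "'")
  } else if (order[[to]] < order[[table$normalized_state]] ||
             table$normalized_state == "median") {
    stop("normalization state may only move forward (",
         table$normalized_state, " -> ", to, " not allowed)")
  }
  table$normalized_state <- to
  table
}

#' Subset an omics table by feature and/or sample
#'
#' @param table an [omics_table()].
#' @param features character vector of feature ids (default: all).
#' @param samples character vector of sample ids (default: all).
#' @return the subset `omics_table`.
#' @export
subset_table <- function(table, features = NULL, samples = NULL) {
  stopifnot(inherits(table, "omics_table"))
  fi <- if (is.null(features)) seq_len(nrow(table$matrix)) else
    match(features, table$feature_meta$feature_id)
  si <- if (is.null(samples)) seq_len(ncol(table$matrix)) else
    match(samples, table$sample_meta$sample_id)
  if (anyNA(fi)) stop("unknown feature ids")
  if (anyNA(si)) stop("unknown sample ids")
  table$matrix <- table$matrix[fi, si, drop = FALSE]
  table$feature_meta <- table$feature_meta[fi, , drop = FALSE]
  table$sample_meta <- table$sample_meta[si, , drop = FALSE]
  rownames(table$feature_meta) <- NULL
  rownames(table$sample_meta) <- NULL
  table
}

#' Bind omics tables that share the same samples
#'
#' Stacks features from several tables (e.g., the per-omic tables of a
#' study) over a common sample set; group labels must agree.
#'
#' @param ... `omics_table` objects with identical sample columns.
#' @return one combined `omics_table`; `normalized_state` is set to the
#'   first table's state (the caller is responsible for combining tables at
#'   comparable normalization stages).
#' @export
bind_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !inherits(tabs[[1]], "omics_table"))
    tabs <- tabs[[1]]
  stopifnot(length(tabs) >= 1L, all(vapply(tabs, inherits, TRUE, "omics_table")))
  ref <- tabs[[1]]$sample_meta
  for (t in tabs[-1]) {
    if (!identical(t$sample_meta$sample_id, ref$sample_id) ||
        !identical(t$sample_meta$group, ref$group))
      stop("tables do not share identical samples/groups")
  }
  out <- tabs[[1]]
  out$matrix <- do.call(rbind, lapply(tabs, `[[`, "matrix"))
  out$feature_meta <- do.call(rbind, lapply(tabs, `[[`, "feature_meta"))
  if (anyDuplicated(out$feature_meta$feature_id))
    stop("duplicate feature ids across bound tables")
  rownames(out$feature_meta) <- NULL
  out
}

#' Read / write the package's TSV conventions
#'
#' Tables are written as one TSV per data matrix (features in rows, samples
#' in columns, first column `feature_id`), alongside a sample-metadata TSV
#' (`sample_id`, `group`) and a feature-metadata TSV (`feature_id`,
#' `data_type`, `tissue`).
#'
#' @param table an [omics_table()].
#' @param prefix path prefix; writes `<prefix>_matrix.tsv`,
#'   `<prefix>_samples.tsv`, `<prefix>_features.tsv`.
#' @return (`write_omics_tsv`) the prefix, invisibly; (`read_omics_tsv`)
#'   an `omics_table`.
#' @export
write_omics_tsv <- function(table, prefix) {
  stopifnot(inherits(table, "omics_table"))
  m <- data.frame(feature_id = rownames(table$matrix), table$matrix,
                  check.names = FALSE)
  utils::write.table(m, paste0(prefix, "_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(table$sample_meta, paste0(prefix, "_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$feature_meta, paste0(prefix, "_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_omics_tsv
#' @param normalized_state state to stamp on the table read back.
#' @export
read_omics_tsv <- function(prefix, normalized_state = "raw") {
  m <- utils::read.table(paste0(prefix, "_matrix.tsv"), sep = "\t",
                         header = TRUE, check.names = FALSE)
  sm <- utils::read.table(paste0(prefix, "_samples.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  fm <- utils::read.table(paste0(prefix, "_features.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  mat <- as.matrix(m[, -1, drop = FALSE])
  rownames(mat) <- m[[1]]
  omics_table(mat, data_type = fm$data_type, tissue = fm$tissue,
              group = sm$group[match(colnames(mat), sm$sample_id)],
              normalized_state = normalized_state)
}
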