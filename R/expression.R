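#' Expression matrix container
#'
#' A light S3 wrapper around a genes x samples numeric matrix of (log-)TPM
#' values. Row names are locus tags, column names are sample identifiers.
#' `is_centered` records whether reference-condition centering has been
#' applied; several downstream steps (ICA, explained variance) require a
#' centered matrix.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names.
#' @param is_centered logical; has [batch_center()] been applied?
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, is_centered = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id in expression matrix")
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite values")
  structure(list(values = values, is_centered = isTRUE(is_centered)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_centered) "centered" else "not centered"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read a genes x samples expression table
#'
#' Expects TSV/CSV with one header row of sample ids and a first column of
#' gene locus tags. Set `transposed = TRUE` when the file stores samples in
#' rows and genes in columns; the returned object is always genes x samples.
#'
#' @param path file path (delimiter inferred from content by data.table).
#' @param transposed logical; file stores samples in rows.
#' @param is_centered logical flag to set on the result (e.g. when reading a
#'   previously centered matrix back in).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, transposed = FALSE, is_centered = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  dt <- data.table::fread(path, header = TRUE)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene id in ", path)
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in ", path)
  rownames(m) <- ids
  if (transposed) m <- t(m)
  expression_matrix(m, is_centered = is_centered)
}

#' Write an expression matrix as TSV
#' @param x an `expr_matrix`.
#' @param path output file.
#' @param id_col name for the first (gene id) column.
#' @export
write_expression <- function(x, path, id_col = "gene_id") {
  dt <- data.table::data.table(id = rownames(x$values))
  data.table::setnames(dt, "id", id_col)
  out <- cbind(dt, data.table::as.data.table(x$values))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read sample metadata
#'
#' CSV/TSV with columns sample_id, project_id, condition, is_reference
#' (true/false) and optionally replicate_group.
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  meta <- as.data.frame(data.table::fread(path, header = TRUE))
  validate_metadata(meta)
}

validate_metadata <- function(meta, x = NULL) {
  need <- c("sample_id", "project_id", "condition", "is_reference")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (is.character(meta$is_reference))
    meta$is_reference <- tolower(meta$is_reference) %in% c("true", "t", "1", "yes")
  meta$is_reference <- as.logical(meta$is_reference)
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (!is.null(x)) {
    absent <- setdiff(sample_ids(x), meta$sample_id)
    if (length(absent))
      stop("sample without metadata: ", paste(utils::head(absent, 5), collapse = ", "))
  }
  meta
}

#' log10(TPM + 1) transform
#'
#' The pipeline's working unit: raw TPM values are mapped through
#' v -> log10(v + 1), a monotone, order-preserving transform that keeps
#' zeros at zero.
#'
#' @param x `expr_matrix` of raw TPM (all entries >= 0).
#' @return `expr_matrix` of log-TPM.
#' @export
tpm_to_logtpm <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (any(x$values < 0)) stop("negative TPM entry")
  expression_matrix(log10(x$values + 1), is_centered = FALSE)
}

#' Inverse of [tpm_to_logtpm()]
#' @param x `expr_matrix` of log10(TPM+1) values.
#' @return `expr_matrix` of raw TPM.
#' @export
logtpm_to_tpm <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  expression_matrix(10^x$values - 1, is_centered = FALSE)
}

#' Center expression to per-project reference conditions
#'
#' For each project the per-gene mean over that project's reference samples
#' is subtracted from all of that project's samples, removing batch offsets
#' while anchoring every experiment to its own control condition.
#'
#' @param x `expr_matrix` of log-TPM.
#' @param meta metadata data.frame (see [read_sample_metadata()]).
#' @return Centered `expr_matrix` (`is_centered = TRUE`).
#' @export
batch_center <- function(x, meta) {
  stopifnot(inherits(x, "expr_matrix"))
  meta <- validate_metadata(meta, x)
  v <- x$values
  for (proj in unique(meta$project_id)) {
    proj_samples <- meta$sample_id[meta$project_id == proj]
    proj_samples <- intersect(proj_samples, colnames(v))
    if (!length(proj_samples)) next
    ref <- meta$sample_id[meta$project_id == proj & meta$is_reference]
    ref <- intersect(ref, colnames(v))
    if (!length(ref)) stop("project with no reference sample: ", proj)
    ref_mean <- rowMeans(v[, ref, drop = FALSE])
    v[, proj_samples] <- v[, proj_samples, drop = FALSE] - ref_mean
  }
  expression_matrix(v, is_centered = TRUE)
}

#' Pearson correlation between two gene expression profiles
#'
#' @param x `expr_matrix`.
#' @param gene_a,gene_b locus tags present in `x`.
#' @return Pearson correlation across all samples, in [-1, 1].
#' @export
gene_correlation <- function(x, gene_a, gene_b) {
  stopifnot(inherits(x, "expr_matrix"))
  for (g in c(gene_a, gene_b))
    if (!g %in% gene_ids(x)) stop("unknown gene: ", g)
  a <- x$values[gene_a, ]
  b <- x$values[gene_b, ]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance gene")
  stats::cor(a, b)
}

#' Per-gene log fold change between two sample groups
#'
#' Difference of per-gene group means on the log scale (no shrinkage or
#' dispersion model): the in-scope use is comparing fold-change profiles,
#' not calling differential genes from counts. With `base = 2` the log10
#' difference is rescaled to log2 units by the factor log2(10).
#'
#' @param x `expr_matrix` of log10-scale expression.
#' @param group_a,group_b disjoint, non-empty character vectors of sample ids.
#' @param base 10 (native) or 2 (report in log2 units).
#' @return Named per-gene numeric vector.
#' @export
log_fold_change <- function(x, group_a, group_b, base = 10) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!length(group_a) || !length(group_b)) stop("empty group")
  if (length(intersect(group_a, group_b))) stop("overlapping groups")
  absent <- setdiff(c(group_a, group_b), sample_ids(x))
  if (length(absent)) stop("unknown sample: ", paste(absent, collapse = ", "))
  lfc <- rowMeans(x$values[, group_a, drop = FALSE]) -
    rowMeans(x$values[, group_b, drop = FALSE])
  if (base == 2) lfc <- lfc * log2(10)
  lfc
}
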