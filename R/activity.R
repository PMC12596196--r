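# Working with the activity matrix A: each row tracks one module's inferred
# regulatory signal across samples and is treated as a proxy for its
# regulator's condition-dependent activity.

#' Hierarchically cluster activity rows (Euclidean distance, Ward linkage)
#'
#' @param A components x samples activity matrix (>= 2 rows).
#' @param k optional number of flat clusters to cut.
#' @param h optional cut height (used when `k` is NULL).
#' @return List: `hclust` (the tree), `labels` (flat cluster labels, NULL if
#'   no cut requested), `newick` (serialized tree).
#' @export
cluster_activity_rows <- function(A, k = NULL, h = NULL) {
  if (!is.matrix(A) || nrow(A) < 2) stop("need at least 2 activity rows")
  if (is.null(rownames(A))) rownames(A) <- sprintf("IC%02d", seq_len(nrow(A)))
  hc <- stats::hclust(stats::dist(A, method = "euclidean"), method = "ward.D2")
  labels <- NULL
  if (!is.null(k)) labels <- stats::cutree(hc, k = k)
  else if (!is.null(h)) labels <- stats::cutree(hc, h = h)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, labels = labels, newick = newick)
}

#' Differential activity of one module between two condition groups
#'
#' delta = mean(group_a) - mean(group_b) with a two-sample independent
#' t-test p-value (Welch by default; set `var_equal = TRUE` for the pooled
#' test). No multiple-testing correction is applied here; batch callers
#' adjust with [fdr_adjust()].
#'
#' @param activities named per-sample activity vector (one row of A).
#' @param group_a,group_b disjoint sample-id sets, each of size >= 2.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return List: `delta`, `p_value`, `t`, `df`.
#' @export
differential_activity <- function(activities, group_a, group_b,
                                  var_equal = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 samples")
  if (length(intersect(group_a, group_b))) stop("overlapping groups")
  absent <- setdiff(c(group_a, group_b), names(activities))
  if (length(absent)) stop("unknown sample: ", paste(absent, collapse = ", "))
  a <- activities[group_a]
  b <- activities[group_b]
  delta <- mean(a) - mean(b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate constant groups: identical means are maximally consistent
    return(list(delta = delta, p_value = if (delta == 0) 1 else 0,
                t = if (delta == 0) 0 else Inf, df = NA_real_))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(delta = delta, p_value = tt$p.value,
       t = unname(tt$statistic), df = unname(tt$parameter))
}

#' Differential activity of all modules between two groups
#'
#' @param A components x samples activity matrix.
#' @param group_a,group_b disjoint sample-id sets.
#' @param var_equal pooled t-test flag.
#' @return data.frame: component_id, delta, p_value, q_value.
#' @export
differential_activity_all <- function(A, group_a, group_b, var_equal = FALSE) {
  rows <- lapply(rownames(A), function(cid) {
    r <- differential_activity(A[cid, ], group_a, group_b, var_equal)
    data.frame(component_id = cid, delta = r$delta, p_value = r$p_value)
  })
  out <- do.call(rbind, rows)
  out$q_value <- fdr_adjust(out$p_value)
  out
}

#' Correlation between a module's activity and one gene's expression
#'
#' @param activities named per-sample activity vector.
#' @param x [expression_matrix()] sharing sample ids.
#' @param gene locus tag.
#' @return Pearson correlation in [-1, 1].
#' @export
activity_expression_correlation <- function(activities, x, gene) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!gene %in% gene_ids(x)) stop("unknown gene: ", gene)
  expr <- x$values[gene, names(activities)]
  if (stats::sd(expr) == 0 || stats::sd(activities) == 0)
    stop("zero-variance input")
  stats::cor(activities, expr)
}

#' Per-category explained-variance summary
#'
#' Computes each component's marginal explained variance (single-component
#' least-squares reconstruction of the centered matrix) and aggregates by
#' curation category. Because components need not be orthogonal, category
#' shares may not sum exactly to the joint explained variance; both are
#' reported.
#'
#' @param x centered [expression_matrix()].
#' @param decomp `robust_decomposition`.
#' @param categories named character vector component_id -> category
#'   covering every component.
#' @return List: `by_component` (component_id, category, ev),
#'   `by_category` (category, ev, share_of_total), `total_ev`.
#' @export
variance_treemap <- function(x, decomp, categories) {
  ids <- colnames(decomp$M)
  missing_cat <- setdiff(ids, names(categories))
  if (length(missing_cat))
    stop("uncategorized component: ", paste(missing_cat, collapse = ", "))
  ev <- vapply(seq_len(decomp$K), function(k)
    explained_variance(x, decomp, subset = k), 1)
  by_component <- data.frame(component_id = ids,
                             category = unname(categories[ids]),
                             ev = ev, stringsAsFactors = FALSE)
  agg <- stats::aggregate(ev ~ category, data = by_component, FUN = sum)
  total <- explained_variance(x, decomp)
  agg$share_of_total <- agg$ev / total
  list(by_component = by_component, by_category = agg, total_ev = total)
}
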