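# Gene membership: a robust component's weight vector is mostly
# near-Gaussian background with a heavy tail of truly co-regulated genes.
# Members are peeled off the tail until the remaining weights look normal
# under the D'Agostino K-squared omnibus statistic.

#' D'Agostino K-squared omnibus normality statistic
#'
#' K2 = z_skew^2 + z_kurt^2, combining the D'Agostino (1970) transformed
#' skewness z-score with the Anscombe-Glynn (1983) transformed kurtosis
#' z-score; approximately chi-squared with 2 df under normality.
#'
#' @param values numeric vector, length >= 20, non-constant.
#' @return The non-negative K-squared statistic.
#' @export
dagostino_k2 <- function(values) {
  n <- length(values)
  if (n < 20) stop("vector too short for the K-squared statistic (need >= 20)")
  if (stats::sd(values) == 0) stop("constant vector")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)

  # transformed skewness (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * asinh(y / alpha)

  # transformed kurtosis (Anscombe-Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  denom <- 1 + xk * sqrt(2 / (a - 4))
  term <- (1 - 2 / a) / denom
  z_kurt <- ((1 - 2 / (9 * a)) - sign(term) * abs(term)^(1 / 3)) /
    sqrt(2 / (9 * a))

  z_skew^2 + z_kurt^2
}

#' Threshold one component's gene weights into an iModulon member set
#'
#' Iteratively removes the gene(s) with the largest absolute weight (ties
#' removed together, so the result is order-independent) and recomputes the
#' K-squared statistic on the remaining weights, stopping once the statistic
#' drops below `k2_cutoff`: the removed genes are the members, and the
#' threshold is the largest absolute weight among the remaining background
#' genes. If the background never looks normal before fewer than 20 genes
#' remain, the component is flagged degenerate.
#'
#' @param weights named per-gene numeric weight vector (one column of M).
#' @param k2_cutoff K-squared cutoff (default 550).
#' @return List: `threshold`, `members` (character vector of gene ids,
#'   possibly empty), `degenerate`, `n_removed`.
#' @export
threshold_component <- function(weights, k2_cutoff = 550) {
  if (is.null(names(weights))) names(weights) <- seq_along(weights)
  aw <- abs(weights)
  ord <- order(-aw)
  w_sorted <- weights[ord]
  aw_sorted <- aw[ord]
  n <- length(weights)
  j <- 0L   # number of genes removed from the top
  while (n - j >= 20) {
    remaining <- w_sorted[(j + 1):n]
    if (stats::sd(remaining) == 0) break
    if (dagostino_k2(remaining) < k2_cutoff) {
      return(list(threshold = max(abs(remaining)),
                  members = names(w_sorted)[seq_len(j)],
                  degenerate = FALSE, n_removed = j))
    }
    # remove every gene tied at the current maximum |weight|
    top <- aw_sorted[j + 1]
    j <- j + sum(aw_sorted[(j + 1):n] == top)
  }
  list(threshold = 0, members = names(w_sorted)[seq_len(j)],
       degenerate = TRUE, n_removed = j)
}

#' Build iModulon objects from a robust decomposition
#'
#' @param decomp `robust_decomposition`.
#' @param k2_cutoff K-squared cutoff for membership (default 550; see
#'   [optimize_cutoff()]).
#' @param categories optional named character vector mapping component id to
#'   one of the eight curation categories (PULs, Uncharacterized, ECF-sigma,
#'   Metabolism, Structural components, Functional, Stress, Single gene).
#' @return List of `imodulon` objects: component_id, weights, threshold,
#'   members, degenerate, category.
#' @export
make_imodulons <- function(decomp, k2_cutoff = 550, categories = NULL) {
  lapply(seq_len(decomp$K), function(k) {
    id <- colnames(decomp$M)[k]
    w <- decomp$M[, k]
    th <- threshold_component(w, k2_cutoff)
    structure(list(component_id = id, weights = w,
                   threshold = th$threshold, members = th$members,
                   degenerate = th$degenerate,
                   category = if (!is.null(categories) && id %in% names(categories))
                     unname(categories[[id]]) else NA_character_),
              class = "imodulon")
  })
}

#' @export
print.imodulon <- function(x, ...) {
  cat(sprintf("imodulon %s: %d members, threshold %.4g%s\n", x$component_id,
              length(x$members), x$threshold,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

f1_score <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Choose the K-squared cutoff that best matches a known TRN
#'
#' Mirrors the workflow's optimized-threshold setting: over a cutoff grid,
#' each candidate cutoff is scored by the mean (over components) of the best
#' F1 between the thresholded member set and any single known regulon; the
#' cutoff with the highest mean F1 wins, ties broken toward the lowest grid
#' value. With an empty TRN the default cutoff 550 is returned with a
#' warning.
#'
#' @param M genes x components weight matrix.
#' @param trn a [make_trn()] object.
#' @param grid numeric cutoff grid (default seq(100, 2000, 50)).
#' @return The selected cutoff.
#' @export
optimize_cutoff <- function(M, trn, grid = seq(100, 2000, by = 50)) {
  stopifnot(length(grid) >= 1)
  if (is.null(trn) || nrow(trn$associations) == 0) {
    warning("empty TRN: falling back to default K-squared cutoff 550")
    return(550)
  }
  regulons <- split(trn$associations$target, trn$associations$regulator)
  grid <- sort(grid)
  scores <- vapply(grid, function(cutoff) {
    f1s <- vapply(seq_len(ncol(M)), function(k) {
      members <- threshold_component(M[, k], cutoff)$members
      if (!length(members)) return(0)
      max(vapply(regulons, f1_score, 1, a = members))
    }, 1)
    mean(f1s)
  }, 1)
  grid[which.max(scores)]   # which.max takes the first (lowest) on ties
}

#' Write iModulons to JSON
#'
#' One object per iModulon: component_id, threshold, members, category, and
#' (if attached) enrichment summary.
#'
#' @param imodulons list of `imodulon` objects.
#' @param path output JSON path.
#' @param enrichment optional data.frame from [enrich_all()] keyed by
#'   component_id.
#' @export
write_imodulons_json <- function(imodulons, path, enrichment = NULL) {
  objs <- lapply(imodulons, function(im) {
    o <- list(component_id = im$component_id,
              threshold = im$threshold,
              members = as.list(im$members),
              category = im$category,
              degenerate = im$degenerate)
    if (!is.null(enrichment)) {
      row <- enrichment[enrichment$component_id == im$component_id, , drop = FALSE]
      if (nrow(row) == 1) o$enrichment <- as.list(row[1, ])
    }
    o
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
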