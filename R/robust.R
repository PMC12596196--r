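# Consensus over the ICA ensemble: pooled components from all random
# restarts are density-clustered under d = 1 - |rho|; components that recur
# across runs form robust components, singletons and noise are discarded.

#' Run an ensemble of randomized FastICA decompositions
#'
#' @param x centered [expression_matrix()].
#' @param dimension number of components per run.
#' @param n_runs number of random restarts (seeds `seeds` default
#'   `0:(n_runs-1)`).
#' @param tolerance FastICA convergence tolerance.
#' @param seeds optional explicit integer seeds (overrides `n_runs`).
#' @param max_iter per-run iteration cap.
#' @return List of `ica_run` objects; non-convergent runs are kept but
#'   flagged (consumers drop them).
#' @export
run_ica_ensemble <- function(x, dimension, n_runs = 100, tolerance = 1e-7,
                             seeds = NULL, max_iter = 1000) {
  if (is.null(seeds)) seeds <- seq_len(n_runs) - 1L
  lapply(seeds, function(s)
    run_ica_single(x, dimension, seed = s, tolerance = tolerance,
                   max_iter = max_iter))
}

# DBSCAN over a precomputed distance matrix. `min_pts` counts the point
# itself (the usual convention). Returns integer labels, 0 = noise.
dbscan_precomputed <- function(D, eps, min_pts) {
  n <- nrow(D)
  neighbors <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(neighbors, length, 1L) >= min_pts
  labels <- integer(n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cluster <- cluster + 1L
    labels[i] <- cluster
    queue <- neighbors[[i]]
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cluster
        if (core[j]) queue <- c(queue, neighbors[[j]][labels[neighbors[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Consensus-cluster pooled ICA components into a robust decomposition
#'
#' Pools the components of all converged runs, clusters them with DBSCAN
#' under the 1 - |rho| distance (epsilon 0.1, minimum cluster seed size 50
#' by default), and summarizes each cluster as one robust component: members
#' are sign-aligned to the cluster medoid, averaged, and re-normalized.
#' Activities A are obtained by ordinary least-squares projection of the
#' centered expression matrix onto the consensus gene-weight matrix M, so
#' that X ~ M A and explained variance is well defined.
#'
#' @param runs list of `ica_run` objects sharing gene order.
#' @param x the centered [expression_matrix()] the runs decomposed.
#' @param epsilon DBSCAN epsilon on the 1 - |rho| scale (default 0.1).
#' @param min_cluster_size DBSCAN min_samples: a component family must recur
#'   this many times across the pooled ensemble (default 50, matching a
#'   100-run ensemble where a family must recur in half the runs).
#' @return List of class `robust_decomposition`: `M` (genes x K), `A`
#'   (K x samples), `K`, `cluster_support` (runs contributing per
#'   component), `seeds_used`, `n_runs_converged`, `params`.
#' @export
cluster_components <- function(runs, x, epsilon = 0.1, min_cluster_size = 50) {
  stopifnot(inherits(x, "expr_matrix"), length(runs) >= 1)
  ok <- vapply(runs, function(r) isTRUE(r$converged), TRUE)
  if (!all(ok)) message(sum(!ok), " non-convergent runs dropped")
  empty_decomposition <- function(seeds) {
    M <- matrix(numeric(0), nrow(x$values), 0,
                dimnames = list(rownames(x$values), NULL))
    A <- matrix(numeric(0), 0, ncol(x$values),
                dimnames = list(NULL, colnames(x$values)))
    structure(list(M = M, A = A, K = 0L, cluster_support = integer(0),
                   seeds_used = seeds, n_runs_converged = sum(ok),
                   params = list(epsilon = epsilon,
                                 min_cluster_size = min_cluster_size)),
              class = "robust_decomposition")
  }
  all_seeds <- vapply(runs, `[[`, 1, "seed")
  runs <- runs[ok]
  if (!length(runs)) {
    message("no converged runs: returning K = 0")
    return(empty_decomposition(all_seeds))
  }
  gene_order <- rownames(runs[[1]]$components)
  for (r in runs)
    if (!identical(rownames(r$components), gene_order))
      stop("runs do not share gene order")

  pool <- do.call(cbind, lapply(runs, `[[`, "components"))
  run_of <- rep(seq_along(runs), vapply(runs, function(r) ncol(r$components), 1L))
  D <- 1 - abs(stats::cor(pool))
  D[D < 0] <- 0
  labels <- dbscan_precomputed(D, eps = epsilon, min_pts = min_cluster_size)

  k_raw <- max(labels)
  if (k_raw == 0L) {
    message("no robust components found (K = 0)")
    return(empty_decomposition(all_seeds))
  }

  cols <- lapply(seq_len(k_raw), function(k) which(labels == k))
  centroids <- vapply(cols, function(idx) {
    sub <- pool[, idx, drop = FALSE]
    Dk <- D[idx, idx, drop = FALSE]
    medoid <- which.min(rowSums(Dk))
    signs <- sign(stats::cor(sub, sub[, medoid]))
    signs[signs == 0] <- 1
    w <- rowMeans(sweep(sub, 2, drop(signs), "*"))
    w / sqrt(sum(w^2))
  }, numeric(nrow(pool)))
  centroids <- orient_components(centroids)
  support <- vapply(cols, function(idx) length(unique(run_of[idx])), 1L)

  # deterministic, run-order-invariant component order: by decreasing
  # support, then decreasing activity variance
  A0 <- project_activities(centroids, x$values)
  ord <- order(-support, -apply(A0, 1, stats::var))
  M <- centroids[, ord, drop = FALSE]
  support <- support[ord]
  colnames(M) <- sprintf("IC%02d", seq_len(ncol(M)))
  A <- project_activities(M, x$values)

  structure(list(M = M, A = A, K = ncol(M), cluster_support = support,
                 seeds_used = vapply(runs, `[[`, 1, "seed"),
                 n_runs_converged = length(runs),
                 params = list(epsilon = epsilon,
                               min_cluster_size = min_cluster_size)),
            class = "robust_decomposition")
}

#' @export
print.robust_decomposition <- function(x, ...) {
  cat(sprintf("robust_decomposition: K = %d components over %d genes x %d samples\n",
              x$K, nrow(x$M), ncol(x$A)))
  invisible(x)
}

#' Fraction of expression variance explained by a component subset
#'
#' 1 - ||X - M_s A_s||_F^2 / ||X||_F^2 where A_s is refit by least squares
#' on the selected columns of M (so the measure is non-decreasing as
#' components are added). The empty subset returns 0.
#'
#' @param x centered [expression_matrix()].
#' @param decomp a `robust_decomposition` (or any list with an `M` matrix
#'   whose rows match `x`).
#' @param subset optional component indices or names; default all.
#' @return Explained variance fraction in [0, 1].
#' @export
explained_variance <- function(x, decomp, subset = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  M <- decomp$M
  if (!identical(nrow(M), nrow(x$values)))
    stop("shape mismatch between decomposition and expression matrix")
  if (is.null(subset)) subset <- seq_len(ncol(M))
  if (!length(subset)) return(0)
  Ms <- M[, subset, drop = FALSE]
  As <- project_activities(Ms, x$values)
  resid <- x$values - Ms %*% As
  1 - sum(resid^2) / sum(x$values^2)
}

#' Sweep ICA dimensionality and pick the optimum
#'
#' For each dimension on the grid, runs the full ensemble + consensus
#' clustering + membership thresholding, recording the number of robust
#' components K and the number of non-single components (those whose member
#' set has more than one gene). The optimal dimension is the largest grid
#' value where the two counts are equal (with K > 0); when no dimension
#' satisfies the criterion the dimension maximizing the non-single count is
#' returned with a warning.
#'
#' @param x centered [expression_matrix()].
#' @param dims ascending integer grid of candidate dimensions.
#' @param n_runs restarts per dimension.
#' @param tolerance FastICA tolerance.
#' @param epsilon,min_cluster_size consensus-clustering parameters.
#' @param k2_cutoff D'Agostino K-squared cutoff used to count single-gene
#'   components (default 550).
#' @return List: `optimal_dimension`, `diagnostics` (data.frame with
#'   dimension, K, n_single, n_non_single, criterion_met).
#' @export
dimension_sweep <- function(x, dims, n_runs = 100, tolerance = 1e-7,
                            epsilon = 0.1, min_cluster_size = 50,
                            k2_cutoff = 550) {
  stopifnot(!is.unsorted(dims))
  rows <- lapply(dims, function(d) {
    runs <- run_ica_ensemble(x, d, n_runs = n_runs, tolerance = tolerance)
    dec <- cluster_components(runs, x, epsilon = epsilon,
                              min_cluster_size = min_cluster_size)
    if (dec$K == 0) {
      n_single <- 0L
    } else {
      n_members <- vapply(seq_len(dec$K), function(k)
        length(threshold_component(dec$M[, k], k2_cutoff)$members), 1L)
      n_single <- sum(n_members == 1L)
    }
    data.frame(dimension = d, K = dec$K, n_single = n_single,
               n_non_single = dec$K - n_single,
               criterion_met = dec$K > 0 && n_single == 0L)
  })
  diag_tab <- do.call(rbind, rows)
  if (any(diag_tab$criterion_met)) {
    opt <- max(diag_tab$dimension[diag_tab$criterion_met])
  } else {
    warning("no dimension satisfied K == non-single; returning dimension ",
            "with the most non-single components")
    opt <- diag_tab$dimension[which.max(diag_tab$n_non_single)]
  }
  list(optimal_dimension = opt, diagnostics = diag_tab)
}

#' Write a robust decomposition to TSV plus a run manifest
#'
#' @param decomp `robust_decomposition`.
#' @param dir output directory (created if needed).
#' @param extra named list merged into the manifest JSON.
#' @return Invisibly, the paths written.
#' @export
write_decomposition <- function(decomp, dir, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m_path <- file.path(dir, "M.tsv")
  a_path <- file.path(dir, "A.tsv")
  data.table::fwrite(data.table::data.table(gene_id = rownames(decomp$M),
                                            decomp$M), m_path, sep = "\t")
  data.table::fwrite(data.table::data.table(component_id = rownames(decomp$A),
                                            decomp$A), a_path, sep = "\t")
  manifest <- c(list(K = decomp$K,
                     cluster_support = decomp$cluster_support,
                     seeds_used = decomp$seeds_used,
                     n_runs_converged = decomp$n_runs_converged,
                     params = decomp$params), extra)
  man_path <- file.path(dir, "decomposition_manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(M = m_path, A = a_path, manifest = man_path))
}
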