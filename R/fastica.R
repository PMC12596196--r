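# FastICA core: PCA/SVD whitening followed by the symmetric (parallel)
# fixed-point iteration with the logcosh contrast. The decomposition
# convention is X = M %*% A with X genes x samples: columns of M are
# gene-weight source vectors (independent, heavy-tailed over genes) and
# rows of A are condition-dependent activities.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors) %*% W
}

# Whiten the sample space: X (genes x samples) is reduced to `dimension`
# uncorrelated, unit-variance coordinates over genes.
whiten_samples <- function(v, dimension) {
  n_genes <- nrow(v)
  xt <- t(v)                      # samples x genes
  xt <- xt - rowMeans(xt)         # each sample centered across genes
  sv <- La.svd(xt, nu = min(dim(xt)), nv = 0)
  if (sv$d[dimension] < 1e-12 * sv$d[1])
    stop("whitening failed: requested dimension exceeds numerical rank")
  kw <- t(sv$u[, seq_len(dimension), drop = FALSE] %*%
            diag(1 / sv$d[seq_len(dimension)], dimension))
  x1 <- kw %*% xt * sqrt(n_genes) # dimension x genes, whitened rows
  list(x1 = x1, kw = kw)
}

#' One randomized FastICA run
#'
#' Performs a single FastICA decomposition of a centered expression matrix at
#' a fixed dimension and seed. Deterministic for a fixed seed. Each returned
#' component (column of `components`) is unit L2-normalized and sign-oriented
#' so that its largest-magnitude gene weight is positive.
#'
#' @param x centered [expression_matrix()].
#' @param dimension number of components (<= min(genes, samples)).
#' @param seed integer seed for the random unmixing initialization.
#' @param tolerance convergence tolerance of the fixed-point iteration
#'   (default 1e-7).
#' @param max_iter maximum fixed-point iterations (default 1000).
#' @return List of class `ica_run`: `components` (genes x dimension),
#'   `mixing` (dimension x samples, least-squares fit), `seed`, `dimension`,
#'   `converged`, `n_iter`.
#' @export
run_ica_single <- function(x, dimension, seed, tolerance = 1e-7,
                           max_iter = 1000) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!x$is_centered) stop("ICA input must be centered (see batch_center)")
  v <- x$values
  keep <- apply(v, 1, stats::sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance genes excluded from ICA input")
    v <- v[keep, , drop = FALSE]
  }
  if (dimension > min(dim(v)))
    stop("dimension too large: must be <= min(genes, samples)")
  wh <- whiten_samples(v, dimension)
  x1 <- wh$x1
  n_genes <- ncol(x1)

  W <- with_seed(seed, matrix(stats::rnorm(dimension^2), dimension, dimension))
  W <- sym_decorrelate(W)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    gu <- tanh(W %*% x1)
    W1 <- gu %*% t(x1) / n_genes -
      diag(rowMeans(1 - gu^2), dimension) %*% W
    W1 <- sym_decorrelate(W1)
    lim <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (lim < tolerance) { converged <- TRUE; break }
  }

  S <- W %*% x1                   # dimension x genes: sources over genes
  M <- t(S)
  M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  M <- orient_components(M)
  colnames(M) <- sprintf("run%d_c%02d", seed, seq_len(dimension))
  # embed back into the full gene space (zero weight for excluded genes)
  if (!all(keep)) {
    full <- matrix(0, nrow(x$values), dimension,
                   dimnames = list(rownames(x$values), colnames(M)))
    full[rownames(M), ] <- M
    M <- full
  } else rownames(M) <- rownames(x$values)
  A <- project_activities(M, x$values)
  structure(list(components = M, mixing = A, seed = seed,
                 dimension = dimension, converged = converged,
                 n_iter = iter),
            class = "ica_run")
}

# flip each column so its largest-|weight| entry is positive
orient_components <- function(M) {
  flips <- apply(M, 2, function(w) sign(w[which.max(abs(w))]))
  sweep(M, 2, flips, "*")
}

# least-squares projection of X onto the component basis; SVD-based
# pseudoinverse so near-collinear consensus components stay well defined
project_activities <- function(M, v) {
  sv <- svd(M)
  pos <- sv$d > max(sv$d) * 1e-10
  A <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) %*% v / sv$d[pos])
  rownames(A) <- colnames(M)
  colnames(A) <- colnames(v)
  A
}

#' Distance between two components: 1 - |Pearson rho|
#'
#' The consensus-clustering metric: zero for identical components up to sign
#' and scale, one for uncorrelated components.
#'
#' @param u,v numeric gene-weight vectors of equal length.
#' @return Distance in [0, 1].
#' @export
component_distance <- function(u, v) {
  if (length(u) != length(v)) stop("weight vectors differ in length")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) stop("zero-variance vector")
  1 - abs(stats::cor(u, v))
}
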