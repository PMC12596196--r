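# shared in-code fixtures

# small expression matrix with named genes/samples
tiny_expr <- function(values, genes = NULL, samples = NULL, centered = FALSE) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, is_centered = centered)
}

# metadata where every sample of one project is a reference
all_ref_meta <- function(x, project = "P1") {
  data.frame(sample_id = colnames(x$values), project_id = project,
             condition = "c1", is_reference = TRUE,
             replicate_group = "r1", stringsAsFactors = FALSE)
}

# a weight vector of gaussian background plus planted outlier genes
planted_weights <- function(n_background, outliers, sd = 0.01, seed = 1) {
  set.seed(seed)
  w <- rnorm(n_background + length(outliers), 0, sd)
  idx <- seq_along(outliers)
  w[idx] <- outliers
  names(w) <- sprintf("g%04d", seq_along(w))
  w
}

# brute-force membership: smallest prefix of |weight|-sorted genes whose
# removal drops the K-squared statistic below the cutoff
brute_force_members <- function(weights, cutoff) {
  ord <- order(-abs(weights))
  n <- length(weights)
  for (j in 0:(n - 20)) {
    rem <- weights[ord][(j + 1):n]
    if (sd(rem) == 0) break
    if (dagostino_k2(rem) < cutoff) return(names(weights)[ord][seq_len(j)])
  }
  names(weights)[ord]
}

# exact hypergeometric over-representation tail by direct enumeration
brute_force_hyper <- function(n_members, n_regulon, overlap, universe) {
  ks <- overlap:min(n_members, n_regulon)
  sum(choose(n_regulon, ks) * choose(universe - n_regulon, n_members - ks)) /
    choose(universe, n_members)
}
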