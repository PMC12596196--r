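# Synthetic compendium generator: a log-TPM-like matrix with K planted
# sparse co-regulation modules, condition-block activities, Gaussian noise,
# per-project reference conditions, and a planted TRN whose regulons fall
# into four classes (exact-match, subset, superset, unrelated) so every
# downstream stage has a ground truth.

#' Generate a synthetic expression compendium with planted modules
#'
#' Ground truth: a sparse genes x K weight matrix M* (each module has
#' `module_size_range` member genes with weight magnitudes drawn from
#' |N(effect_size, effect_size/5)| and random signs, background exactly 0)
#' and a K x samples activity matrix A* in which module k is active at
#' level 1 in its own contiguous block of two conditions and 0 elsewhere,
#' plus N(0, 0.1) activity jitter. The expression matrix is
#' X = baseline + M* A* + N(0, noise_sd); per-gene baselines keep all
#' entries non-negative so X behaves like a log10(TPM+1) matrix. Samples
#' are split across `n_projects` projects and each project's first
#' condition is its reference condition. Fully reproducible from `seed`.
#'
#' The planted TRN cycles its regulons through four classes relative to the
#' module member sets: exact (regulon = members), subset (the module is a
#' strict subset of the regulon: extra non-member targets are added),
#' superset (the module strictly contains the regulon: only half the
#' members are targets), and unrelated (random background genes).
#'
#' @param n_genes,n_samples,k_modules problem dimensions
#'   (n_samples >= 2 * k_modules).
#' @param module_size_range integer pair, members per module (default
#'   c(10, 50)).
#' @param effect_size mean planted weight magnitude (default 5).
#' @param noise_sd expression noise standard deviation (default 0.25; the
#'   signal-to-noise ratio is effect_size / noise_sd).
#' @param n_projects number of synthetic projects (default 2).
#' @param activity_jitter_sd activity noise (default 0.1).
#' @param seed integer seed.
#' @return List of class `synthetic_dataset`: `x` (expr_matrix), `meta`,
#'   `M_star`, `A_star`, `trn_star`, `noise_sd`, `seed`, `params`.
#' @export
generate_synthetic <- function(n_genes = 4000, n_samples = 200,
                               k_modules = 20,
                               module_size_range = c(10, 50),
                               effect_size = 5, noise_sd = 0.25,
                               n_projects = 2, activity_jitter_sd = 0.1,
                               seed = 1) {
  if (k_modules > 0 && k_modules * max(module_size_range) > n_genes)
    stop("infeasible sizes: modules cannot fit in the gene set")
  if (k_modules > 0 && n_samples < 2 * k_modules)
    stop("infeasible sizes: need n_samples >= 2 * k_modules")
  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- sprintf("s%03d", seq_len(n_samples))
  n_conditions <- max(2 * max(k_modules, 1L), 4L)
  conditions <- sprintf("cond%02d", seq_len(n_conditions))
  cond_of <- rep(conditions, length.out = n_samples)

  with_seed(seed, {
    # ground-truth sparse weights, disjoint member sets
    M_star <- matrix(0, n_genes, k_modules,
                     dimnames = list(genes,
                                     if (k_modules) sprintf("mod%02d", seq_len(k_modules))))
    sizes <- if (k_modules)
      sample(seq(module_size_range[1], module_size_range[2]), k_modules,
             replace = TRUE) else integer(0)
    pool <- sample(genes)
    offset <- 0L
    members_star <- list()
    for (k in seq_len(k_modules)) {
      mem <- pool[(offset + 1):(offset + sizes[k])]
      offset <- offset + sizes[k]
      members_star[[colnames(M_star)[k]]] <- sort(mem)
      M_star[mem, k] <- abs(stats::rnorm(sizes[k], effect_size, effect_size / 5)) *
        sample(c(-1, 1), sizes[k], replace = TRUE)
    }

    # block activities: module k owns conditions 2k-1 and 2k
    A_star <- matrix(0, k_modules, n_samples,
                     dimnames = list(colnames(M_star), samples))
    for (k in seq_len(k_modules)) {
      block <- conditions[c(2 * k - 1, 2 * k)]
      A_star[k, cond_of %in% block] <- 1
    }
    if (k_modules)
      A_star <- A_star + matrix(stats::rnorm(length(A_star), 0, activity_jitter_sd),
                                nrow(A_star))

    signal <- if (k_modules) M_star %*% A_star else
      matrix(0, n_genes, n_samples)
    noise <- matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                    n_genes, n_samples)
    baseline <- stats::runif(n_genes, 1, 3)
    baseline <- baseline + pmax(0, -apply(signal + noise, 1, min))
    X <- baseline + signal + noise
    dimnames(X) <- list(genes, samples)

    # metadata: projects split the condition axis; first condition of each
    # project is its reference
    proj_of_cond <- rep(sprintf("P%02d", seq_len(n_projects)),
                        length.out = n_conditions)
    proj_of_cond <- sort(proj_of_cond)
    names(proj_of_cond) <- conditions
    ref_conds <- tapply(conditions, proj_of_cond, `[`, 1)
    meta <- data.frame(sample_id = samples,
                       project_id = unname(proj_of_cond[cond_of]),
                       condition = cond_of,
                       is_reference = cond_of %in% ref_conds,
                       replicate_group = cond_of,
                       stringsAsFactors = FALSE)

    trn_star <- planted_trn(members_star, genes)

    structure(list(x = expression_matrix(X), meta = meta, M_star = M_star,
                   A_star = A_star, trn_star = trn_star,
                   members_star = members_star, noise_sd = noise_sd,
                   seed = seed,
                   params = list(n_genes = n_genes, n_samples = n_samples,
                                 k_modules = k_modules,
                                 module_size_range = module_size_range,
                                 effect_size = effect_size,
                                 noise_sd = noise_sd,
                                 n_projects = n_projects,
                                 activity_jitter_sd = activity_jitter_sd)),
              class = "synthetic_dataset")
  })
}

# Build the four-class planted TRN. Class is assigned cyclically by module
# index; regulon sizes are chosen so the classes land in distinct recall
# quadrants at the 0.7 cut on noise-free member sets.
planted_trn <- function(members_star, genes) {
  classes <- c("exact", "subset", "superset", "unrelated")
  rows <- list()
  non_members_pool <- setdiff(genes, unlist(members_star))
  used_extra <- character(0)
  for (k in seq_along(members_star)) {
    mem <- members_star[[k]]
    cls <- classes[(k - 1) %% 4 + 1]
    reg <- sprintf("R%02d_%s", k, cls)
    targets <- switch(cls,
      exact = mem,
      subset = {  # module strictly inside a larger regulon
        avail <- setdiff(non_members_pool, used_extra)
        extra <- avail[seq_len(min(length(mem), length(avail)))]
        used_extra <- c(used_extra, extra)
        c(mem, extra)
      },
      superset = mem[seq_len(max(1, floor(length(mem) / 2)))],
      unrelated = {
        avail <- setdiff(non_members_pool, used_extra)
        pick <- avail[seq_len(min(length(mem), length(avail)))]
        used_extra <- c(used_extra, pick)
        pick
      })
    rows[[k]] <- data.frame(regulator = reg, target = targets,
                            evidence = cls, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(make_trn(data.frame(regulator = character(0), target = character(0),
                               evidence = character(0)), genes))
  make_trn(do.call(rbind, rows), genes)
}

#' Match recovered components to planted modules
#'
#' Greedy one-to-one matching by descending |Pearson rho| between columns of
#' the recovered and ground-truth weight matrices; a planted module counts
#' as matched when its assigned |rho| reaches `min_abs_corr`. Membership F1
#' compares the thresholded member set of the matched recovered component
#' against the planted member set (unmatched modules score 0).
#'
#' @param M_recovered,M_star genes x components weight matrices with
#'   identical row order (gene ids).
#' @param min_abs_corr match acceptance threshold (default 0.8).
#' @param k2_cutoff cutoff used to threshold recovered components
#'   (default 550).
#' @param members_recovered optional list of member sets (by recovered
#'   column) overriding internal thresholding.
#' @return List: `matched_fraction`, `matches` (data.frame module,
#'   component, abs_corr, matched, f1), `mean_f1`.
#' @export
match_components <- function(M_recovered, M_star, min_abs_corr = 0.8,
                             k2_cutoff = 550, members_recovered = NULL) {
  if (!identical(rownames(M_recovered), rownames(M_star)))
    stop("gene-order mismatch between recovered and ground-truth matrices")
  k_star <- ncol(M_star)
  if (k_star == 0) stop("no planted modules to match")
  if (ncol(M_recovered) == 0) {
    return(list(matched_fraction = 0,
                matches = data.frame(module = colnames(M_star),
                                     component = NA, abs_corr = 0,
                                     matched = FALSE, f1 = 0),
                mean_f1 = 0))
  }
  if (is.null(colnames(M_recovered)))
    colnames(M_recovered) <- sprintf("c%02d", seq_len(ncol(M_recovered)))
  if (is.null(colnames(M_star)))
    colnames(M_star) <- sprintf("mod%02d", seq_len(ncol(M_star)))
  C <- abs(stats::cor(M_recovered, M_star))
  assign_to <- rep(NA_integer_, k_star)
  rho <- numeric(k_star)
  Cw <- C
  for (i in seq_len(min(dim(C)))) {
    best <- which(Cw == max(Cw), arr.ind = TRUE)[1, ]
    assign_to[best[2]] <- best[1]
    rho[best[2]] <- Cw[best[1], best[2]]
    Cw[best[1], ] <- -1
    Cw[, best[2]] <- -1
  }
  matched <- !is.na(assign_to) & rho >= min_abs_corr
  # report the best available correlation for unassigned modules too
  rho[is.na(assign_to)] <- apply(C[, is.na(assign_to), drop = FALSE], 2, max)

  f1 <- vapply(seq_len(k_star), function(k) {
    if (!matched[k]) return(0)
    true_members <- rownames(M_star)[M_star[, k] != 0]
    rec <- if (!is.null(members_recovered))
      members_recovered[[assign_to[k]]]
    else threshold_component(M_recovered[, assign_to[k]], k2_cutoff)$members
    f1_score(rec, true_members)
  }, 1)

  list(matched_fraction = mean(matched),
       matches = data.frame(module = colnames(M_star),
                            component = colnames(M_recovered)[assign_to],
                            abs_corr = rho, matched = matched, f1 = f1,
                            stringsAsFactors = FALSE),
       mean_f1 = mean(f1))
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' @param ds `synthetic_dataset`.
#' @param dir output directory.
#' @return Invisibly, the paths written (expression.tsv, metadata.csv,
#'   trn.csv, M_star.tsv, A_star.tsv, manifest JSON).
#' @export
write_synthetic <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.csv"),
             trn = file.path(dir, "trn.csv"),
             M_star = file.path(dir, "M_star.tsv"),
             A_star = file.path(dir, "A_star.tsv"),
             manifest = file.path(dir, "dataset_manifest.json"))
  write_expression(ds$x, paths["expression"])
  data.table::fwrite(ds$meta, paths["metadata"])
  data.table::fwrite(ds$trn_star$associations, paths["trn"])
  data.table::fwrite(data.table::data.table(gene_id = rownames(ds$M_star),
                                            ds$M_star), paths["M_star"], sep = "\t")
  data.table::fwrite(data.table::data.table(module = rownames(ds$A_star),
                                            ds$A_star), paths["A_star"], sep = "\t")
  jsonlite::write_json(c(ds$params, list(seed = ds$seed)), paths["manifest"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
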