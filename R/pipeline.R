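# End-to-end orchestration. A single config (YAML/JSON file or R list)
# drives four file-coupled stages -- decompose, threshold, enrich,
# activities -- so that running them separately on saved intermediates is
# byte-identical to a single run_pipeline() call.

#' Default pipeline configuration
#'
#' Parameter defaults follow the published workflow: 100 FastICA restarts
#' at tolerance 1e-7, DBSCAN epsilon 0.1 with minimum cluster seed size 50,
#' regulatory FDR 1e-4 and term FDR 1e-2, quadrant cut 0.7.
#'
#' @return Nested list of defaults; override via [read_pipeline_config()]
#'   or by merging your own list.
#' @export
default_config <- function() {
  list(paths = list(expression = NULL, metadata = NULL, trn = NULL,
                    annotation = NULL, output_dir = "pipeline_out"),
       ica = list(dimension = NULL, sweep_grid = NULL, n_runs = 100,
                  tolerance = 1e-7, seed = 0),
       clustering = list(epsilon = 0.1, min_cluster_size = 50),
       membership = list(k2_cutoff = 550, optimize = FALSE,
                         cutoff_grid = seq(100, 2000, by = 50)),
       enrichment = list(regulatory_fdr = 1e-4, term_fdr = 1e-2,
                         quadrant_cut = 0.7),
       activity = list(cluster_k = NULL, var_equal = FALSE))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline config file (YAML or JSON), merged over the defaults
#' @param path config file path.
#' @return Full config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  merge_config(default_config(), cfg)
}

log_line <- function(stage, ..., logfile = NULL) {
  msg <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 stage, paste0(...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the iModulon inference pipeline
#'
#' Stages (any subset, in order): `decompose` (read + log-transform if
#' needed + reference-center + ensemble ICA + consensus clustering, or a
#' dimension sweep first when `ica$sweep_grid` is set), `threshold`
#' (membership via the K-squared cutoff, optionally optimized against the
#' TRN), `enrich` (Fisher/FDR scoring, quadrants, expansion accounting) and
#' `activities` (Ward clustering of activity rows). Every stage reads its
#' inputs from and writes its outputs to `paths$output_dir`, so stages can
#' be re-run independently; a manifest records parameters, seeds, and input
#' checksums.
#'
#' @param config config list (see [default_config()]) or path to a
#'   YAML/JSON config file.
#' @param stages character vector of stages to run.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config,
                         stages = c("decompose", "threshold", "enrich",
                                    "activities")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- merge_config(default_config(), config)
  out <- config$paths$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out, "run.log")

  if ("decompose" %in% stages) {
    log_line("decompose", "reading expression and metadata", logfile = logfile)
    x <- read_expression(config$paths$expression)
    meta <- read_sample_metadata(config$paths$metadata)
    if (any(x$values < 0)) stop("decompose: expression matrix has negative ",
                                "entries; expected (log-)TPM input")
    xc <- batch_center(x, meta)
    dim_used <- config$ica$dimension
    sweep_diag <- NULL
    if (!is.null(config$ica$sweep_grid)) {
      log_line("decompose", "dimension sweep over {",
               paste(config$ica$sweep_grid, collapse = ", "), "}",
               logfile = logfile)
      sw <- dimension_sweep(xc, config$ica$sweep_grid,
                            n_runs = config$ica$n_runs,
                            tolerance = config$ica$tolerance,
                            epsilon = config$clustering$epsilon,
                            min_cluster_size = config$clustering$min_cluster_size,
                            k2_cutoff = config$membership$k2_cutoff)
      dim_used <- sw$optimal_dimension
      sweep_diag <- sw$diagnostics
      data.table::fwrite(sweep_diag, file.path(out, "dimension_sweep.tsv"),
                         sep = "\t")
    }
    if (is.null(dim_used)) stop("decompose: config needs ica$dimension or ",
                                "ica$sweep_grid")
    log_line("decompose", sprintf("ensemble of %d runs at dimension %d",
                                  config$ica$n_runs, dim_used),
             logfile = logfile)
    runs <- run_ica_ensemble(xc, dim_used, n_runs = config$ica$n_runs,
                             tolerance = config$ica$tolerance,
                             seeds = config$ica$seed + seq_len(config$ica$n_runs) - 1L)
    dec <- cluster_components(runs, xc,
                              epsilon = config$clustering$epsilon,
                              min_cluster_size = config$clustering$min_cluster_size)
    log_line("decompose", sprintf("K = %d robust components, EV = %.3f",
                                  dec$K, explained_variance(xc, dec)),
             logfile = logfile)
    write_expression(xc, file.path(out, "X_centered.tsv"))
    write_decomposition(dec, out, extra = list(
      dimension = dim_used,
      explained_variance = explained_variance(xc, dec),
      input_checksums = as.list(tools::md5sum(stats::na.omit(c(
        config$paths$expression, config$paths$metadata, config$paths$trn)))),
      config = config))
  }

  if ("threshold" %in% stages) {
    dec <- read_decomposition(out)
    cutoff <- config$membership$k2_cutoff
    if (isTRUE(config$membership$optimize)) {
      if (is.null(config$paths$trn)) {
        warning("threshold: optimize requested without a TRN; using default cutoff")
        log_line("threshold", "no TRN for cutoff optimization, default used",
                 logfile = logfile)
      } else {
        trn <- read_trn(config$paths$trn, rownames(dec$M))
        cutoff <- optimize_cutoff(dec$M, trn, config$membership$cutoff_grid)
        log_line("threshold", "optimized K-squared cutoff = ", cutoff,
                 logfile = logfile)
      }
    }
    imods <- make_imodulons(dec, k2_cutoff = cutoff)
    write_imodulons_json(imods, file.path(out, "imodulons.json"))
    jsonlite::write_json(list(k2_cutoff = cutoff),
                         file.path(out, "membership_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line("threshold", length(imods), " iModulons thresholded",
             logfile = logfile)
  }

  if ("enrich" %in% stages) {
    if (is.null(config$paths$trn)) {
      log_line("enrich", "no TRN configured; stage skipped", logfile = logfile)
    } else {
      dec <- read_decomposition(out)
      imods <- read_imodulons_json(file.path(out, "imodulons.json"), dec)
      trn <- read_trn(config$paths$trn, rownames(dec$M))
      res <- enrich_all(imods, trn,
                        regulatory_fdr = config$enrichment$regulatory_fdr,
                        cut = config$enrichment$quadrant_cut)
      write_enrichment(res, file.path(out, "enrichment.tsv"))
      exp_counts <- count_trn_expansion(
        res[res$is_regulatory, , drop = FALSE], imods, trn)
      jsonlite::write_json(exp_counts[c("total_associations",
                                        "novel_associations",
                                        "expansion_fraction")],
                           file.path(out, "trn_expansion.json"),
                           auto_unbox = TRUE, digits = NA)
      log_line("enrich", sprintf("%d regulatory iModulons; %d associations (%d novel)",
                                 sum(res$is_regulatory),
                                 exp_counts$total_associations,
                                 exp_counts$novel_associations),
               logfile = logfile)
    }
  }

  if ("activities" %in% stages) {
    dec <- read_decomposition(out)
    if (dec$K >= 2) {
      cl <- cluster_activity_rows(dec$A, k = config$activity$cluster_k)
      writeLines(cl$newick, file.path(out, "activity_tree.nwk"))
      if (!is.null(cl$labels))
        data.table::fwrite(data.table::data.table(component_id = names(cl$labels),
                                                  cluster = cl$labels),
                           file.path(out, "activity_clusters.tsv"), sep = "\t")
      log_line("activities", "activity rows clustered", logfile = logfile)
    } else {
      log_line("activities", "fewer than 2 components; clustering skipped",
               logfile = logfile)
    }
  }

  invisible(out)
}

#' Read a decomposition written by [write_decomposition()]
#' @param dir directory containing M.tsv and A.tsv.
#' @return A `robust_decomposition` (manifest fields re-attached when
#'   present).
#' @export
read_decomposition <- function(dir) {
  m_dt <- data.table::fread(file.path(dir, "M.tsv"), header = TRUE)
  M <- as.matrix(m_dt[, -1, drop = FALSE])
  rownames(M) <- m_dt[[1]]
  a_dt <- data.table::fread(file.path(dir, "A.tsv"), header = TRUE)
  A <- matrix(as.matrix(a_dt[, -1, drop = FALSE]), nrow = nrow(a_dt),
              dimnames = list(a_dt[[1]], colnames(a_dt)[-1]))
  man_path <- file.path(dir, "decomposition_manifest.json")
  man <- if (file.exists(man_path)) jsonlite::read_json(man_path,
                                                        simplifyVector = TRUE)
  else list()
  structure(list(M = M, A = A, K = ncol(M),
                 cluster_support = man$cluster_support,
                 seeds_used = man$seeds_used,
                 n_runs_converged = man$n_runs_converged,
                 params = man$params),
            class = "robust_decomposition")
}

#' Read iModulons back from imodulons.json
#' @param path JSON path written by [write_imodulons_json()].
#' @param decomp the matching `robust_decomposition` (weights source).
#' @return List of `imodulon` objects.
#' @export
read_imodulons_json <- function(path, decomp) {
  objs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(objs, function(o) {
    structure(list(component_id = o$component_id,
                   weights = decomp$M[, o$component_id],
                   threshold = o$threshold,
                   members = unlist(o$members) %||% character(0),
                   degenerate = isTRUE(o$degenerate),
                   category = o$category %||% NA_character_),
              class = "imodulon")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
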