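# Scoring member sets against a curated transcriptional regulatory network:
# Fisher's exact (hypergeometric) over-representation, Benjamini-Hochberg
# FDR, recall-based quadrant classification, and TRN-expansion accounting.

#' Construct a TRN object
#'
#' @param associations data.frame with columns regulator, target and
#'   optionally evidence; duplicate (regulator, target) pairs are an error.
#' @param gene_universe character vector of all locus tags in the expression
#'   space (the enrichment background).
#' @return List of class `trn`: `associations`, `gene_universe`, `regulons`
#'   (named list regulator -> target set).
#' @export
make_trn <- function(associations, gene_universe) {
  stopifnot(all(c("regulator", "target") %in% names(associations)))
  if (!"evidence" %in% names(associations))
    associations$evidence <- rep("", nrow(associations))
  key <- paste(associations$regulator, associations$target)
  if (anyDuplicated(key)) stop("duplicate (regulator, target) pair in TRN")
  outside <- setdiff(associations$target, gene_universe)
  if (length(outside))
    stop("TRN targets outside the gene universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  structure(list(associations = associations[, c("regulator", "target", "evidence")],
                 gene_universe = unique(gene_universe),
                 regulons = split(associations$target, associations$regulator)),
            class = "trn")
}

#' Read a TRN from CSV/TSV (columns regulator, target, evidence)
#' @param path file path.
#' @param gene_universe background gene set.
#' @return A `trn` object.
#' @export
read_trn <- function(path, gene_universe) {
  if (!file.exists(path)) stop("TRN file not found: ", path)
  make_trn(as.data.frame(data.table::fread(path, header = TRUE)), gene_universe)
}

#' Fisher's exact over-representation p-value
#'
#' One-sided hypergeometric tail probability P(overlap >= observed) of the
#' intersection between an iModulon member set and a regulon drawn from a
#' common gene universe.
#'
#' @param members non-empty gene set.
#' @param regulon gene set.
#' @param universe_size total number of genes in the background.
#' @return p-value in (0, 1].
#' @export
fisher_enrichment <- function(members, regulon, universe_size) {
  if (!length(members)) stop("empty member set")
  members <- unique(members); regulon <- unique(regulon)
  if (universe_size < length(union(members, regulon)))
    stop("universe smaller than the union of the two sets")
  k <- length(intersect(members, regulon))
  stats::phyper(k - 1, length(regulon), universe_size - length(regulon),
                length(members), lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#' @param p_values numeric vector of p-values in (0, 1].
#' @return Step-up adjusted q-values.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1 | !is.finite(p_values)))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' iModulon recall and regulon recall of a member-set/regulon overlap
#'
#' iModulon recall (precision of the iModulon) = |overlap| / |members|;
#' regulon recall (coverage of the regulon) = |overlap| / |regulon|.
#'
#' @param members non-empty gene set.
#' @param regulon non-empty gene set.
#' @return Named numeric vector c(imodulon_recall, regulon_recall).
#' @export
compute_recalls <- function(members, regulon) {
  if (!length(members) || !length(regulon)) stop("empty input set")
  ov <- length(intersect(unique(members), unique(regulon)))
  c(imodulon_recall = ov / length(unique(members)),
    regulon_recall = ov / length(unique(regulon)))
}

#' Classify an (iModulon recall, regulon recall) pair into a quadrant
#'
#' Boundary-inclusive at the cut (default 0.7): both high = well-matched;
#' high iModulon recall only = regulon subset (the iModulon sits inside a
#' larger regulon); high regulon recall only = unknown-containing (the
#' iModulon covers the regulon plus unknown genes); both low = closest
#' match.
#'
#' @param imodulon_recall,regulon_recall values in [0, 1].
#' @param cut quadrant cut (default 0.7).
#' @return One of "well-matched", "regulon subset", "unknown-containing",
#'   "closest match".
#' @export
classify_quadrant <- function(imodulon_recall, regulon_recall, cut = 0.7) {
  stopifnot(imodulon_recall >= 0, imodulon_recall <= 1,
            regulon_recall >= 0, regulon_recall <= 1)
  if (imodulon_recall >= cut) {
    if (regulon_recall >= cut) "well-matched" else "regulon subset"
  } else {
    if (regulon_recall >= cut) "unknown-containing" else "closest match"
  }
}

#' Enrich every iModulon against every regulator of a TRN
#'
#' Computes the one-sided Fisher p-value of each (iModulon, regulator) pair,
#' adjusts all p-values jointly by Benjamini-Hochberg, and reports for each
#' iModulon its best-enriched regulator (lowest q, ties broken by larger
#' overlap then lexicographic regulator id) with recalls, quadrant, and the
#' regulatory flag (q below `regulatory_fdr`).
#'
#' @param imodulons list of `imodulon` objects (empty-member components are
#'   reported with NA enrichment).
#' @param trn a `trn` object.
#' @param regulatory_fdr FDR threshold for the regulatory flag
#'   (default 1e-4).
#' @param cut quadrant cut (default 0.7).
#' @return data.frame: component_id, regulator, p_value, q_value, overlap,
#'   imodulon_recall, regulon_recall, quadrant, is_regulatory.
#' @export
enrich_all <- function(imodulons, trn, regulatory_fdr = 1e-4, cut = 0.7) {
  stopifnot(inherits(trn, "trn"))
  if (nrow(trn$associations) == 0) stop("empty TRN")
  universe_size <- length(trn$gene_universe)
  regulators <- names(trn$regulons)

  grid <- do.call(rbind, lapply(imodulons, function(im) {
    if (!length(im$members)) return(NULL)
    do.call(rbind, lapply(regulators, function(reg) {
      regulon <- trn$regulons[[reg]]
      data.frame(component_id = im$component_id, regulator = reg,
                 p_value = fisher_enrichment(im$members, regulon, universe_size),
                 overlap = length(intersect(im$members, regulon)),
                 imodulon_recall = compute_recalls(im$members, regulon)[[1]],
                 regulon_recall = compute_recalls(im$members, regulon)[[2]],
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(grid) || !nrow(grid)) stop("no non-empty iModulons to enrich")
  grid$q_value <- fdr_adjust(grid$p_value)

  best <- do.call(rbind, lapply(split(grid, grid$component_id), function(g) {
    g <- g[order(g$q_value, -g$overlap, g$regulator), , drop = FALSE]
    g[1, , drop = FALSE]
  }))
  best$quadrant <- mapply(classify_quadrant, best$imodulon_recall,
                          best$regulon_recall, MoreArgs = list(cut = cut))
  best$is_regulatory <- best$q_value < regulatory_fdr
  # keep the iModulon input order
  best <- best[match(vapply(imodulons, `[[`, "", "component_id"),
                     best$component_id), , drop = FALSE]
  best <- best[!is.na(best$component_id), , drop = FALSE]
  rownames(best) <- NULL
  best[, c("component_id", "regulator", "p_value", "q_value", "overlap",
           "imodulon_recall", "regulon_recall", "quadrant", "is_regulatory")]
}

#' Count regulator-target associations implied by enriched iModulons
#'
#' Each (enriched regulator, member gene) pair over the declared component
#' set is counted once; pairs absent from the known TRN are novel, and the
#' expansion fraction is novel / |known TRN associations|.
#'
#' @param results data.frame from [enrich_all()].
#' @param imodulons list of `imodulon` objects (source of member sets).
#' @param trn the known `trn`.
#' @param component_ids optional subset of component ids to count (default:
#'   all components present in `results`).
#' @return List: `total_associations`, `novel_associations`,
#'   `expansion_fraction`, `pairs` (data.frame regulator/target/novel).
#' @export
count_trn_expansion <- function(results, imodulons, trn, component_ids = NULL) {
  stopifnot(inherits(trn, "trn"))
  if (is.null(component_ids)) component_ids <- results$component_id
  members_of <- stats::setNames(lapply(imodulons, `[[`, "members"),
                                vapply(imodulons, `[[`, "", "component_id"))
  pairs <- do.call(rbind, lapply(component_ids, function(cid) {
    row <- results[results$component_id == cid, , drop = FALSE]
    if (nrow(row) != 1 || !length(members_of[[cid]])) return(NULL)
    data.frame(regulator = row$regulator, target = members_of[[cid]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) {
    return(list(total_associations = 0L, novel_associations = 0L,
                expansion_fraction = 0, pairs = NULL))
  }
  pairs <- unique(pairs)
  known <- paste(trn$associations$regulator, trn$associations$target)
  pairs$novel <- !(paste(pairs$regulator, pairs$target) %in% known)
  list(total_associations = nrow(pairs),
       novel_associations = sum(pairs$novel),
       expansion_fraction = sum(pairs$novel) / nrow(trn$associations),
       pairs = pairs)
}

#' Write an enrichment table as TSV
#' @param results data.frame from [enrich_all()].
#' @param path output path.
#' @export
write_enrichment <- function(results, path) {
  data.table::fwrite(results, path, sep = "\t")
  invisible(path)
}
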