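# Two-level functional classification of regulated genes: functional role ->
# Specific Functional Category (SFC) -> Overall Functional Category (OFC),
# with the Miscellaneous fallback for unmapped or empty roles.

#' Assign SFC and OFC categories to genes
#'
#' Roles are matched exactly after case/whitespace normalization. Genes with
#' an empty or unmapped role receive SFC "Other or unknown functional roles"
#' and OFC "Miscellaneous". Every gene receives exactly one (SFC, OFC) pair.
#'
#' @param genes data.frame with at least gene_id and functional_role columns
#'   (extra columns such as genome_id, motif_id, taxgroup_id are carried
#'   through).
#' @param fmap a `FunctionalMap` from [read_functional_map()].
#' @return `genes` with `sfc` and `ofc` columns appended.
#' @export
assign_categories <- function(genes, fmap) {
  idx <- match(normalize_role(genes$functional_role), fmap$role_norm)
  genes$sfc <- ifelse(is.na(idx), "Other or unknown functional roles",
                      fmap$sfc[idx])
  genes$ofc <- ifelse(is.na(idx), "Miscellaneous", fmap$ofc[idx])
  genes
}

#' Collect the regulated genes of a set of regulogs
#'
#' Expands regulog member operons to their genes, one record per
#' (gene, motif, taxgroup): a gene regulated by two motif families is counted
#' once per family; within one family a gene appearing in several regulated
#' operons (after deduplication of operon membership) is counted once.
#'
#' @param regulogs regulog table from [assemble_regulogs()].
#' @param operons operon table.
#' @param genomes named list of [Genome] objects.
#' @return data.frame motif_id, taxgroup_id, genome_id, gene_id,
#'   functional_role.
#' @export
regulog_genes <- function(regulogs, operons, genomes) {
  rows <- list()
  for (i in seq_len(nrow(regulogs))) {
    ops <- unique(regulogs$operon_ids[[i]])
    for (op in ops) {
      oi <- which(operons$operon_id == op)
      gid <- operons$genome_id[oi]
      genes <- operons$gene_ids[[oi]]
      gt <- genomes[[gid]]$genes
      role <- gt$functional_role[match(genes, gt$gene_id)]
      rows[[length(rows) + 1]] <- data.frame(
        motif_id = regulogs$motif_id[i], taxgroup_id = regulogs$taxgroup_id[i],
        genome_id = gid, gene_id = genes, functional_role = role,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_id = character(), taxgroup_id = character(),
               genome_id = character(), gene_id = character(),
               functional_role = character(), stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("motif_id", "genome_id", "gene_id")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count genes per functional category
#'
#' @param assignments output of [assign_categories()] on regulated genes
#'   (one row per gene-motif record).
#' @param level `"sfc"` or `"ofc"`.
#' @param by grouping columns, default motif and taxgroup.
#' @return data.frame of grouping columns, category and n. The grand total of
#'   n equals the number of input records at either level.
#' @export
category_counts <- function(assignments, level = c("sfc", "ofc"),
                            by = c("motif_id", "taxgroup_id")) {
  level <- match.arg(level)
  if (nrow(assignments) == 0) {
    out <- assignments[, intersect(by, names(assignments)), drop = FALSE]
    out$category <- character(0)
    out$n <- integer(0)
    return(out)
  }
  f <- c(assignments[by], list(category = assignments[[level]]))
  agg <- stats::aggregate(list(n = seq_len(nrow(assignments))), by = f, FUN = length)
  agg <- agg[do.call(order, agg[c(by, "category")]), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
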