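# Distribution and composition statistics: presence matrix with A-F motif
# classification, per-lineage and per-motif aggregates under the mixed
# integer/one-decimal formatting rule, OFC proportions and tandem statistics.

#' Classify a motif's taxonomic distribution
#'
#' Ribosomal leaders, amino acid leaders and T-boxes are fixed to groups D, E
#' and F by motif class. Riboswitches and other motifs are classified by
#' presence: group A when present in more than 75% of taxonomic groups,
#' group C when present in no more than three groups, group B otherwise.
#'
#' @param n_present number of taxonomic groups with at least one accepted
#'   regulog of the motif.
#' @param motif_class one of riboswitch, pyrR, ribosomal_leader, aa_leader,
#'   tbox.
#' @param n_groups total number of taxonomic groups analyzed. Default 24.
#' @return a group letter in A-F.
#' @export
classify_distribution_group <- function(n_present, motif_class, n_groups = 24) {
  switch(motif_class,
         ribosomal_leader = "D",
         aa_leader = "E",
         tbox = "F",
         {
           if (n_present / n_groups > 0.75) "A"
           else if (n_present <= 3) "C"
           else "B"
         })
}

#' Motif-by-taxgroup presence matrix with distribution groups
#'
#' Presence is derived from accepted regulogs only.
#'
#' @param regulogs regulog table from [assemble_regulogs()].
#' @param registry a `MotifRegistry`.
#' @param taxgroups character vector of all analyzed taxonomic group ids.
#' @return list with `presence` (logical motif x taxgroup matrix) and
#'   `groups` (data.frame motif_id, n_present, distribution_group).
#' @export
distribution_matrix <- function(regulogs, registry, taxgroups) {
  motifs <- registry$motif_id
  presence <- matrix(FALSE, length(motifs), length(taxgroups),
                     dimnames = list(motifs, taxgroups))
  if (nrow(regulogs))
    presence[cbind(match(regulogs$motif_id, motifs),
                   match(regulogs$taxgroup_id, taxgroups))] <- TRUE
  groups <- data.frame(
    motif_id = motifs,
    n_present = rowSums(presence),
    distribution_group = vapply(seq_along(motifs), function(i)
      classify_distribution_group(sum(presence[i, ]), registry$motif_class[i],
                                  length(taxgroups)), ""),
    stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  list(presence = presence, groups = groups)
}

#' Per-lineage totals from assembled regulogs
#'
#' @param regulogs regulog table.
#' @param genomes named list of [Genome] objects (defines lineage genome
#'   counts, including lineages with zero regulogs).
#' @return data.frame taxgroup_id, genomes, sites, regulogs, genes.
#' @export
lineage_summary <- function(regulogs, genomes) {
  tg <- vapply(genomes, function(g) g$taxgroup_id, "")
  groups <- sort(unique(tg))
  out <- data.frame(taxgroup_id = groups,
                    genomes = as.integer(table(tg)[groups]),
                    sites = 0L, regulogs = 0L, genes = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(regulogs)) {
    agg <- stats::aggregate(cbind(sites = total_sites, genes = total_genes) ~
                              taxgroup_id, data = regulogs, FUN = sum)
    cnt <- stats::aggregate(list(regulogs = regulogs$motif_id),
                            by = list(taxgroup_id = regulogs$taxgroup_id),
                            FUN = length)
    i <- match(agg$taxgroup_id, out$taxgroup_id)
    out$sites[i] <- agg$sites; out$genes[i] <- agg$genes
    out$regulogs[match(cnt$taxgroup_id, out$taxgroup_id)] <- cnt$regulogs
  }
  out
}

#' Per-lineage statistics table with per-genome ratios and a grand-total row
#'
#' Per-genome ratios follow the mixed formatting rule of [format_ratio()]
#' (integers at 10 and above, one decimal below, half-up). Two grand-total
#' conventions are used deliberately and labeled in the `convention`
#' attribute: the grand sites-per-genome ratio is weighted (grand site total
#' over grand genome total) while the grand genes-per-genome value is the
#' unweighted mean of the lineage per-genome ratios. Lineages with zero
#' genomes yield zero ratios rather than division errors.
#'
#' @param totals data.frame with columns taxgroup_id, genomes, sites,
#'   regulogs, genes (e.g. from [lineage_summary()] or a transcribed
#'   reference table).
#' @return data.frame of the input plus sites_per_genome and genes_per_genome
#'   columns and a final `TOTAL` row; attribute `convention` documents the
#'   two grand-row averaging rules.
#' @export
lineage_stats <- function(totals) {
  t <- totals
  spg_raw <- ifelse(t$genomes > 0, t$sites / t$genomes, 0)
  gpg_raw <- ifelse(t$genomes > 0, t$genes / t$genomes, 0)
  t$sites_per_genome <- format_ratio(spg_raw)
  t$genes_per_genome <- format_ratio(gpg_raw)
  grand <- data.frame(
    taxgroup_id = "TOTAL", genomes = sum(t$genomes), sites = sum(t$sites),
    regulogs = sum(t$regulogs), genes = sum(t$genes),
    sites_per_genome = if (sum(t$genomes) > 0)
      format_ratio(sum(t$sites) / sum(t$genomes)) else 0,
    genes_per_genome = if (nrow(t) > 0) format_ratio(mean(gpg_raw)) else 0,
    stringsAsFactors = FALSE)
  out <- rbind(t[, names(grand)], grand)
  rownames(out) <- NULL
  attr(out, "convention") <- c(
    sites_per_genome = "grand row: weighted (total sites / total genomes)",
    genes_per_genome = "grand row: unweighted mean of lineage per-genome values")
  out
}

#' Per-motif totals from assembled regulogs
#'
#' @param regulogs regulog table.
#' @param regulated regulated-operon table (defines genomes with at least one
#'   site per motif).
#' @return data.frame motif_id, sites, genes, genomes_with_site.
#' @export
motif_summary <- function(regulogs, regulated) {
  if (nrow(regulogs) == 0)
    return(data.frame(motif_id = character(), sites = integer(),
                      genes = integer(), genomes_with_site = integer(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(cbind(sites = total_sites, genes = total_genes) ~
                            motif_id, data = regulogs, FUN = sum)
  gws <- vapply(agg$motif_id, function(m) {
    ops <- unlist(regulogs$operon_ids[regulogs$motif_id == m])
    length(unique(regulated$genome_id[regulated$operon_id %in% ops &
                                        regulated$motif_id == m]))
  }, integer(1))
  agg$genomes_with_site <- unname(gws)
  agg
}

#' Per-motif aggregate statistics
#'
#' Genes per genome is total genes over genomes carrying at least one site of
#' the motif; genes per riboswitch is total genes over total sites. Both are
#' formatted under the mixed integer/one-decimal rule. Motifs with zero sites
#' get `NA` ratios and an `undefined` flag.
#'
#' @param totals data.frame with columns motif_id, sites, genes,
#'   genomes_with_site (e.g. from [motif_summary()] or a transcribed
#'   reference table).
#' @return data.frame of the input plus genes_per_genome,
#'   genes_per_riboswitch and undefined columns.
#' @export
motif_stats <- function(totals) {
  t <- totals
  t$genes_per_genome <- ifelse(t$genomes_with_site > 0,
                               format_ratio(t$genes / t$genomes_with_site),
                               NA_real_)
  t$genes_per_riboswitch <- ifelse(t$sites > 0,
                                   format_ratio(t$genes / t$sites), NA_real_)
  t$undefined <- t$sites == 0
  t
}

#' OFC proportions per taxonomic group or per motif
#'
#' Proportions of Overall Functional Categories among the regulated genes
#' with an assigned function: genes in the "Other or unknown functional
#' roles" SFC are excluded before normalization (the other Miscellaneous
#' SFCs participate). Scopes whose genes are all unknown are reported as
#' `NA` proportions with `label = "N/A"`. Within a scope, proportions sum to
#' one (within 1e-9) whenever any classified gene exists.
#'
#' @param assignments output of [assign_categories()] on regulated genes.
#' @param scope `"taxgroup"` or `"motif"`.
#' @return data.frame scope, ofc, n, proportion, label.
#' @export
ofc_proportions <- function(assignments, scope = c("taxgroup", "motif")) {
  scope <- match.arg(scope)
  col <- if (scope == "taxgroup") "taxgroup_id" else "motif_id"
  scopes <- unique(assignments[[col]])
  rows <- list()
  for (s in scopes) {
    sub <- assignments[assignments[[col]] == s, , drop = FALSE]
    known <- sub[sub$sfc != "Other or unknown functional roles", , drop = FALSE]
    if (nrow(known) == 0) {
      rows[[length(rows) + 1]] <- data.frame(scope = s, ofc = NA_character_,
                                             n = 0L, proportion = NA_real_,
                                             label = "N/A",
                                             stringsAsFactors = FALSE)
      next
    }
    tab <- table(known$ofc)
    rows[[length(rows) + 1]] <- data.frame(scope = s, ofc = names(tab),
                                           n = as.integer(tab),
                                           proportion = as.numeric(tab) / nrow(known),
                                           label = "", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tandem-arrangement statistics for one motif's regulated operons
#'
#' @param regulated regulated-operon table restricted to one motif family.
#' @return list with `tandem_fraction` (tandem operons over regulated
#'   operons), `mean_operon_size` (each operon counted once regardless of
#'   tandem sites) and `n_operons`; all `NA` with `undefined = TRUE` when
#'   there are no regulated operons.
#' @export
tandem_stats <- function(regulated) {
  if (nrow(regulated) == 0)
    return(list(tandem_fraction = NA_real_, mean_operon_size = NA_real_,
                n_operons = 0L, undefined = TRUE))
  list(tandem_fraction = mean(regulated$tandem),
       mean_operon_size = mean(regulated$n_genes),
       n_operons = nrow(regulated), undefined = FALSE)
}
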