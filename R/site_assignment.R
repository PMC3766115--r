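# Assignment of filtered RNA motif hits to target operons through the
# upstream window anchored at the leader gene's start codon, plus overlap
# deduplication and tandem detection.

#' Deduplicate overlapping hits of one motif family
#'
#' Among hits of the same family whose genomic intervals overlap (within one
#' genome, contig and strand), only the highest-scoring hit is retained.
#' Selection is greedy by descending score with ties broken by leftmost start,
#' then lexicographic site_id. Interval overlap is computed with `IRanges`.
#'
#' @param sites site data.frame (any mix of genomes/motifs; grouping is
#'   internal).
#' @return deduplicated site data.frame.
#' @export
deduplicate_hits <- function(sites) {
  if (nrow(sites) == 0) return(sites)
  grp <- paste(sites$genome_id, sites$motif_id, sites$contig_id, sites$strand,
               sep = "\r")
  keep <- logical(nrow(sites))
  for (idx in split(seq_len(nrow(sites)), grp)) {
    ord <- idx[order(-sites$score[idx], sites$start[idx], sites$site_id[idx])]
    kept <- integer(0)
    for (i in ord) {
      if (length(kept)) {
        ov <- IRanges::countOverlaps(
          IRanges::IRanges(sites$start[i], sites$end[i]),
          IRanges::IRanges(sites$start[kept], sites$end[kept]))
        if (ov > 0) next
      }
      kept <- c(kept, i)
    }
    keep[kept] <- TRUE
  }
  out <- sites[keep, , drop = FALSE]
  out <- out[order(out$genome_id, out$motif_id, out$contig_id, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign RNA sites to target operons via the upstream window
#'
#' A site qualifies for an operon when both lie on the same contig and strand
#' and the site's gene-proximal end (its end coordinate for a plus-strand
#' operon, its start coordinate for a minus-strand operon) falls between
#' `upstream` nucleotides upstream and `downstream` nucleotides downstream of
#' the leader gene's start codon, measured in gene orientation. Each site goes
#' to at most one operon: if it qualifies for several (divergent anchors), the
#' operon whose start codon is nearest wins; an exact distance tie leaves the
#' site unassigned and flagged ambiguous for curation. Multiple same-family
#' sites assigned to one operon form a single regulated operon with
#' `tandem = TRUE`.
#'
#' @param sites deduplicated site data.frame.
#' @param operons operon table from [infer_operons()] (one or many genomes).
#' @param upstream window extent upstream of the start codon (nt). Default 500.
#' @param downstream window extent downstream of the start codon (nt).
#'   Default 100.
#' @return list with elements
#'   * `assigned`: data.frame site_id, motif_id, genome_id, operon_id,
#'     distance (signed nt; negative = upstream of the start codon);
#'   * `ambiguous`: same columns for exact-tie sites (operon_id comma-joined);
#'   * `orphans`: sites qualifying for no operon;
#'   * `regulated`: one row per (motif_id, operon_id) with site_ids (list),
#'     n_sites, tandem, site_to_start_distance (distance of the nearest site)
#'     and the operon's genome_id/n_genes/leader columns.
#' @export
assign_sites <- function(sites, operons, upstream = 500, downstream = 100) {
  stopifnot(upstream >= 0, downstream >= 0)
  asg <- data.frame(site_id = character(), motif_id = character(),
                    genome_id = character(), operon_id = character(),
                    distance = integer(), stringsAsFactors = FALSE)
  amb <- asg
  orphan_idx <- integer(0)
  if (nrow(sites)) {
    for (i in seq_len(nrow(sites))) {
      cand <- operons[operons$genome_id == sites$genome_id[i] &
                        operons$contig_id == sites$contig_id[i] &
                        operons$strand == sites$strand[i], , drop = FALSE]
      if (nrow(cand) == 0) { orphan_idx <- c(orphan_idx, i); next }
      prox <- if (sites$strand[i] == "+") sites$end[i] else sites$start[i]
      d <- if (sites$strand[i] == "+") prox - cand$leader_start_codon
           else cand$leader_start_codon - prox
      ok <- d >= -upstream & d <= downstream
      if (!any(ok)) { orphan_idx <- c(orphan_idx, i); next }
      cand <- cand[ok, , drop = FALSE]; d <- d[ok]
      best <- abs(d) == min(abs(d))
      row <- data.frame(site_id = sites$site_id[i], motif_id = sites$motif_id[i],
                        genome_id = sites$genome_id[i],
                        operon_id = paste(cand$operon_id[best], collapse = ","),
                        distance = d[best][1], stringsAsFactors = FALSE)
      if (sum(best) > 1) amb <- rbind(amb, row) else asg <- rbind(asg, row)
    }
  }
  orphans <- sites[orphan_idx, , drop = FALSE]
  rownames(orphans) <- NULL

  if (nrow(asg)) {
    key <- paste(asg$motif_id, asg$operon_id, sep = "\r")
    regulated <- do.call(rbind, lapply(split(seq_len(nrow(asg)), key), function(ix) {
      op <- operons[operons$operon_id == asg$operon_id[ix[1]], , drop = FALSE]
      nearest <- ix[which.min(abs(asg$distance[ix]))]
      data.frame(motif_id = asg$motif_id[ix[1]], genome_id = asg$genome_id[ix[1]],
                 operon_id = asg$operon_id[ix[1]],
                 site_ids = I(list(sort(asg$site_id[ix]))),
                 n_sites = length(ix), tandem = length(ix) >= 2,
                 site_to_start_distance = asg$distance[nearest],
                 n_genes = op$n_genes, leader_gene = op$leader_gene,
                 taxgroup_id = NA_character_, stringsAsFactors = FALSE)
    }))
    rownames(regulated) <- NULL
  } else {
    regulated <- empty_regulated()
  }
  list(assigned = asg, ambiguous = amb, orphans = orphans, regulated = regulated)
}

empty_regulated <- function() {
  data.frame(motif_id = character(), genome_id = character(),
             operon_id = character(), site_ids = I(list()),
             n_sites = integer(), tandem = logical(),
             site_to_start_distance = integer(), n_genes = integer(),
             leader_gene = character(), taxgroup_id = character(),
             stringsAsFactors = FALSE)
}

#' Build per-genome regulons from regulated operons
#'
#' A regulon is the set of genes of one genome controlled by sites of one
#' motif family: one row per (motif_id, genome_id) with at least one regulated
#' operon. `gene_count` sums genes over member operons (tandem sites do not
#' multiply genes).
#'
#' @param regulated regulated-operon table from [assign_sites()].
#' @return data.frame motif_id, genome_id, n_operons, n_sites, gene_count,
#'   operon_ids (list column).
#' @export
build_regulons <- function(regulated) {
  if (nrow(regulated) == 0)
    return(data.frame(motif_id = character(), genome_id = character(),
                      n_operons = integer(), n_sites = integer(),
                      gene_count = integer(), operon_ids = I(list()),
                      stringsAsFactors = FALSE))
  key <- paste(regulated$motif_id, regulated$genome_id, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(regulated)), key), function(ix) {
    data.frame(motif_id = regulated$motif_id[ix[1]],
               genome_id = regulated$genome_id[ix[1]],
               n_operons = length(ix),
               n_sites = sum(regulated$n_sites[ix]),
               gene_count = sum(regulated$n_genes[ix]),
               operon_ids = I(list(regulated$operon_id[ix])),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
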