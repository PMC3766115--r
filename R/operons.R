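# Operon inference: partition each genome's genes into operons by the
# intergenic-distance rule with the coding-region-overlap option.

#' Infer operons from a genome's gene annotations
#'
#' Walks the genes of each contig in genomic order and merges a gene into the
#' current operon when it lies on the same strand and either the intergenic
#' gap (`next.start - prev.end - 1`, the number of nucleotides strictly
#' between coding regions) is at most `max_gap`, or the coding regions overlap
#' (gap < 0) and `merge_overlaps` is on. A strand change always breaks the
#' operon. Nested genes (fully contained, same strand) are a special case of
#' the overlap rule and are merged. The gap is measured against the running
#' maximum end of the current operon so nesting cannot reopen a break.
#'
#' Within each operon, genes are ordered 5'→3' in transcription direction
#' (reversed genomic order on the minus strand); the first gene in that order
#' is the leader anchor whose translation start (start coordinate on `+`,
#' end coordinate on `-`) anchors the site-assignment window.
#'
#' @param genome a [Genome].
#' @param max_gap maximum intergenic distance (nt) for an operon boundary;
#'   the merge bound is inclusive. Default 200.
#' @param merge_overlaps merge genes whose coding regions overlap. Default TRUE.
#' @return data.frame with one row per operon: operon_id, genome_id,
#'   contig_id, strand, gene_ids (list column, transcription order), n_genes,
#'   leader_gene, leader_start_codon (genomic coordinate of the leader's
#'   translation start), span_start, span_end. The rows form a partition of
#'   the genome's genes.
#' @export
infer_operons <- function(genome, max_gap = 200, merge_overlaps = TRUE) {
  stopifnot(inherits(genome, "Genome"), max_gap >= 0)
  g <- genome$genes
  if (nrow(g) == 0) return(empty_operons())
  block <- integer(nrow(g))
  bid <- 0L
  prev_contig <- ""
  prev_strand <- ""
  prev_maxend <- -Inf
  for (i in seq_len(nrow(g))) {
    gap <- g$start[i] - prev_maxend - 1
    new_block <- g$contig_id[i] != prev_contig ||
      g$strand[i] != prev_strand ||
      (gap > max_gap) ||
      (gap < 0 && !merge_overlaps)
    if (new_block) {
      bid <- bid + 1L
      prev_maxend <- g$end[i]
    } else {
      prev_maxend <- max(prev_maxend, g$end[i])
    }
    block[i] <- bid
    prev_contig <- g$contig_id[i]
    prev_strand <- g$strand[i]
  }
  rows <- lapply(split(seq_len(nrow(g)), block), function(idx) {
    strand <- g$strand[idx[1]]
    ord <- if (strand == "+") idx[order(g$start[idx])] else idx[order(-g$end[idx])]
    leader <- ord[1]
    data.frame(genome_id = genome$genome_id, contig_id = g$contig_id[idx[1]],
               strand = strand,
               gene_ids = I(list(g$gene_id[ord])),
               n_genes = length(idx),
               leader_gene = g$gene_id[leader],
               leader_start_codon = if (strand == "+") g$start[leader] else g$end[leader],
               span_start = min(g$start[idx]), span_end = max(g$end[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig_id, out$span_start), , drop = FALSE]
  out <- cbind(operon_id = sprintf("%s.op%04d", genome$genome_id,
                                   seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_operons <- function() {
  data.frame(operon_id = character(), genome_id = character(),
             contig_id = character(), strand = character(),
             gene_ids = I(list()), n_genes = integer(),
             leader_gene = character(), leader_start_codon = integer(),
             span_start = integer(), span_end = integer(),
             stringsAsFactors = FALSE)
}

#' Write an operon table to TSV
#'
#' Gene ids are comma-joined in transcription order.
#'
#' @param operons operon table from [infer_operons()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_operons <- function(operons, path) {
  out <- operons
  out$gene_ids <- vapply(operons$gene_ids, paste, "", collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse-complement a genome's coordinate system
#'
#' Maps every gene to start' = L - end + 1, end' = L - start + 1 on its contig
#' of length L and flips strands. Used by the strand-symmetry property tests:
#' operon partitions and site assignments must be invariant under this
#' transform.
#'
#' @param genome a [Genome].
#' @return transformed [Genome].
#' @export
revcomp_genome <- function(genome) {
  g <- genome$genes
  L <- genome$contigs[g$contig_id]
  new_start <- L - g$end + 1L
  new_end <- L - g$start + 1L
  g$start <- as.integer(new_start)
  g$end <- as.integer(new_end)
  g$strand <- ifelse(g$strand == "+", "-", "+")
  Genome(genome$genome_id, genome$taxgroup_id, g, contigs = genome$contigs)
}

#' Reverse-complement a site table against contig lengths
#'
#' @param sites site data.frame.
#' @param contigs named integer vector of contig lengths.
#' @return transformed site data.frame.
#' @export
revcomp_sites <- function(sites, contigs) {
  L <- contigs[sites$contig_id]
  ns <- L - sites$end + 1L
  ne <- L - sites$start + 1L
  sites$start <- as.integer(ns)
  sites$end <- as.integer(ne)
  sites$strand <- ifelse(sites$strand == "+", "-", "+")
  sites
}
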