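# Shared fixture builders. Everything is constructed in code; no data files.

# quick gene table: each argument is c(start, end), names give ids,
# strands supplied in parallel
gene_table <- function(ids, starts, ends, strands, contig = "c1", roles = "") {
  data.frame(gene_id = ids, contig_id = contig, start = starts, end = ends,
             strand = strands, locus_tag = ids,
             functional_role = rep_len(roles, length(ids)),
             stringsAsFactors = FALSE)
}

make_genome <- function(ids, starts, ends, strands, contig = "c1",
                        genome_id = "G1", taxgroup_id = "tgX", roles = "",
                        contigs = NULL) {
  Genome(genome_id, taxgroup_id,
         gene_table(ids, starts, ends, strands, contig, roles),
         contigs = contigs)
}

make_sites <- function(ids, motif, genome, starts, ends, strands,
                       contig = "c1", scores = 50) {
  data.frame(site_id = ids, motif_id = motif, genome_id = genome,
             contig_id = contig, start = as.integer(starts),
             end = as.integer(ends), strand = strands,
             score = rep_len(scores, length(ids)), stringsAsFactors = FALSE)
}

tiny_registry <- function(high_conf = 70) {
  r <- data.frame(
    motif_id = c("RF00059", "RF00504", "RF00230"),
    name = c("TPP", "Glycine", "T-box"),
    motif_class = c("riboswitch", "riboswitch", "tbox"),
    effector = c("thiamin pyrophosphate", "glycine", "-"),
    score_threshold = 30, high_conf_threshold = high_conf,
    stringsAsFactors = FALSE)
  class(r) <- c("MotifRegistry", "data.frame")
  r
}

make_orthology <- function(genome_ids, gene_ids, groups) {
  o <- data.frame(genome_id = genome_ids, gene_id = gene_ids,
                  ortholog_group_id = groups, stringsAsFactors = FALSE)
  class(o) <- c("OrthologyMap", "data.frame")
  o
}

bundled_fmap <- function() {
  read_functional_map(system.file("extdata", "functional_categories.tsv",
                                  package = "rnaregulon"))
}

# independent brute-force oracle for CRON merging: transitive closure over
# the pairwise Jaccard predicate, computed by repeated reachability expansion
# (no graph library)
oracle_components <- function(og_sets, min_jaccard = 0.5) {
  n <- length(og_sets)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    u <- length(union(og_sets[[i]], og_sets[[j]]))
    jac <- if (u == 0) 0 else length(intersect(og_sets[[i]], og_sets[[j]])) / u
    if (jac >= min_jaccard) adj[i, j] <- TRUE
  }
  repeat {
    reach <- (adj %*% adj) > 0
    if (identical(reach, adj > 0)) break
    adj <- reach
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[which(adj[i, ])] <- next_id
    }
  }
  comp
}

# canonical partition signature so component labelings can be compared
partition_signature <- function(membership) {
  unname(lapply(sort(vapply(split(seq_along(membership), membership),
                            function(ix) paste(ix, collapse = ","), "")),
                identity))
}
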