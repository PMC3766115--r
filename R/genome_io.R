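# Readers and writers for the shared data model: genomes (gene annotations),
# RNA motif hit tables, the motif registry, orthology and the functional map.
# Coordinates are 1-based inclusive throughout (GFF3 convention).

#' Construct a Genome object
#'
#' A Genome bundles a genome identifier, its taxonomic group, contig lengths
#' and a gene table. Genes are sorted by (contig, start); invariants (strand
#' alphabet, coordinate sanity, uniqueness, contig containment) are enforced
#' here so every reader and the simulator share one validator.
#'
#' @param genome_id genome identifier.
#' @param taxgroup_id taxonomic group the genome belongs to.
#' @param genes data.frame with columns gene_id, contig_id, start, end,
#'   strand, locus_tag, functional_role.
#' @param contigs named integer vector of contig lengths. If omitted, each
#'   contig length is set just past its last gene.
#' @return object of class `Genome`.
#' @export
Genome <- function(genome_id, taxgroup_id, genes, contigs = NULL) {
  stopifnot(is.character(genome_id), nzchar(genome_id))
  if (!nzchar(taxgroup_id)) stop("taxgroup_id must be non-empty", call. = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes) == 0) genes <- empty_genes()
  need <- c("gene_id", "contig_id", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (is.null(genes$locus_tag)) genes$locus_tag <- genes$gene_id
  if (is.null(genes$functional_role)) genes$functional_role <- ""
  genes$functional_role[is.na(genes$functional_role)] <- ""
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)

  bad <- which(is.na(genes$start) | is.na(genes$end) | genes$start < 1L |
                 genes$end < genes$start)
  if (length(bad)) stop_record("malformed gene coordinates (need 1 <= start <= end)",
                               genes$gene_id[bad[1]])
  if (anyDuplicated(genes$gene_id))
    stop_record("duplicate gene_id", genes$gene_id[duplicated(genes$gene_id)][1])
  if (!all(genes$strand %in% c("+", "-")))
    stop_record("strand must be '+' or '-'",
                genes$gene_id[!genes$strand %in% c("+", "-")][1])

  if (is.null(contigs)) {
    contigs <- tapply(genes$end, genes$contig_id, max) + 1000L
    contigs <- stats::setNames(as.integer(contigs), names(contigs))
  }
  unknown <- setdiff(unique(genes$contig_id), names(contigs))
  if (length(unknown)) stop("genes on contigs without recorded length: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  over <- genes$end > contigs[genes$contig_id]
  if (any(over)) stop_record("gene extends past contig length", genes$gene_id[over][1])

  genes <- genes[order(genes$contig_id, genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, taxgroup_id = taxgroup_id,
                 contigs = contigs,
                 genes = genes[, c("gene_id", "contig_id", "start", "end",
                                   "strand", "locus_tag", "functional_role")]),
            class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome %s (taxgroup %s): %d genes on %d contig(s)\n",
              x$genome_id, x$taxgroup_id, nrow(x$genes), length(x$contigs)))
  invisible(x)
}

#' Read gene annotations into a Genome
#'
#' Supports GFF3 (via `rtracklayer`; only `gene` and `CDS` features are
#' ingested, `CDS` used only where no `gene` feature shares its ID) and a
#' simplified TSV dialect with columns gene_id, contig, start, end, strand,
#' locus_tag, functional_role.
#'
#' @param path annotation file.
#' @param format `"tsv"` or `"gff3"`.
#' @param genome_id,taxgroup_id identifiers attached to the Genome.
#' @param contigs optional named integer vector of contig lengths.
#' @return a [Genome].
#' @export
read_annotations <- function(path, format = c("tsv", "gff3"), genome_id,
                             taxgroup_id, contigs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such annotation file: ", path, call. = FALSE)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("gene_id", "contig", "start", "end", "strand")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("annotation TSV lacks columns: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    genes <- data.frame(gene_id = tab$gene_id, contig_id = tab$contig,
                        start = suppressWarnings(as.integer(tab$start)),
                        end = suppressWarnings(as.integer(tab$end)),
                        strand = tab$strand,
                        locus_tag = tab$locus_tag %||% tab$gene_id,
                        functional_role = tab$functional_role %||% "",
                        stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) %in% c("gene", "CDS")]
    if (length(gr) == 0) {
      genes <- empty_genes()
    } else {
      ids <- as.character(gr$ID %||% gr$locus_tag)
      ids[is.na(ids) | !nzchar(ids)] <- paste0("feat", seq_len(length(gr)))[
        is.na(ids) | !nzchar(ids)]
      type <- as.character(gr$type)
      keep <- type == "gene"
      # CDS records only stand in for genes that have no gene feature
      keep <- keep | (type == "CDS" & !ids %in% ids[type == "gene"])
      gr <- gr[keep]; ids <- ids[keep]
      role <- as.character(gr$product %||% rep("", length(gr)))
      role[is.na(role)] <- ""
      lt <- as.character(gr$locus_tag %||% ids)
      lt[is.na(lt)] <- ids[is.na(lt)]
      genes <- data.frame(gene_id = ids,
                          contig_id = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr),
                          end = GenomicRanges::end(gr),
                          strand = as.character(GenomicRanges::strand(gr)),
                          locus_tag = lt, functional_role = role,
                          stringsAsFactors = FALSE)
      genes <- genes[genes$strand %in% c("+", "-"), , drop = FALSE]
    }
  }
  Genome(genome_id, taxgroup_id, genes, contigs = contigs)
}

#' Write a Genome to the simplified annotation TSV
#'
#' Round-trip partner of [read_annotations()] with `format = "tsv"`.
#'
#' @param genome a [Genome].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(genome, path) {
  g <- genome$genes
  out <- data.frame(gene_id = g$gene_id, contig = g$contig_id, start = g$start,
                    end = g$end, strand = g$strand, locus_tag = g$locus_tag,
                    functional_role = g$functional_role,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the motif registry
#'
#' TSV with columns motif_id, name, motif_class, effector, score_threshold and
#' optionally high_conf_threshold (used by the CRON singleton rescue). The
#' per-family score_threshold plays the role of the family noise cutoff under
#' which covariance-model hits are discarded.
#'
#' @param path registry TSV.
#' @return data.frame of class `MotifRegistry`.
#' @export
read_registry <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("motif_id", "name", "motif_class", "score_threshold")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("registry lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(tab$motif_id))
    stop_record("duplicate motif_id in registry",
                tab$motif_id[duplicated(tab$motif_id)][1])
  ok_class <- c("riboswitch", "pyrR", "ribosomal_leader", "aa_leader", "tbox")
  if (!all(tab$motif_class %in% ok_class))
    stop("unknown motif_class: ",
         paste(setdiff(tab$motif_class, ok_class), collapse = ", "), call. = FALSE)
  tab$score_threshold <- as.numeric(tab$score_threshold)
  if (any(!is.finite(tab$score_threshold)))
    stop("non-finite score_threshold in registry", call. = FALSE)
  if (is.null(tab$effector)) tab$effector <- "unknown"
  if (is.null(tab$high_conf_threshold)) tab$high_conf_threshold <- Inf
  tab$high_conf_threshold <- as.numeric(tab$high_conf_threshold)
  tab$high_conf_threshold[is.na(tab$high_conf_threshold)] <- Inf
  class(tab) <- c("MotifRegistry", "data.frame")
  tab
}

#' Read RNA motif hits (Infernal tblout or TSV) and apply the score filter
#'
#' Two dialects are accepted. A cmsearch-style tblout (whitespace-delimited,
#' `#` comments; sequence name in column 1, model accession in column 4,
#' sequence from/to in columns 8/9, strand in column 10, bit score in column
#' 15) or a TSV with header motif_id, contig, start, end, strand, score.
#' Coordinates are normalized so start <= end with the strand kept separately
#' (tblout reports reversed coordinates for minus-strand hits). Hits scoring
#' below their family's registry threshold are dropped; the number dropped is
#' reported via `message()`.
#'
#' @param path hit table.
#' @param registry a `MotifRegistry` from [read_registry()].
#' @param genome_id genome the hits belong to.
#' @param format `"auto"`, `"tblout"` or `"tsv"`.
#' @return data.frame of retained sites (site_id, motif_id, genome_id,
#'   contig_id, start, end, strand, score).
#' @export
read_sites <- function(path, registry, genome_id, format = "auto") {
  if (!file.exists(path)) stop("no such site file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (format == "auto") {
    format <- if (length(body) && grepl("^motif_id\t", lines[1])) "tsv" else "tblout"
    if (length(body) == 0) format <- "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("motif_id", "contig", "start", "end", "strand", "score")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("site TSV lacks columns: ", paste(miss, collapse = ", "),
                           call. = FALSE)
    raw <- data.frame(motif_id = tab$motif_id, contig = tab$contig,
                      from = as.integer(tab$start), to = as.integer(tab$end),
                      strand = tab$strand, score_chr = as.character(tab$score),
                      stringsAsFactors = FALSE)
    if (!is.null(tab$site_id)) raw$site_id <- tab$site_id
  } else {
    if (length(body) == 0) {
      raw <- data.frame(motif_id = character(), contig = character(),
                        from = integer(), to = integer(), strand = character(),
                        score_chr = character(), stringsAsFactors = FALSE)
    } else {
      fields <- strsplit(trimws(body), "[[:space:]]+")
      short <- vapply(fields, length, 1L) < 15L
      if (any(short)) stop_record("tblout row with fewer than 15 fields",
                                  body[short][1])
      get <- function(i) vapply(fields, `[[`, "", i)
      motif <- get(4); noacc <- motif %in% c("-", "")
      motif[noacc] <- get(3)[noacc]
      raw <- data.frame(motif_id = motif, contig = get(1),
                        from = suppressWarnings(as.integer(get(8))),
                        to = suppressWarnings(as.integer(get(9))),
                        strand = get(10), score_chr = get(15),
                        stringsAsFactors = FALSE)
    }
  }
  if (nrow(raw) == 0) return(empty_sites())
  score <- suppressWarnings(as.numeric(raw$score_chr))
  if (any(is.na(score)))
    stop_record("unparsable score", raw$score_chr[is.na(score)][1])
  unknown <- setdiff(unique(raw$motif_id), registry$motif_id)
  if (length(unknown)) stop("motif_id absent from registry: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  sites <- data.frame(
    site_id = raw$site_id %||% sprintf("%s.site%04d", genome_id,
                                       seq_len(nrow(raw))),
    motif_id = raw$motif_id, genome_id = genome_id, contig_id = raw$contig,
    start = pmin(raw$from, raw$to), end = pmax(raw$from, raw$to),
    strand = ifelse(raw$strand == "-", "-",
                    ifelse(raw$from > raw$to, "-", "+")),
    score = score, stringsAsFactors = FALSE)
  filter_sites(sites, registry)
}

#' Drop sites scoring below their family threshold
#'
#' Idempotent: re-filtering the retained sites drops nothing.
#'
#' @param sites site data.frame.
#' @param registry a `MotifRegistry`.
#' @return filtered site data.frame.
#' @export
filter_sites <- function(sites, registry) {
  if (nrow(sites) == 0) return(sites)
  thr <- stats::setNames(registry$score_threshold, registry$motif_id)
  keep <- sites$score >= thr[sites$motif_id]
  if (any(!keep)) message(sum(!keep), " site(s) dropped below family threshold")
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an orthology map
#'
#' TSV with columns genome_id, gene_id, ortholog_group_id. Each gene maps to
#' at most one ortholog group; a gene listed twice with conflicting groups is
#' a hard error. Genes absent from the loaded genomes are tolerated (warning
#' at pipeline stage, not here).
#'
#' @param path orthology TSV.
#' @return data.frame of class `OrthologyMap`.
#' @export
read_orthology <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0) {
    tab <- data.frame(genome_id = character(), gene_id = character(),
                      ortholog_group_id = character(), stringsAsFactors = FALSE)
  }
  need <- c("genome_id", "gene_id", "ortholog_group_id")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("orthology TSV lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  key <- paste(tab$genome_id, tab$gene_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- match(key[dup], key)
    conflict <- tab$ortholog_group_id[dup] != tab$ortholog_group_id[first]
    if (any(conflict))
      stop_record("gene mapped to two ortholog groups",
                  paste(tab$genome_id[dup][conflict][1],
                        tab$gene_id[dup][conflict][1]))
    tab <- tab[!dup, , drop = FALSE]
  }
  rownames(tab) <- NULL
  class(tab) <- c("OrthologyMap", "data.frame")
  tab
}

#' Look up ortholog groups for genes
#'
#' @param orthology an `OrthologyMap`.
#' @param genome_id,gene_id parallel vectors identifying genes.
#' @return character vector of ortholog group ids; `NA` where unmapped.
#' @export
ortholog_group <- function(orthology, genome_id, gene_id) {
  key <- paste(orthology$genome_id, orthology$gene_id, sep = "\r")
  orthology$ortholog_group_id[match(paste(genome_id, gene_id, sep = "\r"), key)]
}

#' Genomes of a taxonomic group carrying at least one gene of an ortholog group
#'
#' @param orthology an `OrthologyMap`.
#' @param group ortholog group id.
#' @param genome_ids genomes of the taxonomic group to restrict to.
#' @return character vector of genome ids.
#' @export
genomes_with_group <- function(orthology, group, genome_ids) {
  hit <- orthology$genome_id[orthology$ortholog_group_id == group]
  intersect(genome_ids, unique(hit))
}

#' Read the two-level functional classification map
#'
#' TSV with columns functional_role, sfc, ofc (role -> Specific Functional
#' Category -> Overall Functional Category). Every SFC must map to exactly one
#' OFC; the scheme must contain the "Miscellaneous" OFC and the
#' "Other or unknown functional roles" SFC that receive unmapped genes.
#'
#' @param path functional map TSV.
#' @return data.frame of class `FunctionalMap`.
#' @export
read_functional_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("functional_role", "sfc", "ofc")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("functional map lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  amb <- tapply(tab$ofc, tab$sfc, function(x) length(unique(x)))
  if (any(amb > 1))
    stop("SFC mapped to more than one OFC: ",
         paste(names(amb)[amb > 1], collapse = ", "), call. = FALSE)
  if (!"Miscellaneous" %in% tab$ofc ||
      !"Other or unknown functional roles" %in% tab$sfc)
    stop("functional map must include the Miscellaneous OFC and the ",
         "'Other or unknown functional roles' SFC", call. = FALSE)
  tab$role_norm <- normalize_role(tab$functional_role)
  if (anyDuplicated(tab$role_norm))
    stop_record("duplicate functional role in map",
                tab$functional_role[duplicated(tab$role_norm)][1])
  class(tab) <- c("FunctionalMap", "data.frame")
  tab
}
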