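# T-box amino acid specificity: specifier codon extraction from a multiple
# alignment anchored at a declared reference codon span, translation by the
# standard genetic code, and splitting of lineage-level T-box regulogs into
# amino-acid-specific regulogs.

#' Construct a T-box alignment object
#'
#' @param seqs named character vector of equal-length gapped sequences over
#'   A, C, G, U/T and `-` (case-insensitive).
#' @param reference_id name of the reference (anchor) row.
#' @param reference_codon_span three strictly increasing 1-based ungapped
#'   positions in the reference marking the specifier codon.
#' @return object of class `TBoxAlignment`.
#' @export
TBoxAlignment <- function(seqs, reference_id, reference_codon_span) {
  seqs <- vapply(seqs, as.character, "")
  if (length(unique(nchar(seqs))) != 1)
    stop("alignment rows differ in length", call. = FALSE)
  if (!reference_id %in% names(seqs))
    stop("reference_id not in alignment: ", reference_id, call. = FALSE)
  span <- as.integer(reference_codon_span)
  if (length(span) != 3 || any(diff(span) <= 0))
    stop("reference_codon_span must be three strictly increasing positions",
         call. = FALSE)
  ref_ungapped <- nchar(gsub("-", "", seqs[[reference_id]]))
  if (span[3] > ref_ungapped)
    stop("reference_codon_span exceeds ungapped reference length (",
         ref_ungapped, ")", call. = FALSE)
  structure(list(seqs = seqs, reference_id = reference_id,
                 reference_codon_span = span), class = "TBoxAlignment")
}

#' Read a T-box alignment from aligned FASTA or Stockholm
#'
#' Parsing is delegated to `Biostrings` (`readBStringSet` /
#' `readRNAMultipleAlignment`).
#'
#' @param path alignment file.
#' @param reference_id,reference_codon_span see [TBoxAlignment()].
#' @param format `"fasta"` or `"stockholm"`.
#' @return a [TBoxAlignment].
#' @export
read_tbox_alignment <- function(path, reference_id, reference_codon_span,
                                format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- stats::setNames(as.character(ss), names(ss))
  } else {
    ma <- Biostrings::readRNAMultipleAlignment(path, format = "stockholm")
    us <- Biostrings::unmasked(ma)
    seqs <- stats::setNames(as.character(us), names(us))
  }
  TBoxAlignment(seqs, reference_id, reference_codon_span)
}

#' Map the reference specifier codon to alignment columns
#'
#' Converts the reference's ungapped codon positions to the alignment columns
#' they occupy, skipping gap columns in the reference row.
#'
#' @param alignment a [TBoxAlignment].
#' @return integer vector of three alignment column indices.
#' @export
map_anchor_columns <- function(alignment) {
  ref <- strsplit(alignment$seqs[[alignment$reference_id]], "")[[1]]
  ungapped <- cumsum(ref != "-")
  cols <- vapply(alignment$reference_codon_span,
                 function(p) which(ungapped == p & ref != "-")[1], integer(1))
  if (any(is.na(cols)))
    stop("reference row gaps inconsistent with the declared codon span",
         call. = FALSE)
  cols
}

# standard genetic code on the RNA alphabet, three-letter names
codon_to_aa3 <- function(codon) {
  dna <- chartr("Uu", "Tt", toupper(codon))
  aa1 <- Biostrings::GENETIC_CODE[dna]
  ifelse(is.na(aa1) | aa1 == "*", NA_character_,
         unname(Biostrings::AMINO_ACID_CODE[aa1]))
}

#' Call T-box amino acid specificities from an alignment
#'
#' For every row, the characters at the anchor columns form the specifier
#' codon. A codon containing a gap or any non-ACGU character (stop codons
#' included) is reported as `"unresolved"` with amino acid `"unassigned"`;
#' otherwise the codon is translated by the standard genetic code on the RNA
#' alphabet and the specificity group is the three-letter amino acid name
#' (all synonymous codons of one amino acid share a group), optionally
#' renamed through `group_map`.
#'
#' @param alignment a [TBoxAlignment].
#' @param group_map optional named character vector renaming amino acid names
#'   to configured specificity groups.
#' @return data.frame site_id, codon, amino_acid, specificity_group.
#' @export
call_specificity <- function(alignment, group_map = NULL) {
  cols <- map_anchor_columns(alignment)
  rows <- names(alignment$seqs)
  codons <- vapply(rows, function(r) {
    ch <- strsplit(alignment$seqs[[r]], "")[[1]][cols]
    paste(ch, collapse = "")
  }, "")
  codons <- chartr("t", "u", chartr("T", "U", codons))
  valid <- grepl("^[ACGUacgu]{3}$", codons)
  aa <- rep(NA_character_, length(codons))
  aa[valid] <- codon_to_aa3(codons[valid])
  resolved <- valid & !is.na(aa)
  group <- ifelse(resolved, aa, "unassigned")
  if (!is.null(group_map)) {
    hit <- resolved & group %in% names(group_map)
    group[hit] <- group_map[group[hit]]
  }
  data.frame(site_id = rows,
             codon = ifelse(resolved, toupper(codons), "unresolved"),
             amino_acid = ifelse(resolved, aa, "unassigned"),
             specificity_group = group, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Split lineage-level T-box regulogs by amino acid specificity
#'
#' Each T-box regulog (one per lineage) is replaced by one regulog per
#' specificity group present in that lineage. Member operons follow the
#' specificity of their nearest site's call; operons whose sites are all
#' unresolved go to an `"unassigned"` bucket that is excluded from regulog
#' counts (a warning is raised when a whole lineage regulog dissolves into
#' it). Sites are conserved: specificity regulogs plus the unassigned bucket
#' account for every original T-box site.
#'
#' @param regulogs regulog table from [assemble_regulogs()].
#' @param regulated regulated-operon table.
#' @param calls specificity calls from [call_specificity()].
#' @param tbox_motif motif id of the T-box family. Default `"RF00230"`.
#' @return list with `regulogs` (table where T-box rows carry a
#'   `specificity_group` column value; other rows have `""`) and `unassigned`
#'   (data.frame of unresolved operons: taxgroup_id, operon_id, n_sites).
#' @export
split_tbox_regulogs <- function(regulogs, regulated, calls,
                                tbox_motif = "RF00230") {
  regulogs$specificity_group <- rep("", nrow(regulogs))
  tb <- which(regulogs$motif_id == tbox_motif)
  if (length(tb) == 0)
    return(list(regulogs = regulogs,
                unassigned = data.frame(taxgroup_id = character(),
                                        operon_id = character(),
                                        n_sites = integer(),
                                        stringsAsFactors = FALSE)))
  call_of <- stats::setNames(calls$specificity_group, calls$site_id)
  keep <- regulogs[-tb, , drop = FALSE]
  extra <- list()
  unassigned <- data.frame(taxgroup_id = character(), operon_id = character(),
                           n_sites = integer(), stringsAsFactors = FALSE)
  for (i in tb) {
    ops <- regulogs$operon_ids[[i]]
    sub <- regulated[regulated$operon_id %in% ops &
                       regulated$motif_id == tbox_motif, , drop = FALSE]
    grp <- vapply(seq_len(nrow(sub)), function(j) {
      g <- unique(stats::na.omit(call_of[sub$site_ids[[j]]]))
      g <- setdiff(g, "unassigned")
      if (length(g) == 0) "unassigned" else g[1]
    }, "")
    for (g in setdiff(unique(grp), "unassigned")) {
      ix <- which(grp == g)
      extra[[length(extra) + 1]] <- data.frame(
        motif_id = tbox_motif, taxgroup_id = regulogs$taxgroup_id[i],
        n_crons = regulogs$n_crons[i], n_operons = length(ix),
        total_sites = sum(sub$n_sites[ix]), total_genes = sum(sub$n_genes[ix]),
        genome_count = length(unique(sub$genome_id[ix])),
        cron_ids = I(list(regulogs$cron_ids[[i]])),
        operon_ids = I(list(sub$operon_id[ix])),
        specificity_group = g, stringsAsFactors = FALSE)
    }
    un <- which(grp == "unassigned")
    if (length(un))
      unassigned <- rbind(unassigned,
                          data.frame(taxgroup_id = regulogs$taxgroup_id[i],
                                     operon_id = sub$operon_id[un],
                                     n_sites = sub$n_sites[un],
                                     stringsAsFactors = FALSE))
    if (all(grp == "unassigned"))
      warning("all T-boxes unresolved in lineage ", regulogs$taxgroup_id[i],
              "; lineage regulog dropped", call. = FALSE)
  }
  out <- rbind(keep, do.call(rbind, extra))
  rownames(out) <- NULL
  list(regulogs = out, unassigned = unassigned)
}

#' Regulog accounting after the T-box specificity split
#'
#' Lineage-level T-box regulogs are removed from the total and replaced by
#' the amino-acid-specific regulogs inferred from them.
#'
#' @param n_regulogs number of lineage-level regulogs before the split.
#' @param n_tbox_lineage number of lineage-level T-box regulogs among them.
#' @param n_specificity number of amino-acid-specific T-box regulogs.
#' @return total number of regulogs after the split.
#' @export
regulog_accounting <- function(n_regulogs, n_tbox_lineage, n_specificity) {
  stopifnot(n_tbox_lineage <= n_regulogs)
  n_regulogs - n_tbox_lineage + n_specificity
}
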