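# CRON construction: clustering regulated operons across the genomes of one
# taxonomic group by the ortholog group of their leader genes, merging
# clusters with similar operon content, scoring regulatory conservation,
# acceptance, ortholog-supported operon extension, and regulog assembly.

operon_og_set <- function(operon_row, operons, orthology) {
  genes <- operons$gene_ids[[which(operons$operon_id == operon_row)]]
  gid <- operons$genome_id[operons$operon_id == operon_row]
  og <- ortholog_group(orthology, rep(gid, length(genes)), genes)
  unique(og[!is.na(og)])
}

#' Cluster regulated operons into CRONs
#'
#' Regulated operons of one motif family within one taxonomic group are first
#' grouped by the ortholog group of their leader gene (operons whose leader is
#' not in the orthology map form singleton clusters anchored at
#' `"unassigned:<gene_id>"`). Cluster pairs whose member operons'
#' ortholog-group sets (union over members) have Jaccard index >= `min_jaccard`
#' are then merged as connected components (single linkage over the initial
#' anchor clusters, computed with `igraph`). One genome may contribute several
#' operons to a CRON (paralogous operons). The anchor group of a merged CRON
#' is the most frequent leader ortholog group among its members (ties broken
#' lexicographically).
#'
#' @param regulated regulated-operon table from [assign_sites()] (all motifs /
#'   genomes; grouping by motif and taxgroup is internal).
#' @param operons operon table covering all genomes involved.
#' @param orthology an `OrthologyMap`.
#' @param taxgroups named character vector mapping genome_id to taxgroup_id.
#' @param min_jaccard merge bound on the Jaccard index of cluster
#'   ortholog-group sets. Default 0.5.
#' @return data.frame with one row per CRON: cron_id, motif_id, taxgroup_id,
#'   anchor_group, n_members, member_operon_ids (list), member_genomes (list),
#'   n_regulated_genomes, n_sites, n_genes.
#' @export
build_crons <- function(regulated, operons, orthology, taxgroups,
                        min_jaccard = 0.5) {
  if (nrow(regulated) == 0) return(empty_crons())
  regulated$taxgroup_id <- unname(taxgroups[regulated$genome_id])
  if (any(is.na(regulated$taxgroup_id)))
    stop("genome without taxgroup: ",
         regulated$genome_id[is.na(regulated$taxgroup_id)][1], call. = FALSE)
  out <- list()
  for (key in unique(paste(regulated$motif_id, regulated$taxgroup_id, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    sub <- regulated[regulated$motif_id == parts[1] &
                       regulated$taxgroup_id == parts[2], , drop = FALSE]
    anchors <- ortholog_group(orthology, sub$genome_id, sub$leader_gene)
    anchors[is.na(anchors)] <- paste0("unassigned:", sub$leader_gene[is.na(anchors)])
    clusters <- split(seq_len(nrow(sub)), anchors)
    og_sets <- lapply(clusters, function(ix)
      unique(unlist(lapply(sub$operon_id[ix], operon_og_set, operons, orthology))))
    comp <- merge_components(og_sets, min_jaccard)
    for (members in split(seq_along(clusters), comp)) {
      ix <- unlist(clusters[members], use.names = FALSE)
      leaders <- anchors[ix]
      tb <- sort(table(leaders), decreasing = TRUE)
      anchor <- sort(names(tb)[tb == max(tb)])[1]
      out[[length(out) + 1]] <- data.frame(
        motif_id = parts[1], taxgroup_id = parts[2], anchor_group = anchor,
        n_members = length(ix),
        member_operon_ids = I(list(sub$operon_id[ix])),
        member_genomes = I(list(sub$genome_id[ix])),
        n_regulated_genomes = length(unique(sub$genome_id[ix])),
        n_sites = sum(sub$n_sites[ix]), n_genes = sum(sub$n_genes[ix]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$motif_id, out$taxgroup_id, out$anchor_group), , drop = FALSE]
  out <- cbind(cron_id = sprintf("cron%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# connected components over initial clusters under the Jaccard merge predicate
merge_components <- function(og_sets, min_jaccard) {
  n <- length(og_sets)
  if (n == 1) return(1L)
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    u <- length(union(og_sets[[i]], og_sets[[j]]))
    jac <- if (u == 0) 0 else length(intersect(og_sets[[i]], og_sets[[j]])) / u
    if (jac >= min_jaccard) edges <- rbind(edges, c(i, j))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

empty_crons <- function() {
  data.frame(cron_id = character(), motif_id = character(),
             taxgroup_id = character(), anchor_group = character(),
             n_members = integer(), member_operon_ids = I(list()),
             member_genomes = I(list()), n_regulated_genomes = integer(),
             n_sites = integer(), n_genes = integer(), stringsAsFactors = FALSE)
}

#' Regulatory conservation of a CRON
#'
#' The fraction of the taxonomic group's anchor-bearing genomes (genomes with
#' at least one gene in the CRON's anchor ortholog group) that contribute a
#' regulated operon to the CRON. Gene absence therefore does not penalize
#' conservation. A zero denominator (anchor group absent from the orthology
#' map, e.g. an `unassigned:` anchor) yields conservation 0 with a warning.
#'
#' @param member_genomes genomes contributing regulated operons.
#' @param anchor_group the CRON's anchor ortholog group id.
#' @param taxgroup_genomes all genome ids of the taxonomic group.
#' @param orthology an `OrthologyMap`.
#' @return conservation in \[0, 1\].
#' @export
score_conservation <- function(member_genomes, anchor_group, taxgroup_genomes,
                               orthology) {
  bearing <- genomes_with_group(orthology, anchor_group, taxgroup_genomes)
  if (length(bearing) == 0) {
    warning("anchor group ", anchor_group,
            " absent from orthology; conservation set to 0", call. = FALSE)
    return(0)
  }
  length(intersect(unique(member_genomes), bearing)) / length(bearing)
}

#' Score conservation for every CRON in a table
#'
#' @param crons CRON table from [build_crons()].
#' @param orthology an `OrthologyMap`.
#' @param taxgroups named character vector mapping genome_id to taxgroup_id.
#' @return the CRON table with a `conservation` column.
#' @export
score_crons <- function(crons, orthology, taxgroups) {
  crons$conservation <- vapply(seq_len(nrow(crons)), function(i) {
    tg <- names(taxgroups)[taxgroups == crons$taxgroup_id[i]]
    score_conservation(crons$member_genomes[[i]], crons$anchor_group[i], tg,
                       orthology)
  }, numeric(1))
  crons
}

#' Accept or reject CRONs
#'
#' A CRON is accepted when its conservation is at least `min_conservation` and
#' it is regulated in at least `min_genomes` genomes, or through the singleton
#' rescue: a CRON regulated in a single genome whose best site score reaches
#' the family's high-confidence threshold (registry column
#' `high_conf_threshold`). Rejected CRONs carry a reason.
#'
#' @param crons scored CRON table (from [score_crons()]).
#' @param regulated regulated-operon table (for site lookup).
#' @param sites site table (for scores).
#' @param registry a `MotifRegistry`.
#' @param min_conservation acceptance bound on conservation. Default 0.5.
#' @param min_genomes minimum number of regulated genomes. Default 2.
#' @return the CRON table with `accepted` and `reject_reason` columns.
#' @export
accept_crons <- function(crons, regulated, sites, registry,
                         min_conservation = 0.5, min_genomes = 2) {
  if (nrow(crons) == 0) {
    crons$accepted <- logical(0); crons$reject_reason <- character(0)
    return(crons)
  }
  hc <- stats::setNames(registry$high_conf_threshold, registry$motif_id)
  score_of <- stats::setNames(sites$score, sites$site_id)
  crons$accepted <- FALSE
  crons$reject_reason <- ""
  for (i in seq_len(nrow(crons))) {
    main <- crons$conservation[i] >= min_conservation &&
      crons$n_regulated_genomes[i] >= min_genomes
    rescue <- FALSE
    if (!main && crons$n_regulated_genomes[i] == 1) {
      sids <- unlist(regulated$site_ids[regulated$operon_id %in%
                                          crons$member_operon_ids[[i]]])
      best <- suppressWarnings(max(score_of[sids], na.rm = TRUE))
      thr <- hc[crons$motif_id[i]]
      rescue <- is.finite(best) && !is.na(thr) && best >= thr
    }
    crons$accepted[i] <- main || rescue
    if (!crons$accepted[i])
      crons$reject_reason[i] <- if (crons$conservation[i] < min_conservation)
        sprintf("conservation %.2f < %.2f", crons$conservation[i], min_conservation)
      else sprintf("regulated in %d genome(s) < %d", crons$n_regulated_genomes[i],
                   min_genomes)
  }
  crons
}

#' Extend member operons of accepted CRONs with ortholog support
#'
#' For each member operon of an accepted CRON, the next same-strand downstream
#' gene is appended when its intergenic gap is at most `extension_cap` and its
#' ortholog group already occurs in at least half of the CRON's other member
#' operons. Applied iteratively until no gene qualifies. Operon boundaries are
#' expanded in place; the initial inference partition is thereby deliberately
#' overridden for accepted CRONs only.
#'
#' @param crons CRON table with `accepted` flags.
#' @param operons operon table (will be updated).
#' @param genomes named list of [Genome] objects.
#' @param orthology an `OrthologyMap`.
#' @param extension_cap maximum gap (nt) for an appended gene. Default 300.
#' @return list with `operons` (updated table) and `log` (data.frame of
#'   extension events: cron_id, operon_id, gene_id, gap, support).
#' @export
extend_operons <- function(crons, operons, genomes, orthology,
                           extension_cap = 300) {
  log <- data.frame(cron_id = character(), operon_id = character(),
                    gene_id = character(), gap = integer(), support = numeric(),
                    stringsAsFactors = FALSE)
  acc <- which(crons$accepted)
  for (ci in acc) {
    members <- crons$member_operon_ids[[ci]]
    if (length(members) < 2) next  # support over "other members" needs >= 2
    repeat {
      changed <- FALSE
      og_sets <- lapply(members, operon_og_set, operons, orthology)
      names(og_sets) <- members
      for (m in members) {
        oi <- which(operons$operon_id == m)
        op <- operons[oi, ]
        g <- genomes[[op$genome_id]]$genes
        g <- g[g$contig_id == op$contig_id & g$strand == op$strand &
                 !g$gene_id %in% op$gene_ids[[1]], , drop = FALSE]
        if (op$strand == "+") {
          g <- g[g$start > op$span_end, , drop = FALSE]
          if (nrow(g) == 0) next
          nxt <- g[which.min(g$start), ]
          gap <- nxt$start - op$span_end - 1L
        } else {
          g <- g[g$end < op$span_start, , drop = FALSE]
          if (nrow(g) == 0) next
          nxt <- g[which.max(g$end), ]
          gap <- op$span_start - nxt$end - 1L
        }
        if (gap > extension_cap) next
        og <- ortholog_group(orthology, op$genome_id, nxt$gene_id)
        if (is.na(og)) next
        others <- og_sets[setdiff(members, m)]
        support <- mean(vapply(others, function(s) og %in% s, logical(1)))
        if (support < 0.5) next
        operons$gene_ids[[oi]] <- c(op$gene_ids[[1]], nxt$gene_id)
        operons$n_genes[oi] <- op$n_genes + 1L
        operons$span_start[oi] <- min(op$span_start, nxt$start)
        operons$span_end[oi] <- max(op$span_end, nxt$end)
        og_sets[[m]] <- unique(c(og_sets[[m]], og))
        log <- rbind(log, data.frame(cron_id = crons$cron_id[ci], operon_id = m,
                                     gene_id = nxt$gene_id, gap = gap,
                                     support = support, stringsAsFactors = FALSE))
        changed <- TRUE
      }
      if (!changed) break
    }
  }
  list(operons = operons, log = log)
}

#' Refresh regulated-operon gene counts after operon extension
#'
#' @param regulated regulated-operon table.
#' @param operons (possibly extended) operon table.
#' @return regulated table with n_genes synchronized.
#' @export
refresh_regulated <- function(regulated, operons) {
  idx <- match(regulated$operon_id, operons$operon_id)
  regulated$n_genes <- operons$n_genes[idx]
  regulated
}

#' Assemble regulogs from accepted CRONs
#'
#' One regulog per (motif family, taxonomic group) with at least one accepted
#' CRON. Tandem sites are counted individually in `total_sites` while their
#' operon counts once; a motif/lineage combination with only rejected CRONs
#' yields no regulog.
#'
#' @param crons CRON table with `accepted` flags.
#' @param regulated regulated-operon table (post [refresh_regulated()]).
#' @return data.frame motif_id, taxgroup_id, n_crons, n_operons, total_sites,
#'   total_genes, genome_count, cron_ids (list), operon_ids (list).
#' @export
assemble_regulogs <- function(crons, regulated) {
  acc <- crons[crons$accepted, , drop = FALSE]
  if (nrow(acc) == 0)
    return(data.frame(motif_id = character(), taxgroup_id = character(),
                      n_crons = integer(), n_operons = integer(),
                      total_sites = integer(), total_genes = integer(),
                      genome_count = integer(), cron_ids = I(list()),
                      operon_ids = I(list()), stringsAsFactors = FALSE))
  key <- paste(acc$motif_id, acc$taxgroup_id, sep = "\r")
  ng <- stats::setNames(regulated$n_genes, regulated$operon_id)
  out <- do.call(rbind, lapply(split(seq_len(nrow(acc)), key), function(ix) {
    ops <- unlist(acc$member_operon_ids[ix])
    data.frame(motif_id = acc$motif_id[ix[1]], taxgroup_id = acc$taxgroup_id[ix[1]],
               n_crons = length(ix), n_operons = length(ops),
               total_sites = sum(acc$n_sites[ix]),
               total_genes = sum(ng[ops]),
               genome_count = length(unique(unlist(acc$member_genomes[ix]))),
               cron_ids = I(list(acc$cron_id[ix])), operon_ids = I(list(ops)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
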