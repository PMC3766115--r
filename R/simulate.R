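# Synthetic community generator: multi-genome taxonomic groups with shared
# ortholog groups laid out in operon blocks, planted regulatory sites in
# upstream windows at a controlled conservation level, spurious intergenic
# sites strictly outside all assignment windows, template-generated T-box
# alignments with known specifier codons, and a ground-truth manifest.

#' Describe a regulon to plant in a simulated community
#'
#' @param motif_id Rfam-style family id (must exist in the simulated
#'   registry).
#' @param taxgroup_id taxonomic group to plant into.
#' @param conservation probability that each anchor-bearing genome carries a
#'   regulated operon (sampled independently per genome, so the empirical
#'   conservation is Binomial around this value).
#' @param tandem_prob probability that a regulated operon receives two
#'   riboswitch copies instead of one.
#' @param roles functional roles of the operon's genes in transcription
#'   order; recycled to `operon_size` when that is given.
#' @param operon_size optional operon length; `NA` draws from the config's
#'   operon-size distribution.
#' @param specificity amino acid specificity (three-letter code) for T-box
#'   regulons; `NA` otherwise.
#' @return a `planted_regulon` list.
#' @export
planted_regulon <- function(motif_id, taxgroup_id, conservation = 0.8,
                            tandem_prob = 0, roles = "", operon_size = NA,
                            specificity = NA_character_) {
  stopifnot(conservation >= 0, conservation <= 1,
            tandem_prob >= 0, tandem_prob <= 1)
  structure(list(motif_id = motif_id, taxgroup_id = taxgroup_id,
                 conservation = conservation, tandem_prob = tandem_prob,
                 roles = roles, operon_size = operon_size,
                 specificity = specificity), class = "planted_regulon")
}

#' Simulation configuration
#'
#' Defaults describe a small but realistic study community: two taxonomic
#' groups of four genomes, 60 genes per genome arranged in operon blocks
#' conserved within each group, a widely conserved TPP-like regulon, a
#' glycine-like regulon with conservation 0.8 and tandem probability 0.82
#' (the tandem-fraction and operon-size profile characteristic of glycine
#' riboswitches), an Ile-specific T-box, and one spurious site per genome.
#' Intra-operon gaps (20-150 nt) sit inside the 200 nt merge bound and
#' inter-operon gaps (300-900 nt) outside it, so the planted operon structure
#' is exactly recoverable. The glycine operon-size distribution over 1-4
#' genes has mean 2.3.
#'
#' @param seed RNG seed recorded in the manifest.
#' @param n_taxgroups,genomes_per_group community shape.
#' @param genes_per_genome ortholog slots per genome.
#' @param gene_len,intra_gap,inter_gap uniform bounds (nt).
#' @param operon_lambda filler operon size is 1 + Poisson(operon_lambda).
#' @param og_presence presence probability of filler ortholog groups per
#'   genome (planted operon groups are always present, so ground truth stays
#'   unambiguous).
#' @param planted list of [planted_regulon()] descriptions; `NULL` gives the
#'   default community above.
#' @param spurious_per_genome spurious sites planted per genome.
#' @param true_score,spurious_score Normal (mean, sd) of bit scores.
#' @param site_len uniform bounds of site length (nt).
#' @param operon_size_dist probabilities over operon sizes 1..k for planted
#'   regulons with `operon_size = NA`.
#' @param score_threshold,high_conf_threshold registry thresholds applied to
#'   every simulated family.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(seed = 1L, n_taxgroups = 2, genomes_per_group = 4,
                       genes_per_genome = 60, gene_len = c(300, 1500),
                       intra_gap = c(20, 150), inter_gap = c(300, 900),
                       operon_lambda = 1.2, og_presence = 0.9,
                       planted = NULL, spurious_per_genome = 1,
                       true_score = c(65, 8), spurious_score = c(45, 6),
                       site_len = c(80, 110),
                       operon_size_dist = c(0.25, 0.35, 0.25, 0.15),
                       score_threshold = 30, high_conf_threshold = 70) {
  if (is.null(planted)) {
    planted <- list(
      planted_regulon("RF00059", "tg1", conservation = 1.0,
                      roles = c("Thiamin biosynthesis",
                                "Thiamin & precursor transporters")),
      planted_regulon("RF00504", "tg1", conservation = 0.8,
                      tandem_prob = 0.82, roles = "Glycine metabolism",
                      operon_size = NA),
      planted_regulon("RF00504", "tg2", conservation = 0.8,
                      tandem_prob = 0.82, roles = "Glycine metabolism",
                      operon_size = NA),
      planted_regulon("RF00230", "tg1", conservation = 1.0,
                      roles = "Amino acyl-tRNA synthetases",
                      specificity = "Ile"))
  }
  planted <- planted[vapply(planted, function(p)
    p$taxgroup_id %in% paste0("tg", seq_len(n_taxgroups)), logical(1))]
  cfg <- list(seed = as.integer(seed), n_taxgroups = n_taxgroups,
              genomes_per_group = genomes_per_group,
              genes_per_genome = genes_per_genome, gene_len = gene_len,
              intra_gap = intra_gap, inter_gap = inter_gap,
              operon_lambda = operon_lambda, og_presence = og_presence,
              planted = planted, spurious_per_genome = spurious_per_genome,
              true_score = true_score, spurious_score = spurious_score,
              site_len = site_len, operon_size_dist = operon_size_dist,
              score_threshold = score_threshold,
              high_conf_threshold = high_conf_threshold)
  stopifnot(og_presence >= 0, og_presence <= 1, all(operon_size_dist >= 0))
  class(cfg) <- "SimConfig"
  cfg
}

# registry covering the families the simulator can emit
sim_registry <- function(cfg) {
  fam <- data.frame(
    motif_id = c("RF00059", "RF00174", "RF00504", "RF00050", "RF00162",
                 "RF00230", "RF00557", "RF00514", "RF00515"),
    name = c("TPP", "Cobalamin", "Glycine", "FMN", "SAM",
             "T-box", "L10 leader", "His leader", "PyrR"),
    motif_class = c("riboswitch", "riboswitch", "riboswitch", "riboswitch",
                    "riboswitch", "tbox", "ribosomal_leader", "aa_leader",
                    "pyrR"),
    effector = c("thiamin pyrophosphate", "adenosylcobalamin", "glycine",
                 "flavin mononucleotide", "S-adenosylmethionine", "-", "-",
                 "-", "-"),
    stringsAsFactors = FALSE)
  fam$score_threshold <- cfg$score_threshold
  fam$high_conf_threshold <- cfg$high_conf_threshold
  class(fam) <- c("MotifRegistry", "data.frame")
  fam
}

runif_int <- function(n, bounds) {
  as.integer(floor(stats::runif(n, bounds[1], bounds[2] + 1)))
}

#' Generate a synthetic community
#'
#' Lays out the genomes of every taxonomic group gene by gene: a group-level
#' block (operon) structure over ortholog groups is drawn once per group,
#' planted regulons occupy dedicated blocks whose leader ortholog group is
#' the regulon anchor, and each genome instantiates the blocks with drawn
#' gene lengths and gaps (filler groups present with the configured
#' probability). Deterministic for a fixed config (including seed).
#'
#' @param config a [sim_config()].
#' @return list with `genomes` (named list of [Genome]), `orthology`,
#'   `registry`, `functional_map`, `blocks` (internal layout, used by
#'   [plant_regulons()]) and `truth` (skeleton manifest).
#' @export
generate_community <- function(config) {
  set.seed(config$seed)
  registry <- sim_registry(config)
  fmap <- read_functional_map(system.file("extdata",
                                          "functional_categories.tsv",
                                          package = "rnaregulon"))
  genomes <- list()
  orows <- list()
  blocks_all <- list()
  anchor_of <- list()
  for (t in seq_len(config$n_taxgroups)) {
    tg <- paste0("tg", t)
    planted_here <- Filter(function(p) p$taxgroup_id == tg, config$planted)
    # group-level block structure over ortholog groups
    blocks <- list()
    for (k in seq_along(planted_here)) {
      p <- planted_here[[k]]
      size <- if (is.na(p$operon_size))
        sample(seq_along(config$operon_size_dist), 1,
               prob = config$operon_size_dist) else p$operon_size
      roles <- rep_len(p$roles, size)
      blocks[[length(blocks) + 1]] <- list(planted = k, roles = roles)
    }
    used <- sum(vapply(blocks, function(b) length(b$roles), 1L))
    while (used < config$genes_per_genome) {
      size <- min(1L + stats::rpois(1, config$operon_lambda),
                  config$genes_per_genome - used)
      blocks[[length(blocks) + 1]] <- list(planted = NA, roles = rep("", size))
      used <- used + size
    }
    # shuffle block order, draw strands, assign ortholog-group ids
    blocks <- blocks[sample(seq_along(blocks))]
    og_i <- 0L
    for (b in seq_along(blocks)) {
      n <- length(blocks[[b]]$roles)
      blocks[[b]]$strand <- sample(c("+", "-"), 1)
      blocks[[b]]$ogs <- sprintf("%s_og%03d", tg, og_i + seq_len(n))
      og_i <- og_i + n
      if (!is.na(blocks[[b]]$planted))
        anchor_of[[paste(tg, blocks[[b]]$planted)]] <- blocks[[b]]$ogs[1]
    }
    blocks_all[[tg]] <- blocks
    # per-genome instantiation
    for (g in seq_len(config$genomes_per_group)) {
      gid <- sprintf("%s_gen%02d", tg, g)
      rows <- list()
      pos <- 1000L
      gene_i <- 0L
      for (b in blocks) {
        present <- if (is.na(b$planted)) stats::runif(length(b$ogs)) <= config$og_presence
                   else rep(TRUE, length(b$ogs))
        ogs <- b$ogs[present]
        roles <- b$roles[present]
        if (length(ogs) == 0) next
        # ogs are in transcription order; place genomically (reversed on -)
        ord <- if (b$strand == "+") seq_along(ogs) else rev(seq_along(ogs))
        lens <- runif_int(length(ogs), config$gene_len)
        starts <- integer(length(ogs))
        ends <- integer(length(ogs))
        for (j in seq_along(ogs)) {
          gap <- if (j == 1) runif_int(1, config$inter_gap)
                 else runif_int(1, config$intra_gap)
          starts[j] <- pos + gap
          ends[j] <- starts[j] + lens[j] - 1L
          pos <- ends[j]
        }
        for (j in seq_along(ogs)) {
          gene_i <- gene_i + 1L
          k <- ord[j]  # which transcription-order og sits at genomic slot j
          rows[[length(rows) + 1]] <- data.frame(
            gene_id = sprintf("%s_g%04d", gid, gene_i),
            contig_id = "chr", start = starts[j], end = ends[j],
            strand = b$strand, locus_tag = sprintf("%s_g%04d", gid, gene_i),
            functional_role = roles[k], og = ogs[k], stringsAsFactors = FALSE)
        }
      }
      gt <- do.call(rbind, rows)
      contigs <- c(chr = max(gt$end) + 1500L)
      genomes[[gid]] <- Genome(gid, tg, gt[, names(gt) != "og"],
                               contigs = contigs)
      orows[[length(orows) + 1]] <- data.frame(
        genome_id = gid, gene_id = gt$gene_id, ortholog_group_id = gt$og,
        stringsAsFactors = FALSE)
    }
  }
  orthology <- do.call(rbind, orows)
  rownames(orthology) <- NULL
  class(orthology) <- c("OrthologyMap", "data.frame")
  truth <- list(seed = config$seed, planted = list(), spurious_site_ids = character(),
                anchors = anchor_of)
  list(genomes = genomes, orthology = orthology, registry = registry,
       functional_map = fmap, blocks = blocks_all, truth = truth,
       config = config)
}

# genomic interval of the assignment window around a leader start codon,
# padded so spurious sites rejected against it can never graze a true site
window_interval <- function(sc, strand, upstream = 500, downstream = 100,
                            pad = 150) {
  if (strand == "+") c(lo = sc - upstream - pad, hi = sc + downstream + pad)
  else c(lo = sc - downstream - pad, hi = sc + upstream + pad)
}

#' Plant regulatory sites into a generated community
#'
#' For each planted regulon, every anchor-bearing genome of its taxonomic
#' group is regulated independently with probability `conservation`; a
#' regulated genome receives a site (or, with `tandem_prob`, a tandem pair)
#' whose gene-proximal end falls strictly inside the assignment window
#' upstream of the operon leader's start codon, strand-matched, with a bit
#' score from the true-score distribution. Spurious sites are placed in
#' random intergenic positions strictly outside every (padded) assignment
#' window with scores from the spurious distribution, so ground truth is
#' unambiguous by construction.
#'
#' @param community output of [generate_community()].
#' @return the community with `sites` (data.frame) added and `truth` filled
#'   in (`planted`: one record per regulated genome with leader gene, site
#'   ids, tandem flag and specificity; `spurious_site_ids`).
#' @export
plant_regulons <- function(community) {
  cfg <- community$config
  sites <- list()
  site_i <- 0L
  new_site <- function(motif, gid, start, end, strand, score) {
    site_i <<- site_i + 1L
    data.frame(site_id = sprintf("site%05d", site_i), motif_id = motif,
               genome_id = gid, contig_id = "chr", start = as.integer(start),
               end = as.integer(end), strand = strand, score = score,
               stringsAsFactors = FALSE)
  }
  planted_records <- list()
  gene_og <- community$orthology
  for (t in seq_len(cfg$n_taxgroups)) {
    tg <- paste0("tg", t)
    planted_here <- which(vapply(cfg$planted, function(p)
      p$taxgroup_id == tg, logical(1)))
    for (k in seq_along(planted_here)) {
      p <- cfg$planted[[planted_here[k]]]
      anchor <- community$truth$anchors[[paste(tg, k)]]
      gens <- names(community$genomes)[vapply(community$genomes, function(g)
        g$taxgroup_id == tg, logical(1))]
      bearing <- gens[vapply(gens, function(g)
        any(gene_og$genome_id == g & gene_og$ortholog_group_id == anchor),
        logical(1))]
      regulated <- bearing[stats::runif(length(bearing)) <= p$conservation]
      for (g in regulated) {
        leader <- gene_og$gene_id[gene_og$genome_id == g &
                                    gene_og$ortholog_group_id == anchor][1]
        gt <- community$genomes[[g]]$genes
        gi <- match(leader, gt$gene_id)
        sc <- if (gt$strand[gi] == "+") gt$start[gi] else gt$end[gi]
        strand <- gt$strand[gi]
        tandem <- stats::runif(1) <= p$tandem_prob
        d1 <- if (tandem) -runif_int(1, c(20, 150)) else -runif_int(1, c(20, 400))
        lens <- runif_int(2, cfg$site_len)
        ids <- character(0)
        place <- function(d, len) {
          if (strand == "+") c(sc + d - len + 1L, sc + d)
          else c(sc - d, sc - d + len - 1L)
        }
        iv <- place(d1, lens[1])
        s <- new_site(p$motif_id, g, iv[1], iv[2], strand,
                      stats::rnorm(1, cfg$true_score[1], cfg$true_score[2]))
        sites[[length(sites) + 1]] <- s
        ids <- s$site_id
        if (tandem) {
          d2 <- d1 - lens[1] - runif_int(1, c(10, 30))
          iv2 <- place(d2, lens[2])
          s2 <- new_site(p$motif_id, g, iv2[1], iv2[2], strand,
                         stats::rnorm(1, cfg$true_score[1], cfg$true_score[2]))
          sites[[length(sites) + 1]] <- s2
          ids <- c(ids, s2$site_id)
        }
        planted_records[[length(planted_records) + 1]] <- list(
          motif_id = p$motif_id, taxgroup_id = tg, anchor_group = anchor,
          genome_id = g, leader_gene = leader, site_ids = ids,
          tandem = tandem, specificity = p$specificity)
      }
    }
  }
  # spurious sites: intergenic, strictly outside every padded window
  motifs_used <- unique(vapply(cfg$planted, function(p) p$motif_id, ""))
  spurious_ids <- character(0)
  for (g in names(community$genomes)) {
    gen <- community$genomes[[g]]
    gt <- gen$genes
    L <- gen$contigs[["chr"]]
    ops <- infer_operons(gen)
    wins <- do.call(rbind, lapply(seq_len(nrow(ops)), function(i) {
      w <- window_interval(ops$leader_start_codon[i], ops$strand[i])
      data.frame(lo = w[["lo"]], hi = w[["hi"]], strand = ops$strand[i],
                 stringsAsFactors = FALSE)
    }))
    for (s in seq_len(cfg$spurious_per_genome)) {
      len <- runif_int(1, cfg$site_len)
      strand <- sample(c("+", "-"), 1)
      motif <- sample(motifs_used, 1)
      placed <- FALSE
      for (try in 1:200) {
        x <- runif_int(1, c(1, L - len))
        iv <- c(x, x + len - 1L)
        if (any(iv[1] <= gt$end & iv[2] >= gt$start)) next
        same <- wins[wins$strand == strand, , drop = FALSE]
        if (any(iv[1] <= same$hi & iv[2] >= same$lo)) next
        sp <- new_site(motif, g, iv[1], iv[2], strand,
                       stats::rnorm(1, cfg$spurious_score[1],
                                    cfg$spurious_score[2]))
        sites[[length(sites) + 1]] <- sp
        spurious_ids <- c(spurious_ids, sp$site_id)
        placed <- TRUE
        break
      }
      if (!placed) message("could not place a spurious site in ", g)
    }
  }
  community$sites <- if (length(sites)) do.call(rbind, sites) else empty_sites()
  community$truth$planted <- planted_records
  community$truth$spurious_site_ids <- spurious_ids
  community
}

canonical_codon <- function(aa3) {
  code <- Biostrings::GENETIC_CODE
  aa1 <- names(Biostrings::AMINO_ACID_CODE)[match(aa3, Biostrings::AMINO_ACID_CODE)]
  dna <- names(code)[code == aa1][1]
  chartr("T", "U", dna)
}

#' Generate T-box alignments for planted T-box sites
#'
#' Builds an alignment from a fixed random template whose specifier codon
#' (ungapped reference positions 61-63) is substituted per planted
#' specificity; rows acquire random substitutions away from the anchor, and
#' all-gap columns are inserted away from the anchor region. The reference
#' row and codon span are recorded in the returned object and the manifest.
#'
#' @param community output of [plant_regulons()].
#' @param mutation_rate per-position substitution probability outside the
#'   anchor. Default 0.03.
#' @param n_gap_columns all-gap columns inserted. Default 4.
#' @return the community with `tbox_alignment` (a [TBoxAlignment]) added, or
#'   unchanged when no T-box sites were planted.
#' @export
generate_tbox_alignments <- function(community, mutation_rate = 0.03,
                                     n_gap_columns = 4) {
  tb <- Filter(function(r) !is.na(r$specificity), community$truth$planted)
  if (length(tb) == 0) return(community)
  nt <- c("A", "C", "G", "U")
  template <- sample(nt, 120, replace = TRUE)
  span <- c(61L, 62L, 63L)
  rows <- list(tbox_ref = paste(replace(template, span,
                                        strsplit("UAC", "")[[1]]), collapse = ""))
  truth_spec <- character(0)
  for (r in tb) {
    for (sid in r$site_ids) {
      row <- template
      mut <- which(stats::runif(120) < mutation_rate)
      mut <- setdiff(mut, span)
      row[mut] <- sample(nt, length(mut), replace = TRUE)
      row[span] <- strsplit(canonical_codon(r$specificity), "")[[1]]
      rows[[sid]] <- paste(row, collapse = "")
      truth_spec[sid] <- r$specificity
    }
  }
  seqs <- unlist(rows)
  # all-gap columns away from the anchor region
  if (n_gap_columns > 0) {
    w <- nchar(seqs[[1]])
    candidates <- setdiff(seq_len(w), (span[1] - 5):(span[3] + 5))
    at <- sort(sample(candidates, n_gap_columns), decreasing = TRUE)
    nm <- names(seqs)
    for (pos in at)
      seqs <- paste0(substr(seqs, 1, pos - 1), "-",
                     substr(seqs, pos, nchar(seqs)))
    names(seqs) <- nm
  }
  community$tbox_alignment <- TBoxAlignment(seqs, "tbox_ref", span)
  community$truth$tbox_specificities <- truth_spec
  community
}

#' Simulate a full community in one call
#'
#' [generate_community()], [plant_regulons()] and
#' [generate_tbox_alignments()] chained; deterministic for a fixed config.
#'
#' @param config a [sim_config()].
#' @return community list with genomes, orthology, registry, functional_map,
#'   sites, truth and (if T-boxes were planted) tbox_alignment.
#' @export
simulate_community <- function(config = sim_config()) {
  generate_tbox_alignments(plant_regulons(generate_community(config)))
}

#' Write a simulated community to disk in the pipeline's input formats
#'
#' Emits per-genome annotation TSVs, an annotation manifest, a site TSV, the
#' orthology/registry/functional-map TSVs, the T-box alignment as aligned
#' FASTA and `ground_truth.json`.
#'
#' @param community output of [simulate_community()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "genomes"), showWarnings = FALSE)
  manifest <- data.frame(genome_id = character(), taxgroup_id = character(),
                         path = character(), format = character(),
                         stringsAsFactors = FALSE)
  for (gid in names(community$genomes)) {
    p <- file.path("genomes", paste0(gid, ".tsv"))
    write_annotations(community$genomes[[gid]], file.path(dir, p))
    manifest <- rbind(manifest, data.frame(
      genome_id = gid, taxgroup_id = community$genomes[[gid]]$taxgroup_id,
      path = p, format = "tsv", stringsAsFactors = FALSE))
  }
  utils::write.table(manifest, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  s <- community$sites
  utils::write.table(
    data.frame(motif_id = s$motif_id, contig = s$contig_id, start = s$start,
               end = s$end, strand = s$strand, score = round(s$score, 2),
               genome_id = s$genome_id, site_id = s$site_id,
               stringsAsFactors = FALSE),
    file.path(dir, "sites.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(community$orthology, file.path(dir, "orthology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(community$registry),
                     file.path(dir, "registry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fm <- as.data.frame(community$functional_map)
  utils::write.table(fm[, c("functional_role", "sfc", "ofc")],
                     file.path(dir, "functional_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(community$tbox_alignment)) {
    al <- community$tbox_alignment
    writeLines(paste0(">", names(al$seqs), "\n", unname(al$seqs)),
               file.path(dir, "tbox_alignment.fasta"))
  }
  jsonlite::write_json(community$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
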