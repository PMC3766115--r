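# End-to-end orchestration: in-memory reconstruction, the file-driven
# pipeline with manifest and summary, and recovery metrics against a
# simulated ground truth.

#' Default stage parameters
#'
#' The defaults are the reconstruction's standard operating point: 200 nt
#' maximum intergenic distance with coding-overlap merging, the 500 nt
#' upstream / 100 nt downstream assignment window, Jaccard 0.5 CRON merging,
#' acceptance at conservation 0.5 in at least two genomes, and a 300 nt
#' ortholog-supported extension cap.
#'
#' @param ... overrides of individual parameters.
#' @return named list of stage parameters.
#' @export
default_params <- function(...) {
  p <- list(max_gap = 200, merge_overlaps = TRUE, upstream = 500,
            downstream = 100, min_jaccard = 0.5, min_conservation = 0.5,
            min_genomes = 2, extension_cap = 300, extend = TRUE)
  over <- list(...)
  p[names(over)] <- over
  p
}

#' Reconstruct regulons in memory
#'
#' Runs operon inference, hit deduplication, window assignment, regulon
#' building, CRON construction/scoring/acceptance, optional ortholog
#' extension and regulog assembly on already-loaded objects. This is the
#' computational core wrapped by [run_pipeline()].
#'
#' @param genomes named list of [Genome] objects.
#' @param sites filtered site data.frame.
#' @param orthology an `OrthologyMap`.
#' @param registry a `MotifRegistry`.
#' @param params list from [default_params()].
#' @return list with operons, sites (deduplicated), assignment (list from
#'   [assign_sites()]), regulated, regulons, crons, extension_log, regulogs.
#' @export
reconstruct <- function(genomes, sites, orthology, registry,
                        params = default_params()) {
  taxgroups <- vapply(genomes, function(g) g$taxgroup_id, "")
  operons <- do.call(rbind, lapply(genomes, infer_operons,
                                   max_gap = params$max_gap,
                                   merge_overlaps = params$merge_overlaps))
  rownames(operons) <- NULL
  dedup <- deduplicate_hits(sites)
  asg <- assign_sites(dedup, operons, upstream = params$upstream,
                      downstream = params$downstream)
  regulated <- asg$regulated
  regulons <- build_regulons(regulated)
  crons <- build_crons(regulated, operons, orthology, taxgroups,
                       min_jaccard = params$min_jaccard)
  crons <- score_crons(crons, orthology, taxgroups)
  crons <- accept_crons(crons, regulated, dedup, registry,
                        min_conservation = params$min_conservation,
                        min_genomes = params$min_genomes)
  ext_log <- NULL
  if (isTRUE(params$extend)) {
    ext <- extend_operons(crons, operons, genomes, orthology,
                          extension_cap = params$extension_cap)
    operons <- ext$operons
    ext_log <- ext$log
    regulated <- refresh_regulated(regulated, operons)
  }
  regulogs <- assemble_regulogs(crons, regulated)
  list(operons = operons, sites = dedup, assignment = asg,
       regulated = regulated, regulons = regulons, crons = crons,
       extension_log = ext_log, regulogs = regulogs, taxgroups = taxgroups)
}

#' Recovery metrics against a simulated ground truth
#'
#' A predicted regulated operon is a member operon of an accepted CRON,
#' identified by (motif, genome, leader gene); the truth set is the planted
#' records. Precision and recall are computed over these identities.
#'
#' @param result output of [reconstruct()].
#' @param truth `truth` element of a simulated community (or the parsed
#'   ground_truth.json).
#' @return list precision, recall, tp, fp, fn.
#' @export
recovery_metrics <- function(result, truth) {
  truth_keys <- vapply(truth$planted, function(r)
    paste(r$motif_id, r$genome_id, r$leader_gene, sep = "\r"), "")
  acc <- result$crons[result$crons$accepted, , drop = FALSE]
  pred_keys <- character(0)
  if (nrow(acc)) {
    ops <- result$operons
    for (i in seq_len(nrow(acc))) {
      member <- acc$member_operon_ids[[i]]
      leaders <- ops$leader_gene[match(member, ops$operon_id)]
      gens <- ops$genome_id[match(member, ops$operon_id)]
      pred_keys <- c(pred_keys,
                     paste(acc$motif_id[i], gens, leaders, sep = "\r"))
    }
  }
  pred_keys <- unique(pred_keys)
  tp <- sum(pred_keys %in% truth_keys)
  list(precision = if (length(pred_keys)) tp / length(pred_keys) else NA_real_,
       recall = if (length(truth_keys)) tp / length(truth_keys) else NA_real_,
       tp = tp, fp = length(pred_keys) - tp,
       fn = length(truth_keys) - tp)
}

read_community_dir <- function(dir, tbox = NULL) {
  man_path <- file.path(dir, "annotations.tsv")
  for (f in c(man_path, file.path(dir, c("sites.tsv", "orthology.tsv",
                                         "registry.tsv"))))
    if (!file.exists(f)) stop("missing required input: ", f, call. = FALSE)
  manifest <- utils::read.delim(man_path, stringsAsFactors = FALSE)
  registry <- read_registry(file.path(dir, "registry.tsv"))
  genomes <- list()
  for (i in seq_len(nrow(manifest)))
    genomes[[manifest$genome_id[i]]] <-
      read_annotations(file.path(dir, manifest$path[i]),
                       format = manifest$format[i],
                       genome_id = manifest$genome_id[i],
                       taxgroup_id = manifest$taxgroup_id[i])
  raw <- utils::read.delim(file.path(dir, "sites.tsv"),
                           stringsAsFactors = FALSE)
  sites <- do.call(rbind, lapply(split(raw, raw$genome_id), function(sub) {
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp))
    utils::write.table(sub, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    read_sites(tmp, registry, genome_id = sub$genome_id[1], format = "tsv")
  }))
  rownames(sites) <- NULL
  orthology <- read_orthology(file.path(dir, "orthology.tsv"))
  known <- unlist(lapply(genomes, function(g)
    paste(g$genome_id, g$genes$gene_id, sep = "\r")))
  miss <- !paste(orthology$genome_id, orthology$gene_id, sep = "\r") %in% known
  if (any(miss))
    warning(sum(miss), " orthology record(s) refer to genes absent from the ",
            "loaded genomes", call. = FALSE)
  fmap <- if (file.exists(file.path(dir, "functional_map.tsv")))
    read_functional_map(file.path(dir, "functional_map.tsv")) else NULL
  list(genomes = genomes, sites = sites, orthology = orthology,
       registry = registry, functional_map = fmap)
}

#' Run the full file-driven pipeline
#'
#' Reads a community directory (`annotations.tsv` manifest, per-genome
#' annotation files, `sites.tsv`, `orthology.tsv`, `registry.tsv`, optional
#' `functional_map.tsv`, `tbox_alignment.fasta` and `ground_truth.json`),
#' executes import, operon inference, site assignment, CRON clustering and
#' extension, T-box specificity calling and splitting, functional
#' classification and statistics, and writes every stage table plus a JSON
#' summary and a run manifest (parameter values and input checksums) to
#' `out_dir`. Rerunning on identical inputs and configuration produces
#' identical outputs.
#'
#' @param config list (or path to a YAML file encoding it) with elements
#'   `input_dir`, `out_dir`, optional `params` (see [default_params()]) and
#'   optional `tbox` (list with reference_id and codon_span).
#' @return invisibly, the in-memory result bundle.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$input_dir), !is.null(config$out_dir))
  params <- do.call(default_params, as.list(config$params %||% list()))
  inp <- read_community_dir(config$input_dir)
  res <- reconstruct(inp$genomes, inp$sites, inp$orthology, inp$registry,
                     params)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # T-box specificity
  calls <- NULL
  tbx <- file.path(config$input_dir, "tbox_alignment.fasta")
  if (file.exists(tbx)) {
    tb <- config$tbox %||% list(reference_id = "tbox_ref",
                                codon_span = c(61, 62, 63))
    aln <- read_tbox_alignment(tbx, tb$reference_id,
                               as.integer(tb$codon_span), format = "fasta")
    calls <- call_specificity(aln)
    split <- split_tbox_regulogs(res$regulogs, res$regulated, calls)
    res$regulogs_split <- split$regulogs
    res$tbox_unassigned <- split$unassigned
  }

  # functional classification and statistics
  summary <- list(parameters = params,
                  n_genomes = length(inp$genomes),
                  n_sites = nrow(res$sites),
                  n_regulated_operons = nrow(res$regulated),
                  n_crons = nrow(res$crons),
                  n_crons_accepted = sum(res$crons$accepted),
                  n_regulogs = nrow(res$regulogs))
  if (!is.null(res$regulogs_split))
    summary$n_regulogs_after_tbox_split <- nrow(res$regulogs_split)
  if (!is.null(inp$functional_map)) {
    genes <- regulog_genes(res$regulogs, res$operons, inp$genomes)
    assigns <- assign_categories(genes, inp$functional_map)
    res$gene_categories <- assigns
    write_tsv <- function(x, f) utils::write.table(
      x, file.path(out, f), sep = "\t", quote = FALSE, row.names = FALSE)
    write_tsv(category_counts(assigns, "sfc"), "sfc_counts.tsv")
    write_tsv(category_counts(assigns, "ofc"), "ofc_counts.tsv")
    write_tsv(ofc_proportions(assigns, "taxgroup"), "ofc_by_taxgroup.tsv")
    write_tsv(ofc_proportions(assigns, "motif"), "ofc_by_motif.tsv")
  }
  dm <- distribution_matrix(res$regulogs, inp$registry,
                            sort(unique(res$taxgroups)))
  lstats <- lineage_stats(lineage_summary(res$regulogs, inp$genomes))
  mstats <- motif_stats(motif_summary(res$regulogs, res$regulated))

  # stage outputs
  write_operons(res$operons, file.path(out, "operons.tsv"))
  flat <- function(df, cols) {
    for (c in cols) df[[c]] <- vapply(df[[c]], paste, "", collapse = ",")
    df
  }
  utils::write.table(res$assignment$assigned, file.path(out, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$assignment$orphans, file.path(out, "orphans.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$assignment$ambiguous, file.path(out, "ambiguous.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(flat(res$regulated, "site_ids"),
                     file.path(out, "regulated_operons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(flat(res$crons, c("member_operon_ids", "member_genomes")),
                     file.path(out, "crons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(flat(res$regulogs, c("cron_ids", "operon_ids")),
                     file.path(out, "regulogs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(calls))
    utils::write.table(calls, file.path(out, "tbox_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(motif_id = rownames(dm$presence),
                           as.data.frame(dm$presence)),
                     file.path(out, "distribution_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(lstats, file.path(out, "lineage_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mstats, file.path(out, "motif_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # recovery metrics against ground truth, if present
  gt_path <- file.path(config$input_dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    truth <- jsonlite::read_json(gt_path, simplifyVector = FALSE)
    truth$planted <- lapply(truth$planted, function(r) {
      r$site_ids <- unlist(r$site_ids); r
    })
    summary$recovery <- recovery_metrics(res, truth)
  }
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  inputs <- list.files(config$input_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(parameters = params,
                   inputs = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
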