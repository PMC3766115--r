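# Benchmark configurations exercising the pipeline under its reference study
# conditions, shared by the test suite and the acceptance script.

#' Recovery-benchmark configuration
#'
#' The planted-regulon recovery conditions: two taxonomic groups of five
#' genomes, five riboswitch regulons per group at conservation 0.8 (the
#' glycine-like one with tandem probability 0.82), and one spurious
#' intergenic site per genome, which puts the spurious fraction near 20% of
#' all emitted sites.
#'
#' @param seed RNG seed.
#' @return a [sim_config()].
#' @export
recovery_config <- function(seed) {
  planted <- list()
  for (tg in c("tg1", "tg2")) {
    planted <- c(planted, list(
      planted_regulon("RF00059", tg, conservation = 0.8,
                      roles = c("Thiamin biosynthesis",
                                "Thiamin & precursor transporters")),
      planted_regulon("RF00504", tg, conservation = 0.8, tandem_prob = 0.82,
                      roles = "Glycine metabolism"),
      planted_regulon("RF00162", tg, conservation = 0.8,
                      roles = "Methionine biosynthesis"),
      planted_regulon("RF00174", tg, conservation = 0.8,
                      roles = c("B12 biosynthesis", "Cobalt transporters")),
      planted_regulon("RF00050", tg, conservation = 0.8,
                      roles = "Riboflavin biosynthesis")))
  }
  sim_config(seed = seed, n_taxgroups = 2, genomes_per_group = 5,
             genes_per_genome = 60, planted = planted,
             spurious_per_genome = 1)
}

#' Pooled planted-regulon recovery over seeded replicates
#'
#' Simulates a community per seed under [recovery_config()], reconstructs
#' regulons with default parameters, and pools true/false positives and
#' false negatives across replicates.
#'
#' @param seeds integer vector of replicate seeds.
#' @return list precision, recall, tp, fp, fn, n_truth, spurious_fraction
#'   (spurious sites over all sites across replicates).
#' @export
recovery_benchmark <- function(seeds) {
  tp <- fp <- fn <- n_truth <- n_sites <- n_spur <- 0
  for (s in seeds) {
    sim <- simulate_community(recovery_config(s))
    res <- reconstruct(sim$genomes, sim$sites, sim$orthology, sim$registry)
    m <- recovery_metrics(res, sim$truth)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    n_truth <- n_truth + length(sim$truth$planted)
    n_sites <- n_sites + nrow(sim$sites)
    n_spur <- n_spur + length(sim$truth$spurious_site_ids)
  }
  list(precision = tp / (tp + fp), recall = tp / (tp + fn),
       tp = tp, fp = fp, fn = fn, n_truth = n_truth,
       spurious_fraction = n_spur / n_sites)
}

#' Glycine-benchmark configuration
#'
#' Many independent glycine-like regulons (one per taxonomic group) at the
#' characteristic glycine operating point: conservation 0.8, tandem
#' probability 0.82 and the 1-4 gene operon-size distribution with mean 2.3.
#'
#' @param seed RNG seed.
#' @param n_taxgroups,genomes_per_group community shape (defaults give about
#'   forty regulated operons per replicate).
#' @return a [sim_config()].
#' @export
glycine_config <- function(seed, n_taxgroups = 6, genomes_per_group = 8) {
  planted <- lapply(seq_len(n_taxgroups), function(t)
    planted_regulon("RF00504", paste0("tg", t), conservation = 0.8,
                    tandem_prob = 0.82, roles = "Glycine metabolism",
                    operon_size = NA))
  sim_config(seed = seed, n_taxgroups = n_taxgroups,
             genomes_per_group = genomes_per_group, genes_per_genome = 30,
             planted = planted, spurious_per_genome = 0)
}

#' Tandem statistics of simulated glycine regulons
#'
#' Simulates under [glycine_config()] for each seed, reconstructs, and pools
#' the glycine-family regulated operons.
#'
#' @param seeds integer vector of replicate seeds.
#' @return [tandem_stats()] of the pooled operons, plus `n_operons`.
#' @export
glycine_benchmark <- function(seeds) {
  pooled <- list()
  for (s in seeds) {
    sim <- simulate_community(glycine_config(s))
    res <- reconstruct(sim$genomes, sim$sites, sim$orthology, sim$registry)
    pooled[[length(pooled) + 1]] <-
      res$regulated[res$regulated$motif_id == "RF00504",
                    c("tandem", "n_genes")]
  }
  tandem_stats(do.call(rbind, pooled))
}
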