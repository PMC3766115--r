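test_that("distribution groups follow class fixing and the presence thresholds", {
  expect_equal(classify_distribution_group(24, "riboswitch"), "A")
  expect_equal(classify_distribution_group(19, "riboswitch"), "A")  # >75%
  expect_equal(classify_distribution_group(18, "riboswitch"), "B")  # exactly 75%
  expect_equal(classify_distribution_group(4, "riboswitch"), "B")
  expect_equal(classify_distribution_group(3, "riboswitch"), "C")
  expect_equal(classify_distribution_group(1, "pyrR"), "C")
  expect_equal(classify_distribution_group(12, "ribosomal_leader"), "D")
  expect_equal(classify_distribution_group(12, "aa_leader"), "E")
  expect_equal(classify_distribution_group(24, "tbox"), "F")
})

test_that("group classification is monotone in presence", {
  for (n in 1:23) {
    a <- classify_distribution_group(n, "riboswitch")
    b <- classify_distribution_group(n + 1, "riboswitch")
    rank <- c(C = 1, B = 2, A = 3)
    expect_true(rank[b] >= rank[a])
  }
})

test_that("presence matrix column sums equal per-lineage distinct-motif regulog counts", {
  sim <- simulate_community(sim_config(seed = 23))
  res <- reconstruct(sim$genomes, sim$sites, sim$orthology, sim$registry)
  dm <- distribution_matrix(res$regulogs, sim$registry,
                            sort(unique(res$taxgroups)))
  for (tg in colnames(dm$presence)) {
    expect_equal(sum(dm$presence[, tg]),
                 length(unique(res$regulogs$motif_id[
                   res$regulogs$taxgroup_id == tg])))
  }
})

test_that("the bundled lineage reference table reproduces every printed ratio", {
  ref <- utils::read.delim(system.file("extdata",
                                       "reference_lineage_totals.tsv",
                                       package = "rnaregulon"))
  st <- lineage_stats(ref[, c("taxgroup_id", "genomes", "sites", "regulogs",
                              "genes")])
  body <- st[st$taxgroup_id != "TOTAL", ]
  expect_equal(body$sites_per_genome, ref$published_sites_per_genome)
  expect_equal(body$genes_per_genome, ref$published_genes_per_genome)
  grand <- st[st$taxgroup_id == "TOTAL", ]
  expect_equal(grand$genomes, 255)
  expect_equal(grand$sites, sum(ref$sites))
  expect_equal(grand$sites_per_genome, 20)  # weighted convention
  expect_equal(grand$genes, 12451)
  expect_equal(grand$genes_per_genome, 46)  # unweighted lineage-mean convention
})

test_that("lineages with zero regulogs yield zeros, not division errors", {
  t <- data.frame(taxgroup_id = "empty", genomes = 0L, sites = 0L,
                  regulogs = 0L, genes = 0L)
  st <- lineage_stats(t)
  expect_equal(st$sites_per_genome, c(0, 0))
  expect_false(any(is.na(st$genes_per_genome)))
})

test_that("per-motif ratios follow the mixed formatting rule and flag zero-site motifs", {
  t <- data.frame(motif_id = c("RF00174", "RF00059", "none"),
                  sites = c(535L, 564L, 0L), genes = c(2400L, 1800L, 0L),
                  genomes_with_site = c(197L, 249L, 0L))
  ms <- motif_stats(t)
  expect_equal(ms$genes_per_riboswitch[1], 4.5)
  expect_equal(ms$genes_per_genome[1], 12)
  expect_equal(ms$genes_per_riboswitch[2], 3.2)
  expect_true(is.na(ms$genes_per_riboswitch[3]))
  expect_true(ms$undefined[3])
})

test_that("OFC proportions exclude unknown genes, sum to one and report N/A scopes", {
  fmap <- bundled_fmap()
  recs <- data.frame(
    motif_id = c(rep("m1", 5), "m2"),
    taxgroup_id = c(rep("t1", 5), "t2"),
    gene_id = paste0("g", 1:6),
    functional_role = c("Thiamin biosynthesis", "B12 biosynthesis",
                        "Riboflavin biosynthesis", "Thiamin & precursor transporters",
                        "", ""),
    stringsAsFactors = FALSE)
  a <- assign_categories(recs, fmap)
  p <- ofc_proportions(a, "motif")
  m1 <- p[p$scope == "m1", ]
  expect_equal(sum(m1$proportion), 1, tolerance = 1e-9)
  expect_equal(m1$proportion[m1$ofc == "Coenzyme metabolism"], 0.75)
  expect_equal(m1$proportion[m1$ofc == "Coenzyme uptake"], 0.25)
  m2 <- p[p$scope == "m2", ]
  expect_equal(m2$label, "N/A")
  expect_true(is.na(m2$proportion))
})

test_that("tandem statistics count each operon once", {
  reg <- data.frame(tandem = c(rep(TRUE, 8), rep(FALSE, 2)),
                    n_genes = c(2, 2, 3, rep(2, 7)))
  ts <- tandem_stats(reg)
  expect_equal(ts$tandem_fraction, 0.8)
  expect_equal(ts$mean_operon_size, mean(c(2, 2, 3, rep(2, 7))))

  small <- data.frame(tandem = c(TRUE, FALSE, FALSE), n_genes = c(2, 2, 3))
  expect_equal(tandem_stats(small)$mean_operon_size, 7 / 3, tolerance = 1e-12)

  none <- tandem_stats(reg[0, ])
  expect_true(none$undefined)
  expect_true(is.na(none$tandem_fraction))
})

test_that("half-up rounding and the mixed format rule behave at the edges", {
  expect_equal(round_half_up(11.5), 12)
  expect_equal(round_half_up(29.5), 30)
  expect_equal(round_half_up(7.55, 1), 7.6)
  expect_equal(format_ratio(9.96), 10)   # below 10 -> one decimal -> 10.0
  expect_equal(format_ratio(10.4), 10)
  expect_equal(format_ratio(7.64), 7.6)
})
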