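test_that("the simulator is byte-identical under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  write_community(simulate_community(sim_config(seed = 5)), d1)
  write_community(simulate_community(sim_config(seed = 5)), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # a different seed changes the community
  d3 <- tempfile()
  write_community(simulate_community(sim_config(seed = 6)), d3)
  expect_false(identical(readLines(file.path(d1, "sites.tsv")),
                         readLines(file.path(d3, "sites.tsv"))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("presence probability one puts every ortholog group in every genome", {
  cfg <- sim_config(seed = 8, og_presence = 1)
  sim <- simulate_community(cfg)
  per_genome <- table(sim$orthology$genome_id)
  expect_true(all(per_genome == cfg$genes_per_genome))
  for (tg in c("tg1", "tg2")) {
    gens <- names(sim$genomes)[startsWith(names(sim$genomes), tg)]
    ogs <- lapply(gens, function(g)
      sort(sim$orthology$ortholog_group_id[sim$orthology$genome_id == g]))
    for (k in seq_along(ogs)[-1]) expect_equal(ogs[[k]], ogs[[1]])
  }
})

test_that("planted sites sit inside assignment windows; spurious sites produce no regulated operons", {
  # noise-only configuration: planted conservation zero
  cfg <- sim_config(seed = 12, spurious_per_genome = 3,
                    planted = list(planted_regulon("RF00059", "tg1",
                                                   conservation = 0,
                                                   roles = "Thiamin biosynthesis")))
  sim <- simulate_community(cfg)
  expect_true(all(sim$sites$site_id %in% sim$truth$spurious_site_ids))
  ops <- do.call(rbind, lapply(sim$genomes, infer_operons))
  asg <- assign_sites(deduplicate_hits(sim$sites), ops)
  expect_equal(nrow(asg$regulated), 0)
  expect_equal(nrow(asg$orphans), nrow(deduplicate_hits(sim$sites)))

  # planted sites are all assigned to their intended leader's operon
  sim2 <- simulate_community(sim_config(seed = 12))
  ops2 <- do.call(rbind, lapply(sim2$genomes, infer_operons))
  asg2 <- assign_sites(deduplicate_hits(sim2$sites), ops2)
  planted_sites <- unlist(lapply(sim2$truth$planted, `[[`, "site_ids"))
  expect_true(all(planted_sites %in% asg2$assigned$site_id))
  leader_of <- stats::setNames(ops2$leader_gene, ops2$operon_id)
  for (r in sim2$truth$planted) {
    rows <- asg2$assigned[asg2$assigned$site_id %in% r$site_ids, ]
    expect_true(all(leader_of[rows$operon_id] == r$leader_gene))
  }
})

test_that("tandem probability one doubles every planted operon's sites", {
  cfg <- sim_config(seed = 14,
                    planted = list(planted_regulon("RF00504", "tg1",
                                                   conservation = 1,
                                                   tandem_prob = 1,
                                                   roles = "Glycine metabolism")),
                    spurious_per_genome = 0)
  sim <- simulate_community(cfg)
  expect_true(all(vapply(sim$truth$planted, function(r)
    length(r$site_ids) == 2, logical(1))))
  ops <- do.call(rbind, lapply(sim$genomes, infer_operons))
  asg <- assign_sites(deduplicate_hits(sim$sites), ops)
  expect_true(all(asg$regulated$tandem))
})

test_that("empirical conservation matches the configured level within binomial bounds", {
  p <- 0.7
  n_genomes <- 4
  seeds <- 1:30
  regulated <- 0
  for (s in seeds) {
    cfg <- sim_config(seed = 100 + s,
                      planted = list(planted_regulon("RF00059", "tg1",
                                                     conservation = p,
                                                     roles = "Thiamin biosynthesis")),
                      spurious_per_genome = 0)
    sim <- plant_regulons(generate_community(cfg))
    regulated <- regulated + length(sim$truth$planted)
  }
  n <- length(seeds) * n_genomes
  lo <- qbinom(0.025, n, p); hi <- qbinom(0.975, n, p)
  expect_gte(regulated, lo)
  expect_lte(regulated, hi)
})
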