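# A reusable three-genome fixture: one taxgroup, each genome carrying an
# orthologous two-gene operon (OG1 leader, OG2) with an upstream TPP site.
cron_fixture <- function(n_genomes = 3, regulate = seq_len(n_genomes),
                         taxgroup = "tg1") {
  genomes <- list()
  orows <- list()
  sites <- list()
  for (i in seq_len(n_genomes)) {
    gid <- paste0("G", i)
    genomes[[gid]] <- make_genome(
      paste0(gid, c("_a", "_b", "_c")), c(2000, 2500, 6000),
      c(2400, 2900, 6500), rep("+", 3), genome_id = gid,
      taxgroup_id = taxgroup,
      roles = c("Thiamin biosynthesis", "Thiamin & precursor transporters", ""))
    orows[[gid]] <- make_orthology(rep(gid, 3), paste0(gid, c("_a", "_b", "_c")),
                                   c("OG1", "OG2", "OG3"))
    if (i %in% regulate)
      sites[[gid]] <- make_sites(paste0("s", i), "RF00059", gid, 1850, 1950, "+")
  }
  orth <- do.call(rbind, orows)
  class(orth) <- c("OrthologyMap", "data.frame")
  list(genomes = genomes, orthology = orth,
       sites = do.call(rbind, sites),
       taxgroups = vapply(genomes, function(g) g$taxgroup_id, ""))
}

test_that("regulated operons with a shared leader ortholog form one CRON", {
  fx <- cron_fixture(3)
  ops <- do.call(rbind, lapply(fx$genomes, infer_operons))
  reg <- assign_sites(fx$sites, ops)$regulated
  crons <- build_crons(reg, ops, fx$orthology, fx$taxgroups)
  expect_equal(nrow(crons), 1)
  expect_equal(crons$n_members, 3)
  expect_equal(crons$anchor_group, "OG1")
})

test_that("clusters merge above the Jaccard bound and stay apart below it", {
  # two anchor clusters with operon OG sets {A,B,C} and {B,C,D}: Jaccard 0.5
  og_sets <- list(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(max(rnaregulon:::merge_components(og_sets, 0.5)), 1)
  # disjoint sets stay separate
  og_sets2 <- list(c("A", "B"), c("C", "D"))
  expect_equal(max(rnaregulon:::merge_components(og_sets2, 0.5)), 2)
})

test_that("CRON merging matches a brute-force transitive-closure oracle", {
  set.seed(21)
  universe <- LETTERS[1:8]
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    og_sets <- lapply(seq_len(n), function(i)
      sample(universe, sample(2:5, 1)))
    got <- rnaregulon:::merge_components(og_sets, 0.5)
    want <- oracle_components(og_sets, 0.5)
    expect_equal(partition_signature(got), partition_signature(want))
  }
})

test_that("conservation is regulated genomes over anchor-bearing genomes", {
  fx <- cron_fixture(5, regulate = 1:4)
  expect_equal(score_conservation(paste0("G", 1:4), "OG1", paste0("G", 1:5),
                                  fx$orthology), 0.8)
  expect_equal(score_conservation(paste0("G", 1:5), "OG1", paste0("G", 1:5),
                                  fx$orthology), 1.0)
  # anchor present in all 5 but regulated in 1
  expect_equal(score_conservation("G1", "OG1", paste0("G", 1:5),
                                  fx$orthology), 0.2)
  expect_warning(z <- score_conservation("G1", "unassigned:x",
                                         paste0("G", 1:5), fx$orthology),
                 "absent")
  expect_equal(z, 0)
})

test_that("conservation is bounded and monotone in regulated members", {
  fx <- cron_fixture(6)
  vals <- vapply(1:6, function(k)
    score_conservation(paste0("G", 1:k), "OG1", paste0("G", 1:6),
                       fx$orthology), numeric(1))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(diff(vals) >= 0))
})

test_that("acceptance applies conservation and genome-count thresholds with singleton rescue", {
  fx <- cron_fixture(5, regulate = 1:4)
  ops <- do.call(rbind, lapply(fx$genomes, infer_operons))
  reg <- assign_sites(fx$sites, ops)$regulated
  crons <- score_crons(build_crons(reg, ops, fx$orthology, fx$taxgroups),
                       fx$orthology, fx$taxgroups)
  acc <- accept_crons(crons, reg, fx$sites, tiny_registry())
  expect_true(acc$accepted)  # conservation 0.8, 4 genomes

  # single regulated genome, low score: rejected
  fx1 <- cron_fixture(5, regulate = 1)
  fx1$sites$score <- 40
  ops1 <- do.call(rbind, lapply(fx1$genomes, infer_operons))
  reg1 <- assign_sites(fx1$sites, ops1)$regulated
  cr1 <- score_crons(build_crons(reg1, ops1, fx1$orthology, fx1$taxgroups),
                     fx1$orthology, fx1$taxgroups)
  expect_false(accept_crons(cr1, reg1, fx1$sites, tiny_registry())$accepted)

  # same cluster with a high-confidence site: rescued
  fx1$sites$score <- 90
  expect_true(accept_crons(cr1, reg1, fx1$sites, tiny_registry())$accepted)
})

test_that("operon extension requires both the gap cap and ortholog support", {
  build <- function(gap, with_support) {
    genomes <- list(); orows <- list(); sites <- list()
    for (i in 1:5) {
      gid <- paste0("G", i)
      # two-gene operon (OG1,OG2) then a downstream gene at the given gap in
      # genome 1; in the others the downstream gene is adjacent (in-operon)
      # when support is wanted, absent otherwise
      if (i == 1) {
        starts <- c(2000, 2500, 2900 + gap + 1)
        ends <- c(2400, 2900, 2900 + gap + 400)
        ids <- paste0(gid, c("_a", "_b", "_x"))
        ogs <- c("OG1", "OG2", "OGX")
      } else if (with_support) {
        starts <- c(2000, 2500, 3000); ends <- c(2400, 2900, 3400)
        ids <- paste0(gid, c("_a", "_b", "_x"))
        ogs <- c("OG1", "OG2", "OGX")
      } else {
        starts <- c(2000, 2500); ends <- c(2400, 2900)
        ids <- paste0(gid, c("_a", "_b"))
        ogs <- c("OG1", "OG2")
      }
      genomes[[gid]] <- make_genome(ids, starts, ends, rep("+", length(ids)),
                                    genome_id = gid, taxgroup_id = "tg1")
      orows[[gid]] <- make_orthology(rep(gid, length(ids)), ids, ogs)
      sites[[gid]] <- make_sites(paste0("s", i), "RF00059", gid, 1850, 1950, "+")
    }
    orth <- do.call(rbind, orows); class(orth) <- c("OrthologyMap", "data.frame")
    taxgroups <- vapply(genomes, function(g) g$taxgroup_id, "")
    ops <- do.call(rbind, lapply(genomes, infer_operons))
    reg <- assign_sites(do.call(rbind, sites), ops)$regulated
    crons <- score_crons(build_crons(reg, ops, orth, taxgroups), orth, taxgroups)
    crons <- accept_crons(crons, reg, do.call(rbind, sites), tiny_registry())
    list(crons = crons, ops = ops, genomes = genomes, orth = orth)
  }

  # gap 250 with the downstream ortholog in the 4 other members: appended
  fx <- build(gap = 250, with_support = TRUE)
  ext <- extend_operons(fx$crons, fx$ops, fx$genomes, fx$orth)
  g1op <- ext$operons[ext$operons$genome_id == "G1" &
                        ext$operons$leader_gene == "G1_a", ]
  expect_true("G1_x" %in% g1op$gene_ids[[1]])
  expect_equal(ext$log$gap[ext$log$gene_id == "G1_x"], 250)

  # gap 250 without support elsewhere: not appended
  fx2 <- build(gap = 250, with_support = FALSE)
  ext2 <- extend_operons(fx2$crons, fx2$ops, fx2$genomes, fx2$orth)
  g1op2 <- ext2$operons[ext2$operons$genome_id == "G1" &
                          ext2$operons$leader_gene == "G1_a", ]
  expect_false("G1_x" %in% g1op2$gene_ids[[1]])

  # gap 301 with universal support: blocked by the cap
  fx3 <- build(gap = 301, with_support = TRUE)
  ext3 <- extend_operons(fx3$crons, fx3$ops, fx3$genomes, fx3$orth)
  g1op3 <- ext3$operons[ext3$operons$genome_id == "G1" &
                          ext3$operons$leader_gene == "G1_a", ]
  expect_false("G1_x" %in% g1op3$gene_ids[[1]])
})

test_that("regulogs aggregate accepted CRONs with tandem-aware totals", {
  fx <- cron_fixture(3)
  ops <- do.call(rbind, lapply(fx$genomes, infer_operons))
  # add a tandem partner upstream of genome 1's operon
  extra <- make_sites("s1b", "RF00059", "G1", 1700, 1800, "+")
  sites <- rbind(fx$sites, extra)
  reg <- assign_sites(sites, ops)$regulated
  crons <- score_crons(build_crons(reg, ops, fx$orthology, fx$taxgroups),
                       fx$orthology, fx$taxgroups)
  crons <- accept_crons(crons, reg, sites, tiny_registry())
  rl <- assemble_regulogs(crons, reg)
  expect_equal(nrow(rl), 1)
  expect_equal(rl$total_sites, 4)   # tandem pair counts both sites
  expect_equal(rl$n_operons, 3)     # but the operon only once
  expect_equal(rl$total_genes, 6)
  expect_equal(rl$genome_count, 3)

  # a motif with only rejected CRONs yields no regulog
  crons$accepted <- FALSE
  expect_equal(nrow(assemble_regulogs(crons, reg)), 0)
})
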