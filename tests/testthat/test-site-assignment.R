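test_that("overlap deduplication keeps the dominant hit with declared tie-breaks", {
  s <- make_sites(c("s1", "s2"), "RF00059", "G1", c(100, 150), c(200, 250),
                  c("+", "+"), scores = c(50, 45))
  expect_equal(deduplicate_hits(s)$site_id, "s1")

  s2 <- make_sites(c("s1", "s2"), "RF00059", "G1", c(100, 300), c(200, 400),
                   c("+", "+"), scores = c(50, 45))
  expect_equal(nrow(deduplicate_hits(s2)), 2)

  # three mutually overlapping equal-score hits: leftmost survives
  s3 <- make_sites(c("sC", "sB", "sA"), "RF00059", "G1",
                   c(120, 110, 100), c(220, 210, 200), rep("+", 3),
                   scores = 50)
  expect_equal(deduplicate_hits(s3)$site_id, "sA")
})

test_that("the assignment window is 500 nt upstream to 100 nt downstream of the start codon", {
  g <- make_genome("A", 1000, 1900, "+")
  ops <- infer_operons(g)
  inside <- make_sites("s1", "RF00059", "G1", 450, 520, "+")
  asg <- assign_sites(inside, ops)
  expect_equal(nrow(asg$assigned), 1)
  expect_equal(asg$assigned$distance, -480)

  boundary <- make_sites("s2", "RF00059", "G1", 430, 500, "+")  # exactly -500
  expect_equal(nrow(assign_sites(boundary, ops)$assigned), 1)

  outside <- make_sites("s3", "RF00059", "G1", 430, 499, "+")   # -501
  res <- assign_sites(outside, ops)
  expect_equal(nrow(res$assigned), 0)
  expect_equal(nrow(res$orphans), 1)

  down <- make_sites("s4", "RF00059", "G1", 1050, 1100, "+")    # +100
  expect_equal(assign_sites(down, ops)$assigned$distance, 100)
  past <- make_sites("s5", "RF00059", "G1", 1050, 1101, "+")    # +101
  expect_equal(nrow(assign_sites(past, ops)$assigned), 0)
})

test_that("minus-strand windows mirror the plus-strand geometry", {
  g <- make_genome("A", 4000, 5000, "-", contigs = c(c1 = 10000L))
  ops <- infer_operons(g)
  expect_equal(ops$leader_start_codon, 5000)
  s <- make_sites("s1", "RF00059", "G1", 5400, 5480, "-")
  asg <- assign_sites(s, ops)
  expect_equal(nrow(asg$assigned), 1)
  expect_equal(asg$assigned$distance, -400)
  # wrong strand never qualifies
  s2 <- make_sites("s2", "RF00059", "G1", 5400, 5480, "+")
  expect_equal(nrow(assign_sites(s2, ops)$assigned), 0)
})

test_that("tandem sites form one regulated operon and are counted once", {
  g <- make_genome(c("A", "B", "C"), c(2000, 2500, 3000),
                   c(2400, 2900, 3400), rep("+", 3))
  ops <- infer_operons(g)
  expect_equal(nrow(ops), 1)
  s <- make_sites(c("s1", "s2"), "RF00504", "G1", c(1850, 1700),
                  c(1950, 1820), c("+", "+"))
  asg <- assign_sites(s, ops)
  expect_equal(nrow(asg$regulated), 1)
  expect_true(asg$regulated$tandem)
  expect_equal(asg$regulated$n_sites, 2)
  reg <- build_regulons(asg$regulated)
  expect_equal(reg$gene_count, 3)  # sites do not multiply genes
})

test_that("divergent anchors resolve to the nearer start codon; exact ties stay ambiguous", {
  # divergent pair: minus-strand gene ending 1000, plus-strand gene starting 1500
  g <- make_genome(c("L", "R"), c(500, 1500), c(1000, 2200), c("-", "+"),
                   contigs = c(c1 = 5000L))
  ops <- infer_operons(g)
  # a minus-strand site in the shared gap is upstream of L only
  s <- make_sites("s1", "RF00059", "G1", 1100, 1180, "-")
  asg <- assign_sites(s, ops)
  expect_equal(asg$assigned$operon_id,
               ops$operon_id[ops$leader_gene == "L"])

  # nearer start codon wins when a site qualifies for two operons
  g2 <- make_genome(c("A", "B"), c(1000, 1200), c(1090, 1600), c("+", "+"))
  ops2 <- infer_operons(g2, max_gap = 100)  # gap 109 -> two operons
  s2 <- make_sites("near", "RF00059", "G1", 1030, 1110, "+")
  # distance to A = +110 (outside); to B = -90 (inside) -> B
  expect_equal(assign_sites(s2, ops2)$assigned$operon_id, ops2$operon_id[2])

  # exact distance tie: flagged ambiguous, neither auto-assigned
  s3 <- make_sites("tie", "RF00059", "G1", 1030, 1100, "+")
  # distance to A = +100, to B = -100
  asg3 <- assign_sites(s3, ops2)
  expect_equal(nrow(asg3$assigned), 0)
  expect_equal(nrow(asg3$ambiguous), 1)
  expect_equal(nrow(asg3$orphans), 0)
})

test_that("every deduplicated site is assigned, ambiguous or orphaned exactly once", {
  sim <- simulate_community(sim_config(seed = 13, spurious_per_genome = 2))
  ops <- do.call(rbind, lapply(sim$genomes, infer_operons))
  dedup <- deduplicate_hits(sim$sites)
  asg <- assign_sites(dedup, ops)
  expect_equal(nrow(asg$assigned) + nrow(asg$ambiguous) + nrow(asg$orphans),
               nrow(dedup))
  expect_false(any(asg$assigned$site_id %in% asg$orphans$site_id))
})

test_that("assignments are invariant under reverse complement of the genome", {
  sim <- simulate_community(sim_config(seed = 17))
  g <- sim$genomes[[1]]
  sites <- sim$sites[sim$sites$genome_id == g$genome_id, ]
  a1 <- assign_sites(sites, infer_operons(g))
  a2 <- assign_sites(revcomp_sites(sites, g$contigs),
                     infer_operons(revcomp_genome(g)))
  expect_equal(sort(a1$assigned$site_id), sort(a2$assigned$site_id))
  expect_equal(a1$assigned$distance[order(a1$assigned$site_id)],
               a2$assigned$distance[order(a2$assigned$site_id)])
})

test_that("regulons aggregate operons per motif and genome", {
  g <- make_genome(c("A", "B", "C", "D", "E"),
                   c(2000, 2500, 6000, 6500, 7000),
                   c(2400, 2900, 6400, 6900, 7400), rep("+", 5))
  ops <- infer_operons(g)
  expect_equal(nrow(ops), 2)
  s <- make_sites(c("s1", "s2"), "RF00059", "G1", c(1850, 5850),
                  c(1950, 5950), c("+", "+"))
  reg <- build_regulons(assign_sites(s, ops)$regulated)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$gene_count, 5)
  expect_equal(reg$n_operons, 2)
  # absence: a motif with no assigned sites emits no regulon
  expect_equal(nrow(build_regulons(assign_sites(
    make_sites("x", "RF00504", "G1", 100, 150, "+"), ops)$regulated)), 0)
})
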