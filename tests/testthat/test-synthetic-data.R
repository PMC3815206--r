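test_that("Yule trees are binary, reproducible, and match the depth expectation", {
  tr <- simulateSpeciesTree(3, 1, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$Nnode, 2)
  expect_true(all(tr$edge.length > 0))

  expect_identical(ape::write.tree(simulateSpeciesTree(7, 2, seed = 9)),
                   ape::write.tree(simulateSpeciesTree(7, 2, seed = 9)))

  # Monte-Carlo root-to-tip depth vs the pure-birth expectation
  # (1/lambda) * sum_{k=2..n} 1/k
  n <- 6
  lambda <- 1
  set.seed(11)
  H <- replicate(200, {
    t2 <- simulateSpeciesTree(n, lambda)
    max(ape::node.depth.edgelength(t2)[seq_len(n)])
  })
  expected <- sum(1 / (2:n)) / lambda
  se <- stats::sd(H) / sqrt(length(H))
  expect_lt(abs(mean(H) - expected), 3 * se + 1e-9)
})

test_that("gene content evolution is local, conservative and matches exp(-loss*t)", {
  tr <- ape::read.tree(text = "((t1:1,t2:1):0.5,t3:1.5);")
  # no events: all genomes identical to the root inventory
  cfg0 <- simulationConfig(nTaxa = 3, rootGeneCount = 40, gainRate = 0,
                           lossRate = 0, dupRate = 0, substRate = 0,
                           inversionRate = 0, translocationRate = 0,
                           seed = 2)
  res0 <- evolveGeneContent(tr, cfg0)
  expect_true(all(vapply(res0$inventories, nrow, 0L) == 40))
  expect_equal(nClusters(res0$clusters), 40)
  # conservation: cluster member counts sum to the total gene count
  expect_equal(nrow(res0$clusters@members),
               sum(vapply(res0$inventories, nrow, 0L)))

  # loss on one terminal branch only shrinks only that genome
  # base loss ~0; the branch effect makes t1's effective rate 1
  cfg1 <- simulationConfig(nTaxa = 3, rootGeneCount = 200, gainRate = 0,
                           lossRate = 1e-6, dupRate = 0, substRate = 0,
                           inversionRate = 0, translocationRate = 0,
                           lineageEffects = list(
                             list(tips = "t1", lossMult = 1e6)),
                           seed = 3)
  res1 <- evolveGeneContent(tr, cfg1)
  expect_lt(nrow(res1$inventories$t1), 200)
  expect_equal(nrow(res1$inventories$t2), 200)
  expect_equal(nrow(res1$inventories$t3), 200)
  ev <- res1$eventLog
  expect_true(all(ev$branch[ev$event == "loss"] == "t1"))

  # mean retained fraction over replicates ~ exp(-loss * t)
  kept <- vapply(1:40, function(s) {
    cfg <- simulationConfig(nTaxa = 3, rootGeneCount = 100, gainRate = 0,
                            lossRate = 0.5, dupRate = 0, substRate = 0,
                            inversionRate = 0, translocationRate = 0,
                            seed = 1000 + s)
    nrow(evolveGeneContent(tr, cfg)$inventories$t3) / 100
  }, numeric(1))
  expect_lt(abs(mean(kept) - exp(-0.5 * 1.5)), 0.03)
})

test_that("gene order evolution leaves orders unchanged without events", {
  tr <- simulateSpeciesTree(4, 1, seed = 5)
  cfg <- simulationConfig(nTaxa = 4, rootGeneCount = 25, gainRate = 0,
                          lossRate = 0, dupRate = 0, substRate = 0,
                          inversionRate = 0, translocationRate = 0, seed = 5)
  ords <- evolveGeneOrder(tr, cfg)
  base <- sub("^t[0-9]+\\|", "", ords[[1]])
  for (o in ords) expect_equal(sub("^t[0-9]+\\|", "", o), base)
})

test_that("sequence evolution shifts aminoGC with the lineage GC bias", {
  # zero substitution: all orthologs identical
  tr <- simulateSpeciesTree(4, 1, seed = 6)
  cfg0 <- simulationConfig(nTaxa = 4, rootGeneCount = 20, gainRate = 0,
                           lossRate = 0, dupRate = 0, substRate = 0,
                           inversionRate = 0, translocationRate = 0,
                           seed = 6)
  prot <- evolveSequences(tr, cfg0)
  s1 <- as.character(prot[[1]])
  for (p in prot) expect_identical(unname(as.character(p)), unname(s1))

  # gc_bias -0.8 on one lineage: aminoGC strictly below the unbiased mean
  cfg1 <- simulationConfig(nTaxa = 6, rootGeneCount = 100, substRate = 0.5,
                           lineageEffects = list(
                             list(tips = "t1", gcBias = -0.8)),
                           seed = 9)
  sim <- simulateDataset(cfg1)
  agc <- vapply(sim@proteomes, function(p)
    mean(aminoGC(as.character(p))), numeric(1))
  expect_lt(agc[["t1"]], mean(agc[names(agc) != "t1"]))
  expect_lt(agc[["t1"]], min(agc[names(agc) != "t1"]))

  # sibling taxa with equal settings: statistically indistinguishable
  # aminoGC (the tree from seed 13 has the cherry (t5, t6))
  cfg2 <- simulationConfig(nTaxa = 6, rootGeneCount = 100, seed = 13)
  sim2 <- simulateDataset(cfg2)
  g5 <- aminoGC(as.character(sim2@proteomes$t5))
  g6 <- aminoGC(as.character(sim2@proteomes$t6))
  expect_gt(stats::wilcox.test(g5, g6)$p.value, 0.01)
})

test_that("datasets are a pure function of the configuration", {
  cfg <- simulationConfig(nTaxa = 5, rootGeneCount = 30, seed = 17)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeDataset(simulateDataset(cfg), d1)
  writeDataset(simulateDataset(cfg), d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("written datasets round-trip through the format readers", {
  cfg <- simulationConfig(nTaxa = 4, rootGeneCount = 20, seed = 19)
  sim <- simulateDataset(cfg)
  d <- withr::local_tempdir()
  writeDataset(sim, d)
  cs <- readClusters(file.path(d, "true_clusters.txt"),
                     taxa = clusterTaxa(sim@clusters))
  expect_identical(cs@members, sim@clusters@members)
  ann <- readGeneTable(file.path(d, "gene_tables.tsv"))
  expect_identical(sort(names(ann)), sort(names(sim@annotations)))
  for (g in names(ann))
    expect_equal(geneOrder(ann[[g]]), geneOrder(sim@annotations[[g]]))
  prot <- readFasta(file.path(d, "proteome_t1.faa"))
  expect_identical(as.character(prot), as.character(sim@proteomes$t1))
  tr <- readNewick(file.path(d, "species_tree.nwk"))
  expect_equal(sort(tr$tip.label), sort(sim@tree$tip.label))
  tax <- readTaxonomy(file.path(d, "taxonomy.tsv"))
  expect_identical(tax, sim@taxonomy)
  # taxonomy strata are tree cuts: same genus implies same family/order
  byG <- split(tax, tax$genus)
  for (d2 in byG) {
    expect_equal(length(unique(d2$family)), 1)
    expect_equal(length(unique(d2$order)), 1)
  }
})
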