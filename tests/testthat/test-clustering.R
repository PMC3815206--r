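test_that("threshold filtering applies all three predicates", {
  cs <- filterToy()
  res <- filterClusters(cs, minTaxa = 3, maxCopiesPerGenome = 3,
                        maxGenes = 6)
  expect_setequal(clusterIds(res$kept), c("c1", "c3", "c5"))
  rej <- attr(res$report, "rejections")
  expect_equal(unname(rej["taxa"]), 1)   # c4
  expect_equal(unname(rej["copies"]), 1) # c2
  expect_equal(unname(rej["size"]), 1)   # c2 (fails two predicates)

  # single-predicate rejections
  twoTaxa <- toyClusters(list(x = c("A|1", "B|2")),
                         taxa = c("A", "B", "C", "D"))
  expect_equal(nClusters(filterClusters(twoTaxa, 3, 3, 6)$kept), 0)
  fourCopies <- toyClusters(
    list(x = c("A|1", "A|2", "A|3", "A|4", "B|5", "C|6")),
    taxa = c("A", "B", "C", "D"))
  expect_equal(nClusters(filterClusters(fourCopies, 3, 3, 6)$kept), 0)

  # idempotence
  again <- filterClusters(res$kept, 3, 3, 6)
  expect_identical(again$kept@members, res$kept@members)

  expect_error(filterClusters(cs, 10, 3, 6), "minTaxa")
})

test_that("pan-ortholog selection equals one-copy-everywhere filtering", {
  cs <- toyClusters(list(
    pan = c("A|1", "B|1", "C|1", "D|1"),
    missing = c("A|2", "B|2", "C|2"),
    dup = c("A|3", "A|4", "B|3", "C|3", "D|2")),
    taxa = c("A", "B", "C", "D"))
  pan <- findPanOrthologs(cs)
  expect_equal(clusterIds(pan), "pan")

  # agreement with filterClusters at (|taxa|, 1, |taxa|)
  n <- length(clusterTaxa(cs))
  viaFilter <- filterClusters(cs, n, 1, n)$kept
  expect_identical(pan@members, viaFilter@members)

  simCs <- simulateDataset(simulationConfig(nTaxa = 5, rootGeneCount = 60,
                                            seed = 23))@clusters
  n <- length(clusterTaxa(simCs))
  expect_identical(findPanOrthologs(simCs)@members,
                   filterClusters(simCs, n, 1, n)$kept@members)
})

test_that("paralog resolution implements the four curation rules", {
  mem <- function(...) {
    g <- c(...)
    data.frame(genome_id = sub("\\|.*", "", g), gene_id = g,
               stringsAsFactors = FALSE)
  }
  # rule 1: sister paralogs -> shortest branch retained
  tr1 <- ape::read.tree(
    text = "((a|1:0.1,a|2:0.3):0.2,(b|1:0.1,c|1:0.1):0.2);")
  r1 <- resolveParalogs(mem("a|1", "a|2", "b|1", "c|1"), tr1,
                        ingroup = c("a", "b", "c"))
  expect_equal(r1$decisions$action, "keep_shortest_branch")
  expect_equal(r1$decisions$genes, "a|2")
  expect_setequal(r1$cluster$gene_id, c("a|1", "b|1", "c|1"))
  expect_false(r1$removed)

  # rule 2: ingroup copy inside the outgroup clade is removed
  tr2 <- ape::read.tree(
    text = "((a|1:0.1,b|1:0.1):0.2,(o1|1:0.1,(o2|1:0.1,a|2:0.1):0.1):0.2);")
  r2 <- resolveParalogs(mem("a|1", "a|2", "b|1", "o1|1", "o2|1"), tr2,
                        ingroup = c("a", "b"), outgroup = c("o1", "o2"))
  expect_true("remove_outgroup_copy" %in% r2$decisions$action)
  expect_equal(
    r2$decisions$genes[r2$decisions$action == "remove_outgroup_copy"],
    "a|2")
  expect_false("a|2" %in% r2$cluster$gene_id)
  expect_true("a|1" %in% r2$cluster$gene_id)

  # rule 3: paralogs at different ingroup positions -> whole cluster out
  tr3 <- ape::read.tree(
    text = "((a|1:0.1,b|1:0.1):0.2,(a|2:0.1,c|1:0.1):0.2);")
  r3 <- resolveParalogs(mem("a|1", "a|2", "b|1", "c|1"), tr3,
                        ingroup = c("a", "b", "c"))
  expect_equal(r3$decisions$action, "remove_cluster")
  expect_true(r3$removed)
  expect_equal(nrow(r3$cluster), 0)

  # rule 4: outgroup species copies at different positions -> all removed
  tr4 <- ape::read.tree(text = paste0(
    "((a|1:0.1,b|1:0.1):0.2,",
    "((o1|1:0.1,o2|1:0.1):0.1,(o1|2:0.1,o3|1:0.1):0.1):0.2);"))
  r4 <- resolveParalogs(mem("a|1", "b|1", "o1|1", "o1|2", "o2|1", "o3|1"),
                        tr4, ingroup = c("a", "b"),
                        outgroup = c("o1", "o2", "o3"))
  expect_true("remove_all_copies" %in% r4$decisions$action)
  expect_false(any(c("o1|1", "o1|2") %in% r4$cluster$gene_id))

  # ties keep the lexicographically smallest gene id
  trTie <- ape::read.tree(
    text = "((a|2:0.1,a|1:0.1):0.2,(b|1:0.1,c|1:0.1):0.2);")
  rt <- resolveParalogs(mem("a|1", "a|2", "b|1", "c|1"), trTie,
                        ingroup = c("a", "b", "c"))
  expect_true("a|1" %in% rt$cluster$gene_id)

  # leaf mismatch errors
  expect_error(resolveParalogs(mem("a|1", "b|1"), tr1,
                               ingroup = c("a", "b", "c")),
               "mismatch")
})

test_that("resolution keeps exactly one copy when duplications are terminal", {
  # gene trees mimicking a terminal-branch duplication in one genome:
  # the species tree with the duplicated tip replaced by a cherry
  set.seed(33)
  for (rep in 1:10) {
    bl <- round(stats::runif(2, 0.01, 0.5), 3)
    txt <- sprintf(
      "(((x|1:%g,x|2:%g):0.45,y|1:0.5):0.3,(z|1:0.4,w|1:0.4):0.4);",
      bl[1], bl[2])
    tr <- ape::read.tree(text = txt)
    mem <- data.frame(
      genome_id = c("x", "x", "y", "z", "w"),
      gene_id = c("x|1", "x|2", "y|1", "z|1", "w|1"),
      stringsAsFactors = FALSE)
    r <- resolveParalogs(mem, tr, ingroup = c("x", "y", "z", "w"))
    expect_false(r$removed)
    expect_equal(max(table(r$cluster$genome_id)), 1)
    want <- if (bl[1] < bl[2]) "x|1" else if (bl[2] < bl[1]) "x|2" else "x|1"
    expect_true(want %in% r$cluster$gene_id)
  }
})

test_that("discordance flags strongly supported conflicting bipartitions only", {
  sp <- ape::read.tree(text = "((a:1,b:1):1,((c:1,d:1):1,(e:1,f:1):1):1);")
  same <- ape::read.tree(
    text = "((a:1,b:1)100:1,((c:1,d:1)100:1,(e:1,f:1)100:1)100:1);")
  expect_equal(discordanceFlag(same, sp), "concordant")

  conflict <- ape::read.tree(
    text = "((a:1,c:1)95:1,((b:1,d:1)90:1,(e:1,f:1)88:1)70:1);")
  expect_equal(discordanceFlag(conflict, sp), "discordant")

  weak <- ape::read.tree(
    text = "((a:1,c:1)50:1,((b:1,d:1)50:1,(e:1,f:1)50:1)50:1);")
  expect_equal(discordanceFlag(weak, sp, supportThreshold = 0.9),
               "concordant")

  # brute-force check of the incompatibility call: no 6-leaf tree can
  # display both {a,c} and the species split {a,b}
  skip_if_not_installed("phangorn")
  tips <- sp$tip.label
  hasSplit <- function(tree, side) {
    CladeCompare:::.isUnrootedClade(tree, sort(side))
  }
  all6 <- phangorn::allTrees(6, tip.label = tips, rooted = FALSE)
  both <- vapply(all6, function(tt)
    hasSplit(tt, c("a", "c")) && hasSplit(tt, c("a", "b")), logical(1))
  expect_false(any(both))
})

test_that("reciprocal-best-hit clustering recovers simulated orthology", {
  # zero divergence: clusters equal the ground truth exactly
  cfg <- simulationConfig(nTaxa = 4, rootGeneCount = 30, gainRate = 0,
                          lossRate = 0, dupRate = 0, substRate = 0,
                          inversionRate = 0, translocationRate = 0,
                          seed = 27)
  sim <- simulateDataset(cfg)
  rb <- rbhCluster(sim@proteomes)
  truthSets <- split(sim@clusters@members$gene_id,
                     sim@clusters@members$cluster_id)
  rbSets <- split(rb@members$gene_id, rb@members$cluster_id)
  canon <- function(x) sort(unname(vapply(x, function(s)
    paste(sort(s), collapse = ","), "")))
  expect_identical(canon(rbSets), canon(truthSets))

  # moderate divergence: at least 95% of single-copy clusters recovered
  cfg2 <- simulationConfig(nTaxa = 8, rootGeneCount = 80, substRate = 0.3,
                           gainRate = 0.03, lossRate = 0.05,
                           dupRate = 0.01, seed = 21)
  sim2 <- simulateDataset(cfg2)
  rb2 <- rbhCluster(sim2@proteomes)
  cc <- copyCounts(sim2@clusters)
  single <- rownames(cc)[apply(cc, 1, function(r) all(r == 1))]
  m <- sim2@clusters@members
  rbOf <- stats::setNames(rb2@members$cluster_id, rb2@members$gene_id)
  rbSets2 <- split(rb2@members$gene_id, rb2@members$cluster_id)
  recovered <- vapply(single, function(cid) {
    genes <- m$gene_id[m$cluster_id == cid]
    rcl <- unique(rbOf[genes])
    length(rcl) == 1 && setequal(rbSets2[[rcl]], genes)
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
})
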