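test_that("normalized bit scores use the min-self denominator and clip", {
  expect_equal(normalizedBitscore(50, 200, 100), 0.5)
  expect_equal(normalizedBitscore(100, 100, 150), 1.0)  # identical seqs
  expect_equal(normalizedBitscore(180, 100, 150), 1.0)  # clipped high
  expect_equal(normalizedBitscore(-5, 100, 150), 0.0)   # clipped low
  expect_equal(pairIdentity(data.frame(bitscore_ab = c(40, 90),
                                       selfscore_a = c(100, 150),
                                       selfscore_b = c(120, 160))),
               mean(c(0.4, 0.6)))
})

test_that("synteny fraction matches the printed toy permutations", {
  expect_equal(syntenyFraction(paste0("g", 1:6), paste0("g", 1:6)), 1.0)
  expect_equal(syntenyFraction(paste0("g", 1:6), rev(paste0("g", 1:6))),
               1.0)  # adjacency is orientation-free
  expect_equal(syntenyFraction(paste0("g", 1:6),
                               c("g3", "g1", "g4", "g5", "g2", "g6")),
               2 / 6)
  expect_equal(syntenyFraction(paste0("g", 1:5),
                               c("g1", "g3", "g5", "g2", "g4")), 0.0)
  expect_error(syntenyFraction(paste0("a", 1:3), paste0("b", 1:3)),
               "no shared genes")
})

test_that("one inversion of an internal segment breaks two adjacencies", {
  ord <- paste0("g", 1:10)
  inv <- ord
  inv[3:6] <- rev(inv[3:6])
  adjPairs <- function(o) {
    apply(cbind(o[-length(o)], o[-1]), 1, function(p)
      paste(sort(p), collapse = "-"))
  }
  broken <- setdiff(adjPairs(ord), adjPairs(inv))
  expect_length(broken, 2)
  # with orientation-free single-side adjacency every gene still keeps
  # one neighbour, so the synteny fraction itself stays 1
  expect_equal(syntenyFraction(ord, inv), 1.0)
})

test_that("synteny fraction equals the brute-force adjacency oracle", {
  set.seed(55)
  for (rep in 1:120) {
    n <- sample(c(4:30, 200), 1)
    ord <- paste0("g", seq_len(n))
    perm <- sample(ord)
    circA <- sample(c(TRUE, FALSE), 1)
    circB <- sample(c(TRUE, FALSE), 1)
    got <- syntenyFraction(ord, perm, circularA = circA, circularB = circB)
    expect_equal(got, oracleSynteny(ord, perm, circA, circB))
    # symmetry
    expect_equal(got, syntenyFraction(perm, ord, circularA = circB,
                                      circularB = circA))
  }
  # partial overlap with an explicit ortholog map
  for (rep in 1:30) {
    ordA <- paste0("a", 1:20)
    ordB <- paste0("b", 1:20)
    shared <- sort(sample(1:20, sample(5:15, 1)))
    pairs <- data.frame(gene_a = paste0("a", shared),
                        gene_b = paste0("b", shared))
    permB <- sample(ordB)
    got <- syntenyFraction(ordA, permB, pairs = pairs)
    aliasB <- stats::setNames(pairs$gene_a, pairs$gene_b)
    permBMapped <- ifelse(permB %in% pairs$gene_b, aliasB[permB], permB)
    expect_equal(got, oracleSynteny(ordA[shared], permBMapped[
      permBMapped %in% pairs$gene_a]))
  }
})

test_that("random-permutation synteny agrees with the permutation oracle", {
  set.seed(66)
  n <- 50
  ord <- paste0("g", seq_len(n))
  oracleVals <- replicate(1000, oracleSynteny(ord, sample(ord)))
  implVals <- replicate(300, syntenyFraction(ord, sample(ord)))
  se <- sqrt(stats::var(oracleVals) / 1000 + stats::var(implVals) / 300)
  expect_lt(abs(mean(implVals) - mean(oracleVals)), 3 * se)
  # small and decreasing in n
  big <- replicate(200, oracleSynteny(paste0("g", 1:150),
                                      sample(paste0("g", 1:150))))
  expect_lt(mean(big), mean(oracleVals))
})

test_that("median synteny degrades monotonically with inversion count", {
  set.seed(31)
  ks <- 0:20
  med <- vapply(ks, function(k) {
    stats::median(replicate(50, {
      ord <- paste0("g", 1:200)
      cur <- ord
      for (i in seq_len(k)) {
        ij <- sort(sample.int(200, 2))
        cur[ij[1]:ij[2]] <- rev(cur[ij[1]:ij[2]])
      }
      syntenyFraction(ord, cur)
    }))
  }, numeric(1))
  expect_lt(stats::cor(ks, med, method = "spearman"), -0.9)
})

test_that("pair classification picks the most specific stratum", {
  tax <- data.frame(genome_id = c("w", "x", "y", "z"),
                    genus = c("G1", "G1", "G2", "G3"),
                    family = c("F1", "F1", "F1", "F2"),
                    order = c("O1", "O1", "O1", "O1"),
                    stringsAsFactors = FALSE)
  expect_equal(classifyPair("w", "x", tax), "within_genus")
  expect_equal(classifyPair("w", "y", tax), "within_family")
  expect_equal(classifyPair("w", "z", tax), "within_order")
  tax$order[4] <- "O2"
  expect_equal(classifyPair("w", "z", tax), "between_orders")
  expect_error(classifyPair("w", "nope", tax), "missing")
})

test_that("pair scans emit one record per genome pair with sound values", {
  cfg <- simulationConfig(nTaxa = 6, rootGeneCount = 40, substRate = 0.2,
                          seed = 61)
  sim <- simulateDataset(cfg)
  recs <- pairScan(sim@annotations, sim@proteomes, sim@clusters,
                   sim@taxonomy, scoreMethod = "kmer")
  expect_equal(nrow(recs), choose(6, 2))
  expect_true(all(recs$avg_norm_bitscore >= 0 & recs$avg_norm_bitscore <= 1))
  expect_true(all(recs$synteny_fraction >= 0 & recs$synteny_fraction <= 1))
  expect_true(all(recs$category %in% c("within_genus", "within_family",
                                       "within_order", "between_orders")))
  # within-clade pairs show higher synteny than the most distant pairs
  d <- stats::cophenetic(sim@tree)
  pathLen <- mapply(function(a, b) d[a, b], recs$genome_a, recs$genome_b)
  close <- recs$synteny_fraction[pathLen < stats::median(pathLen)]
  far <- recs$synteny_fraction[pathLen >= stats::median(pathLen)]
  expect_gt(mean(close), mean(far))
})

test_that("outlier flagging finds a planted extreme pair and nothing else", {
  # evenly spread base points cannot be Tukey outliers themselves
  base <- data.frame(
    genome_a = paste0("g", 1:20), genome_b = paste0("h", 1:20),
    category = "within_order", n_shared = 100,
    avg_norm_bitscore = seq(0.45, 0.55, length.out = 20),
    synteny_fraction = seq(0.55, 0.65, length.out = 20),
    stringsAsFactors = FALSE)
  planted <- data.frame(genome_a = "odd", genome_b = "pair",
                        category = "within_order", n_shared = 100,
                        avg_norm_bitscore = 0.5, synteny_fraction = 0.95,
                        stringsAsFactors = FALSE)
  flagged <- flagOutliers(rbind(base, planted))
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$genome_a, "odd")
  expect_equal(flagged$outlier_axis, "synteny")

  # all-identical records: degenerate fences flag nothing
  same <- base
  same$avg_norm_bitscore <- 0.5
  same$synteny_fraction <- 0.6
  expect_equal(nrow(flagOutliers(same)), 0)
  # empty input
  expect_equal(nrow(flagOutliers(base[0, ])), 0)
})

test_that("the rogue lineage's synteny to the focal clade is not elevated", {
  rp <- rogueLineagePreset(seed = 101)
  sim <- rp$sim
  recs <- pairScan(sim@annotations, sim@proteomes, sim@clusters,
                   sim@taxonomy, scoreMethod = "kmer")
  rogueRecs <- recs[recs$genome_a == rp$rogue | recs$genome_b == rp$rogue, ]
  other <- ifelse(rogueRecs$genome_a == rp$rogue, rogueRecs$genome_b,
                  rogueRecs$genome_a)
  toClade <- rogueRecs$synteny_fraction[other %in% rp$focalClade]
  toBackground <- rogueRecs$synteny_fraction[!other %in% rp$focalClade]
  p <- stats::wilcox.test(toClade, toBackground,
                          alternative = "greater", exact = FALSE)$p.value
  expect_gt(p, 0.05)
})
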