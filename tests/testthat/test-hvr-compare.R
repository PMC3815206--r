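test_that("regions between anchor features use boundary coordinates", {
  ann <- toyAnnotation("gA", data.frame(
    gene_id = c("gA|t1", "gA|x", "gA|t2"),
    start0 = c(9900, 12000, 15000),
    end0 = c(10000, 12500, 15080),
    feature_type = c("tRNA", "CDS", "tRNA"),
    product = c("tRNA-Ser", "something", "tRNA-Ala")),
    repliconLength = 60000)
  reg <- locateBetweenFeatures(ann, "tRNA-Ser", "tRNA-Ala")
  expect_equal(reg@start0, 10000)
  expect_equal(reg@end0, 15000)
  expect_equal(reg@anchors, c("gA|t1", "gA|t2"))

  # ambiguity lists candidates
  ann2 <- toyAnnotation("gA", data.frame(
    gene_id = c("gA|t1", "gA|t1b", "gA|t2"),
    start0 = c(100, 500, 900), end0 = c(180, 580, 980),
    feature_type = "tRNA",
    product = c("tRNA-Ser", "tRNA-Ser", "tRNA-Ala")))
  expect_error(locateBetweenFeatures(ann2, "tRNA-Ser", "tRNA-Ala"),
               "ambiguous.*gA\\|t1")
  expect_error(locateBetweenFeatures(ann, "tRNA-Leu", "tRNA-Ala"),
               "no feature")

  # different replicons
  grA <- geneRanges(ann)
  g3 <- GenomicRanges::GRanges("chr2",
                               IRanges::IRanges(start = 1, end = 80),
                               strand = "+")
  S4Vectors::mcols(g3)$gene_id <- "gA|t9"
  S4Vectors::mcols(g3)$feature_type <- "tRNA"
  S4Vectors::mcols(g3)$product <- "tRNA-Gly"
  ann3 <- GenomeAnnotation("gA", suppressWarnings(c(grA, g3)))
  expect_error(locateBetweenFeatures(ann3, "tRNA-Ser", "tRNA-Gly"),
               "different replicons")

  # left anchor downstream of the right one
  expect_error(locateBetweenFeatures(ann, "tRNA-Ala", "tRNA-Ser"),
               "upstream")
})

test_that("region expansion clamps on linear and wraps on circular replicons", {
  reg <- Region("gA", "chr", 10000, 15000, repliconLength = 60000)
  ex <- expandRegion(reg, 20000)
  expect_equal(c(ex@start0, ex@end0), c(0, 35000))

  expect_equal(c(expandRegion(reg, 0)@start0, expandRegion(reg, 0)@end0),
               c(10000, 15000))

  # expansion covering a circular replicon collapses to the full replicon
  regC <- Region("gA", "chr", 1000, 2000, repliconLength = 6000,
                 circular = TRUE)
  full <- expandRegion(regC, 5000)
  expect_equal(c(full@start0, full@end0), c(0, 6000))

  # a modest circular expansion wraps the origin: (100,200) +/- 300 on a
  # 1000 bp circle spans 700 bp, re-linearised as [800, 1500) ==
  # 800..1000 plus 0..500
  regW <- expandRegion(Region("gA", "chr", 100, 200,
                              repliconLength = 1000, circular = TRUE), 300)
  expect_true(regW@wrapped)
  expect_equal(c(regW@start0, regW@end0), c(800, 1500))
  seqs <- Biostrings::DNAStringSet(c(chr = paste(
    rep(c("A", "C", "G", "T"), 250), collapse = "")))
  s <- regionSequence(regW, seqs)
  expect_equal(length(s), 700)
  expect_identical(as.character(s),
                   paste0(substr(as.character(seqs[[1]]), 801, 1000),
                          substr(as.character(seqs[[1]]), 1, 500)))
})

test_that("translated self-comparison yields a full-length forward hit", {
  set.seed(91)
  dna <- randomDna(3000)
  hits <- translatedSearch(dna, dna)
  fwd <- hits[hits$qframe == 1 & hits$sframe == 1, ]
  expect_gte(nrow(fwd), 1)
  expect_equal(fwd$length_aa[1], 1000)        # full-length
  expect_equal(fwd$pct_id[1], 100)
  expect_equal(c(fwd$qstart0[1], fwd$qend0[1]), c(0, 3000))
  expect_lt(fwd$evalue[1], 1e-100)

  # reverse complement: same top score in a (+1,-1)-family frame pair
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(dna)))
  hits2 <- translatedSearch(dna, rc)
  expect_equal(max(hits2$score), max(hits$score))
  top2 <- hits2[which.max(hits2$score), ]
  expect_equal(top2$qframe, -top2$sframe)
})

test_that("search results are symmetric in query and subject", {
  set.seed(92)
  insert <- randomDna(600)
  a <- paste0(randomDna(300), insert, randomDna(300))
  b <- paste0(randomDna(250), mutateDna(insert, 0.05), randomDna(350))
  ab <- translatedSearch(a, b)
  ba <- translatedSearch(b, a)
  expect_identical(sort(ab$score), sort(ba$score))
  expect_identical(sort(ab$evalue), sort(ba$evalue))
})

test_that("independent random regions give no hits below E<1e-10", {
  set.seed(93)
  r1 <- randomDna(5000)
  r2 <- randomDna(5000)
  hits <- translatedSearch(r1, r2)
  expect_equal(nrow(hits), 0)
  # consistent with the Poisson expectation: at E < 1e-10 the expected
  # number of chance hits over the whole search is ~1e-10
  relaxed <- translatedSearch(r1, r2,
                              translatedSearchParams(evalueMax = 10))
  if (nrow(relaxed) > 0) expect_gt(min(relaxed$evalue), 1e-10)
  expect_error(translatedSearch("ACGTAC", r2), "shorter")
})

test_that("E-values decrease monotonically in score at fixed search space", {
  set.seed(94)
  insert <- randomDna(900)
  a <- paste0(randomDna(200), insert, randomDna(200))
  b <- paste0(randomDna(300), mutateDna(insert, 0.1), randomDna(100))
  hits <- translatedSearch(a, b, translatedSearchParams(evalueMax = 1))
  expect_gt(nrow(hits), 1)
  o <- order(hits$score)
  expect_true(all(diff(hits$evalue[o]) <= 0))
})

test_that("a resampled region shows no similarity to a homologous pair", {
  set.seed(95)
  insert <- randomDna(2000)
  r1 <- paste0(randomDna(1000), insert, randomDna(1000))
  r2 <- paste0(randomDna(900), mutateDna(insert, 0.05), randomDna(1100))
  r3 <- randomDna(4000)  # resampled: same length, no homology
  d <- withr::local_tempdir()
  res <- regionComparisonMatrix(list(s1 = r1, s2 = r2, s3 = r3),
                                outdir = d)
  expect_named(res, c("s1_vs_s2", "s2_vs_s3"))
  expect_gt(nrow(res$s1_vs_s2), 0)
  expect_equal(nrow(res$s2_vs_s3), 0)
  # crunch files: hits for the homologous pair, empty-but-valid otherwise
  files <- attr(res, "files")
  expect_true(all(file.exists(files)))
  l12 <- readLines(files["s1_vs_s2"])
  expect_gt(length(l12), 0)
  expect_match(l12[1], "^\\d+ \\d+ \\d+ \\d+ \\d+ [0-9.]+$")
  expect_length(readLines(files["s2_vs_s3"]), 0)
})
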