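# Shared fixture builders and independent oracles. Everything is built in
# code; no fixture files.

# A GenomeAnnotation from a compact spec: data.frame(gene_id, start0, end0,
# strand, feature_type, product), one replicon.
toyAnnotation <- function(genome, genes, replicon = "chr",
                          repliconLength = NA, circular = FALSE) {
  gr <- GenomicRanges::GRanges(
    seqnames = replicon,
    ranges = IRanges::IRanges(start = genes$start0 + 1L, end = genes$end0),
    strand = if (is.null(genes$strand)) "+" else genes$strand)
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id
  S4Vectors::mcols(gr)$feature_type <-
    if (is.null(genes$feature_type)) "CDS" else genes$feature_type
  S4Vectors::mcols(gr)$product <-
    if (is.null(genes$product)) "" else genes$product
  rl <- if (is.na(repliconLength)) NULL
        else stats::setNames(repliconLength, replicon)
  GenomeAnnotation(genome, gr, repliconLengths = rl,
                   circular = stats::setNames(circular, replicon))
}

# ClusterSet from a named list cluster_id -> character vector of
# "genome|gene" tokens.
toyClusters <- function(lst, taxa = NULL) {
  rows <- do.call(rbind, lapply(names(lst), function(cid) {
    data.frame(cluster_id = cid,
               genome_id = sub("\\|.*$", "", lst[[cid]]),
               gene_id = lst[[cid]], stringsAsFactors = FALSE)
  }))
  ClusterSet(rows, taxa = taxa)
}

# Brute-force O(n^2) adjacency-set oracle for the synteny fraction,
# independent of the package implementation.
oracleSynteny <- function(orderA, orderB, circularA = FALSE,
                          circularB = FALSE) {
  shared <- intersect(orderA, orderB)
  ra <- orderA[orderA %in% shared]
  rb <- orderB[orderB %in% shared]
  adj <- function(ord, circ) {
    n <- length(ord)
    out <- list()
    for (i in seq_len(n)) {
      nb <- character(0)
      for (j in seq_len(n)) {
        d <- abs(i - j)
        if (d == 1 || (circ && n > 2 && d == n - 1)) nb <- c(nb, ord[j])
        if (circ && n == 2 && d == 1) nb <- c(nb, ord[j])
      }
      out[[ord[i]]] <- unique(nb)
    }
    out
  }
  A <- adj(ra, circularA)
  B <- adj(rb, circularB)
  mean(vapply(ra, function(g)
    length(intersect(A[[g]], B[[g]])) > 0, logical(1)))
}

# Brute-force set-arithmetic oracle for gene-content similarity.
oracleContent <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  shared <- 0
  for (x in a) if (x %in% b) shared <- shared + 1
  shared / min(length(a), length(b))
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

mutateDna <- function(seq, p) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- which(stats::runif(length(ch)) < p)
  ch[idx] <- sample(c("A", "C", "G", "T"), length(idx), TRUE)
  paste(ch, collapse = "")
}

# the 5-cluster filtering toy (4-genome universe A-D):
# taxa counts 4,4,3,2,4; max copies 1,4,1,1,2; sizes 4,7,3,2,5
filterToy <- function() {
  toyClusters(list(
    c1 = c("A|a1", "B|b1", "C|c1", "D|d1"),
    c2 = c("A|a2", "A|a3", "A|a4", "A|a5", "B|b2", "C|c2", "D|d2"),
    c3 = c("A|a6", "B|b3", "C|c3"),
    c4 = c("A|a7", "B|b4"),
    c5 = c("A|a8", "A|a9", "B|b5", "C|c4", "D|d3")),
    taxa = c("A", "B", "C", "D"))
}
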