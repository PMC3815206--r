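#' aminoGC: GC-rich amino-acid fraction of protein sequences
#'
#' Computes, per sequence, the fraction of residues belonging to the amino
#' acids encoded by codon families with G or C in both of the first two
#' codon positions: glycine (GGN), alanine (GCN), arginine (CGN) and
#' proline (CCN). Low values are the protein-level signature of AT
#' mutational bias. Gaps, stops and ambiguity codes (B, Z, X, J, U, O) are
#' excluded from both numerator and denominator so alignment columns with
#' missing data do not dilute the statistic.
#'
#' Arginine also has AGR codons; set `gcSet = c("G", "A", "P")` to compute
#' the variant that excludes it.
#'
#' @param x character vector, `AAString` or `AAStringSet` of protein
#'   sequences (may contain alignment gaps).
#' @param gcSet residues counted as GC-rich (default G, A, R, P).
#' @return numeric vector of values in [0, 1], named like `x`.
#' @export
aminoGC <- function(x, gcSet = AA_GC_SET) {
  if (methods::is(x, "XString")) x <- as.character(x)
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  ccAssert(is.character(x) && length(x) > 0, "need at least one sequence")
  counted <- setdiff(AA_STANDARD, character(0))
  vals <- vapply(x, function(s) {
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    ch <- ch[ch %in% counted]
    if (length(ch) == 0)
      ccStop("sequence empty after removing gaps and ambiguity codes")
    sum(ch %in% gcSet) / length(ch)
  }, numeric(1), USE.NAMES = FALSE)
  names(vals) <- names(x)
  vals
}

#' Count residues entering the aminoGC statistic
#' @noRd
.aminoGCCounts <- function(s, gcSet = AA_GC_SET) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  ch <- ch[ch %in% AA_STANDARD]
  c(gc = sum(ch %in% gcSet), n = length(ch))
}

#' Per-gene aminoGC over a set of gene alignments
#'
#' For each gene, pools the residues of all taxa in that gene's alignment
#' into a single aminoGC value, and summarises the resulting per-gene
#' distribution with Tukey box-plot statistics (the numbers a box plot of
#' the gene set draws).
#'
#' @param alignments named list of `AAStringSet` (or character vector)
#'   alignments, one per gene.
#' @param gcSet see [aminoGC()].
#' @return list with `perGene` (data.frame: gene, n_residues, amino_gc) and
#'   `boxStats` (lower whisker, lower hinge, median, upper hinge, upper
#'   whisker over the per-gene values).
#' @export
alignmentAminoGC <- function(alignments, gcSet = AA_GC_SET) {
  ccAssert(length(alignments) > 0, "no alignments supplied")
  ccAssert(!is.null(names(alignments)) && all(nzchar(names(alignments))),
           "alignments must be named by gene")
  rows <- lapply(names(alignments), function(g) {
    aln <- alignments[[g]]
    if (methods::is(aln, "XStringSet")) aln <- as.character(aln)
    cnt <- colSums(do.call(rbind, lapply(aln, .aminoGCCounts, gcSet = gcSet)))
    ccAssert(cnt["n"] > 0,
             paste0("gene ", g, " has no countable residues"))
    data.frame(gene = g, n_residues = unname(cnt["n"]),
               amino_gc = unname(cnt["gc"] / cnt["n"]),
               stringsAsFactors = FALSE)
  })
  perGene <- do.call(rbind, rows)
  bs <- grDevices::boxplot.stats(perGene$amino_gc)$stats
  names(bs) <- c("whisker_low", "hinge_low", "median", "hinge_high",
                 "whisker_high")
  list(perGene = perGene, boxStats = bs)
}

#' Nucleotide G+C content
#'
#' @param x character vector, `DNAString` or `DNAStringSet`.
#' @return fraction of unambiguous bases that are G or C.
#' @export
gcContent <- function(x) {
  if (methods::is(x, "XString")) x <- as.character(x)
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  vals <- vapply(x, function(s) {
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    ch <- ch[ch %in% c("A", "C", "G", "T")]
    ccAssert(length(ch) > 0, "sequence has no unambiguous bases")
    sum(ch %in% c("G", "C")) / length(ch)
  }, numeric(1), USE.NAMES = FALSE)
  names(vals) <- names(x)
  vals
}
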