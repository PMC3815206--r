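#' Locate the interval between two anchoring features
#'
#' Finds exactly one feature matching each query (case-insensitive
#' substring of the product description or feature type — e.g.
#' `"tRNA-Ser"`, `"23S"`) and returns the region between them: from the
#' end of the left feature to the start of the right one, with no flanks.
#' Zero or multiple matches, features on different replicons, or a left
#' feature not upstream of the right one are errors. This expresses both
#' anchoring styles used for hypervariable region 2 — between the 23S and
#' 5S rRNA genes, or between a tRNA-Ser and a tRNA-Ala — with no
#' special-case code.
#'
#' @param annotation a [GenomeAnnotation].
#' @param leftQuery,rightQuery feature text queries.
#' @return a [Region] (0-based half-open coordinates).
#' @export
locateBetweenFeatures <- function(annotation, leftQuery, rightQuery) {
  g <- geneRanges(annotation)
  txt <- paste(S4Vectors::mcols(g)$product, S4Vectors::mcols(g)$feature_type)
  findOne <- function(q) {
    hit <- which(textMatches(q, txt))
    if (length(hit) == 0)
      ccStop(paste0("no feature matching '", q, "' in genome ",
                    genomeId(annotation)))
    if (length(hit) > 1)
      ccStop(paste0("query '", q, "' is ambiguous; candidates: ",
                    paste(S4Vectors::mcols(g)$gene_id[hit], collapse = ", ")))
    hit
  }
  li <- findOne(leftQuery)
  ri <- findOne(rightQuery)
  lrep <- as.character(GenomeInfoDb::seqnames(g))[li]
  rrep <- as.character(GenomeInfoDb::seqnames(g))[ri]
  ccAssert(lrep == rrep,
           paste0("anchor features lie on different replicons (", lrep,
                  " vs ", rrep, ")"))
  start0 <- BiocGenerics::end(g)[li]        # 1-based end == 0-based exclusive
  end0 <- BiocGenerics::start(g)[ri] - 1L   # 1-based start - 1 == 0-based
  ccAssert(start0 < end0,
           "left anchor is not upstream of the right anchor")
  circ <- GenomeInfoDb::isCircular(g)[lrep]
  Region(genomeId(annotation), lrep, start0, end0,
         anchors = c(S4Vectors::mcols(g)$gene_id[li],
                     S4Vectors::mcols(g)$gene_id[ri]),
         repliconLength = unname(GenomeInfoDb::seqlengths(g)[lrep]),
         circular = isTRUE(circ))
}

#' Expand a region by a flank on each side
#'
#' Adds `flankBp` to each side. On linear replicons the result is clamped
#' to the replicon; on circular replicons it wraps the origin (the region
#' is re-linearised with `end0 > repliconLength` and flagged `wrapped`),
#' and collapses to the full replicon when the expansion covers it.
#'
#' @param region a [Region].
#' @param flankBp basepairs to add on each side.
#' @param repliconLength override for the replicon length (else taken from
#'   the region).
#' @param circular override for circularity (else taken from the region).
#' @return a [Region].
#' @export
expandRegion <- function(region, flankBp, repliconLength = NULL,
                         circular = NULL) {
  L <- if (is.null(repliconLength)) region@repliconLength
       else as.numeric(repliconLength)
  circ <- if (is.null(circular)) region@circular else circular
  s <- region@start0 - flankBp
  e <- region@end0 + flankBp
  if (!circ) {
    s <- max(0, s)
    if (!is.na(L)) e <- min(L, e)
    return(Region(region@genomeId, region@repliconId, s, e,
                  anchors = region@anchors, flankBp = flankBp,
                  repliconLength = L, circular = FALSE))
  }
  ccAssert(!is.na(L), "circular expansion requires the replicon length")
  if (e - s >= L)
    return(Region(region@genomeId, region@repliconId, 0, L,
                  anchors = c(region@anchors, "full replicon (wrapped)"),
                  flankBp = flankBp, repliconLength = L, circular = TRUE))
  s2 <- s %% L
  Region(region@genomeId, region@repliconId, s2, s2 + (e - s),
         anchors = region@anchors, flankBp = flankBp,
         repliconLength = L, circular = TRUE,
         wrapped = s2 + (e - s) > L)
}

#' Extract a region's nucleotide sequence
#'
#' @param region a [Region].
#' @param sequences named `DNAStringSet` (or character) of replicon
#'   sequences for the region's genome.
#' @return a `DNAString` (wrapped regions are stitched across the origin).
#' @export
regionSequence <- function(region, sequences) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  ccAssert(region@repliconId %in% names(sequences),
           paste0("replicon ", region@repliconId, " not in sequences"))
  s <- sequences[[region@repliconId]]
  L <- length(s)
  from <- region@start0 + 1
  to <- region@end0
  if (!region@wrapped) {
    ccAssert(to <= L, "region exceeds replicon sequence")
    return(Biostrings::subseq(s, from, to))
  }
  Biostrings::xscat(Biostrings::subseq(s, from, L),
                    Biostrings::subseq(s, 1, to - L))
}
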