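#' Shared single-copy ortholog pairs of two genomes
#'
#' Returns the gene pairs of clusters in which both genomes have exactly
#' one copy — the "shared genes" a pair comparison is computed over when
#' orthology comes from a cluster file rather than reciprocal best hits.
#'
#' @param clusterSet a [ClusterSet].
#' @param genomeA,genomeB genome ids.
#' @return data.frame with columns `cluster_id`, `gene_a`, `gene_b`.
#' @export
sharedSingleCopyPairs <- function(clusterSet, genomeA, genomeB) {
  m <- clusterSet@members
  ma <- m[m$genome_id == genomeA, ]
  mb <- m[m$genome_id == genomeB, ]
  one <- function(d) {
    cnt <- table(d$cluster_id)
    d[d$cluster_id %in% names(cnt)[cnt == 1], ]
  }
  ma <- one(ma)
  mb <- one(mb)
  shared <- intersect(ma$cluster_id, mb$cluster_id)
  data.frame(cluster_id = shared,
             gene_a = ma$gene_id[match(shared, ma$cluster_id)],
             gene_b = mb$gene_id[match(shared, mb$cluster_id)],
             stringsAsFactors = FALSE)
}

# gene order of a genome over possibly several replicons:
# list(order = list per replicon of gene ids, circular = named logical)
.genomeOrders <- function(annotation, featureType = "CDS") {
  g <- geneRanges(annotation)
  g <- g[S4Vectors::mcols(g)$feature_type %in% featureType]
  reps <- unique(as.character(GenomeInfoDb::seqnames(g)))
  circ <- GenomeInfoDb::isCircular(g)
  ord <- lapply(reps, function(r)
    S4Vectors::mcols(g)$gene_id[as.character(GenomeInfoDb::seqnames(g)) == r])
  names(ord) <- reps
  list(order = ord,
       circular = vapply(reps, function(r) isTRUE(circ[[r]]), TRUE))
}

# synteny over multi-replicon genomes: restrict the pair map per replicon
# combination; a gene's neighbours are those on its own replicon.
.pairSynteny <- function(annA, annB, pairs, side = "either") {
  oa <- .genomeOrders(annA)
  ob <- .genomeOrders(annB)
  fullA <- unlist(oa$order, use.names = FALSE)
  fullB <- unlist(ob$order, use.names = FALSE)
  pairs <- pairs[pairs$gene_a %in% fullA & pairs$gene_b %in% fullB, ]
  ccAssert(nrow(pairs) > 0, "no shared genes between the two genomes")
  b2a <- stats::setNames(pairs$gene_a, pairs$gene_b)
  adjA <- adjB <- list()
  for (r in names(oa$order)) {
    ra <- oa$order[[r]][oa$order[[r]] %in% pairs$gene_a]
    adjA <- c(adjA, .adjacency(ra, oa$circular[[r]]))
  }
  for (r in names(ob$order)) {
    rb <- ob$order[[r]][ob$order[[r]] %in% pairs$gene_b]
    adjB <- c(adjB, .adjacency(unname(b2a[rb]), ob$circular[[r]]))
  }
  synt <- vapply(pairs$gene_a, function(g) {
    na <- adjA[[g]]
    nb <- adjB[[g]]
    if (is.null(na) || length(na) == 0) return(FALSE)
    if (is.null(nb)) nb <- character(0)
    if (side == "either") length(intersect(na, nb)) > 0 else all(na %in% nb)
  }, logical(1))
  sum(synt) / nrow(pairs)
}

#' Pairwise synteny-identity scan over a genome set
#'
#' Computes, for every unordered genome pair, the average normalized bit
#' score of the shared genes, the synteny fraction, the shared-gene count
#' and the taxonomic pair class — one record per dot of a synteny-vs-
#' identity scatter.
#'
#' @param annotations named list of [GenomeAnnotation] (names = genome ids).
#' @param proteomes named list of `AAStringSet`, names matching
#'   `annotations`; sequence names are gene ids.
#' @param clusterSet [ClusterSet] defining orthology (single-copy shared
#'   clusters become the pair map).
#' @param taxonomy taxonomy data.frame (see [readTaxonomy()]); optional —
#'   without it categories are `NA`.
#' @param scoreMethod `"sw"` (Smith-Waterman bit scores; the reference
#'   setting) or `"kmer"` (fast 3-mer scores).
#' @param side synteny neighbour rule, see [syntenyFraction()].
#' @return data.frame with columns `genome_a`, `genome_b`, `category`,
#'   `n_shared`, `avg_norm_bitscore`, `synteny_fraction`.
#' @export
pairScan <- function(annotations, proteomes, clusterSet, taxonomy = NULL,
                     scoreMethod = c("sw", "kmer"), side = "either") {
  scoreMethod <- match.arg(scoreMethod)
  ids <- sort(names(annotations))
  ccAssert(length(ids) >= 2, "need at least two genomes")
  ccAssert(all(ids %in% names(proteomes)), "proteome missing for a genome")
  recs <- list()
  for (i in seq_len(length(ids) - 1)) {
    for (j in seq.int(i + 1, length(ids))) {
      a <- ids[i]; b <- ids[j]
      pairs <- sharedSingleCopyPairs(clusterSet, a, b)
      if (nrow(pairs) == 0) {
        recs[[length(recs) + 1]] <- data.frame(
          genome_a = a, genome_b = b,
          category = if (is.null(taxonomy)) NA_character_
                     else classifyPair(a, b, taxonomy),
          n_shared = 0L, avg_norm_bitscore = NA_real_,
          synteny_fraction = NA_real_, stringsAsFactors = FALSE)
        next
      }
      scored <- .scorePairs(pairs, proteomes[[a]], proteomes[[b]],
                            method = scoreMethod)
      recs[[length(recs) + 1]] <- data.frame(
        genome_a = a, genome_b = b,
        category = if (is.null(taxonomy)) NA_character_
                   else classifyPair(a, b, taxonomy),
        n_shared = nrow(pairs),
        avg_norm_bitscore = pairIdentity(scored),
        synteny_fraction = .pairSynteny(annotations[[a]], annotations[[b]],
                                        pairs, side = side),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, recs)
}

#' Flag robust outlier pairs within each taxonomic category
#'
#' A pair is flagged when its (identity, synteny) point falls outside the
#' category's Tukey fence (1.5 x IQR beyond the quartiles) on either axis.
#' Deterministic; degenerate categories (all points identical) yield no
#' flags.
#'
#' @param records data.frame from [pairScan()].
#' @return the flagged subset, with an `outlier_axis` column.
#' @export
flagOutliers <- function(records) {
  out <- list()
  for (cat in unique(records$category)) {
    d <- records[!is.na(records$category) & records$category == cat &
                   !is.na(records$avg_norm_bitscore) &
                   !is.na(records$synteny_fraction), , drop = FALSE]
    if (nrow(d) == 0) next
    fence <- function(v) {
      q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2] - q[1]
      c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
    }
    fx <- fence(d$avg_norm_bitscore)
    fy <- fence(d$synteny_fraction)
    offx <- d$avg_norm_bitscore < fx[1] | d$avg_norm_bitscore > fx[2]
    offy <- d$synteny_fraction < fy[1] | d$synteny_fraction > fy[2]
    if (!any(offx | offy)) next
    f <- d[offx | offy, , drop = FALSE]
    f$outlier_axis <- ifelse(offx[offx | offy] & offy[offx | offy], "both",
                             ifelse(offx[offx | offy], "identity", "synteny"))
    out[[length(out) + 1]] <- f
  }
  if (length(out) == 0) {
    empty <- records[0, , drop = FALSE]
    empty$outlier_axis <- character(0)
    return(empty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write pair records as TSV
#'
#' @param records data.frame from [pairScan()].
#' @param path output path.
#' @param header optional comment lines (prefixed with `#`).
#' @return `path`, invisibly.
#' @export
writePairRecords <- function(records, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Scatter plot of synteny against identity
#'
#' One point per genome pair, coloured by taxonomic category; pairs
#' involving a focal genome are over-plotted in orange.
#'
#' @param records data.frame from [pairScan()].
#' @param focal optional focal genome id to highlight.
#' @param file optional PNG path; default plots to the active device.
#' @return invisibly, the records plotted.
#' @export
plotPairScan <- function(records, focal = NULL, file = NULL) {
  d <- records[!is.na(records$avg_norm_bitscore) &
                 !is.na(records$synteny_fraction), , drop = FALSE]
  cats <- c("within_genus", "within_family", "within_order", "between_orders")
  cols <- stats::setNames(c("#1b9e77", "#7570b3", "#66a61e", "#666666"), cats)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off())
  }
  plot(d$avg_norm_bitscore, d$synteny_fraction, xlim = c(0, 1),
       ylim = c(0, 1), xlab = "average normalized bit score",
       ylab = "synteny fraction",
       col = cols[d$category], pch = 19, cex = 0.8)
  if (!is.null(focal)) {
    sel <- d$genome_a == focal | d$genome_b == focal
    graphics::points(d$avg_norm_bitscore[sel], d$synteny_fraction[sel],
                     col = "orange", pch = 19, cex = 1.0)
  }
  graphics::legend("bottomright", legend = cats, col = cols[cats],
                   pch = 19, cex = 0.7, bty = "n")
  invisible(d)
}
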