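#' Threshold filtering of ortholog clusters
#'
#' Keeps clusters that (i) cover at least `minTaxa` genomes, (ii) have at
#' most `maxCopiesPerGenome` copies in any one genome and (iii) contain at
#' most `maxGenes` genes in total. The three predicates mirror the curation
#' thresholds commonly applied to orthoMCL output before phylogenomic use
#' (e.g. at least 130 of 135 genomes, at most 3 copies per genome, at most
#' 142 genes).
#'
#' @param clusterSet a [ClusterSet].
#' @param minTaxa minimum number of genomes represented.
#' @param maxCopiesPerGenome maximum copy number in any genome.
#' @param maxGenes maximum total gene count.
#' @return list with `kept` (a [ClusterSet] over the same taxa universe)
#'   and `report` (per-cluster predicate table plus per-predicate rejection
#'   counts as attribute `"rejections"`).
#' @export
filterClusters <- function(clusterSet, minTaxa, maxCopiesPerGenome,
                           maxGenes) {
  nTaxaUniverse <- length(clusterTaxa(clusterSet))
  ccAssert(minTaxa >= 1 && minTaxa <= nTaxaUniverse,
           "minTaxa must lie in [1, |taxa|]")
  ccAssert(maxCopiesPerGenome >= 1, "maxCopiesPerGenome must be >= 1")
  ccAssert(maxGenes >= minTaxa, "maxGenes must be >= minTaxa")
  m <- clusterSet@members
  sp <- split(m, m$cluster_id)
  rep <- do.call(rbind, lapply(sp, function(d) {
    data.frame(cluster_id = d$cluster_id[1],
               n_taxa = length(unique(d$genome_id)),
               max_copies = max(table(d$genome_id)),
               n_genes = nrow(d), stringsAsFactors = FALSE)
  }))
  rep$pass_taxa <- rep$n_taxa >= minTaxa
  rep$pass_copies <- rep$max_copies <= maxCopiesPerGenome
  rep$pass_size <- rep$n_genes <= maxGenes
  rep$kept <- rep$pass_taxa & rep$pass_copies & rep$pass_size
  rownames(rep) <- NULL
  attr(rep, "rejections") <- c(taxa = sum(!rep$pass_taxa),
                               copies = sum(!rep$pass_copies),
                               size = sum(!rep$pass_size))
  keptIds <- rep$cluster_id[rep$kept]
  kept <- ClusterSet(m[m$cluster_id %in% keptIds, , drop = FALSE],
                     taxa = clusterTaxa(clusterSet))
  list(kept = kept, report = rep)
}

#' Pan-ortholog selection
#'
#' Returns the clusters with exactly one gene copy in every genome of the
#' universe — equivalent to [filterClusters()] with
#' `(minTaxa = |taxa|, maxCopiesPerGenome = 1, maxGenes = |taxa|)`.
#'
#' @param clusterSet a [ClusterSet].
#' @return a [ClusterSet] of pan-ortholog clusters.
#' @export
findPanOrthologs <- function(clusterSet) {
  taxa <- clusterTaxa(clusterSet)
  m <- clusterSet@members
  sp <- split(m, m$cluster_id)
  ok <- vapply(sp, function(d) {
    cnt <- table(d$genome_id)
    length(cnt) == length(taxa) && all(cnt == 1)
  }, logical(1))
  ClusterSet(m[m$cluster_id %in% names(sp)[ok], , drop = FALSE],
             taxa = taxa)
}
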