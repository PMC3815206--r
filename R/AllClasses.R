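#' @include AllGenerics.R utils.R
NULL

#' Ordered gene annotation for one genome
#'
#' `GenomeAnnotation` holds the gene records of a single genome as a
#' [GenomicRanges::GRanges] (1-based closed coordinates, the Bioconductor
#' convention), with replicon lengths and circularity flags carried in the
#' `Seqinfo`. Gene metadata columns are `gene_id` (globally unique,
#' `genome_id|locus_tag`), `feature_type` (`CDS`, `tRNA`, `rRNA`, `other`)
#' and `product` (free text, used to locate flanking features such as
#' "tRNA-Ser" or "23S"). Records are kept sorted by (replicon, start, end,
#' gene_id) so gene order is deterministic even for overlapping genes.
#'
#' The external TSV dialect read and written by [readGeneTable()] /
#' [writeGeneTable()] uses 0-based half-open coordinates; conversion happens
#' at the I/O boundary and is a bijection on valid intervals.
#'
#' @slot genomeId single genome identifier.
#' @slot genes `GRanges` of gene records.
#'
#' @aliases genomeId geneRanges geneOrder repliconLengths
#' @export
setClass("GenomeAnnotation",
  representation(genomeId = "character", genes = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
  g <- object@genes
  msg <- character()
  if (length(object@genomeId) != 1L || !nzchar(object@genomeId))
    msg <- c(msg, "genomeId must be a single non-empty string")
  need <- c("gene_id", "feature_type", "product")
  if (!all(need %in% colnames(S4Vectors::mcols(g))))
    msg <- c(msg, "genes must carry mcols gene_id, feature_type, product")
  else {
    if (anyDuplicated(S4Vectors::mcols(g)$gene_id))
      msg <- c(msg, "duplicated gene_id")
    bad <- !S4Vectors::mcols(g)$feature_type %in% c("CDS", "tRNA", "rRNA", "other")
    if (any(bad)) msg <- c(msg, "feature_type outside {CDS,tRNA,rRNA,other}")
  }
  if (any(!as.character(BiocGenerics::strand(g)) %in% c("+", "-")))
    msg <- c(msg, "strand must be + or -")
  sl <- GenomeInfoDb::seqlengths(g)
  known <- !is.na(sl)
  if (any(known)) {
    lim <- sl[as.character(GenomeInfoDb::seqnames(g))]
    over <- !is.na(lim) & BiocGenerics::end(g) > lim
    if (any(over)) msg <- c(msg, "gene end exceeds replicon length")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param genomeId genome identifier.
#' @param genes a `GRanges` with mcols `gene_id`, `feature_type`, `product`;
#'   replicon lengths / circularity may be supplied through its `Seqinfo` or
#'   via `repliconLengths` / `circular`.
#' @param repliconLengths optional named numeric vector of replicon lengths.
#' @param circular optional logical (scalar or named per replicon).
#' @return a `GenomeAnnotation`.
#' @export
GenomeAnnotation <- function(genomeId, genes, repliconLengths = NULL,
                             circular = NA) {
  if (!is.null(repliconLengths)) {
    sl <- GenomeInfoDb::seqlengths(genes)
    sl[names(repliconLengths)] <- repliconLengths
    GenomeInfoDb::seqlengths(genes) <- sl
  }
  if (!all(is.na(circular))) {
    circ <- GenomeInfoDb::isCircular(genes)
    if (is.null(names(circular))) {
      circ[] <- circular
    } else {
      circ[names(circular)] <- circular
    }
    GenomeInfoDb::isCircular(genes) <- circ
  }
  o <- geneSortOrder(GenomeInfoDb::seqnames(genes), BiocGenerics::start(genes),
                     BiocGenerics::end(genes), S4Vectors::mcols(genes)$gene_id)
  methods::new("GenomeAnnotation", genomeId = genomeId, genes = genes[o])
}

#' @rdname GenomeAnnotation-class
#' @param x a `GenomeAnnotation`.
#' @export
setMethod("genomeId", "GenomeAnnotation", function(x) x@genomeId)

#' @rdname GenomeAnnotation-class
#' @export
setMethod("geneRanges", "GenomeAnnotation", function(x) x@genes)

#' @rdname GenomeAnnotation-class
#' @param replicon replicon to restrict to (default: all, in order).
#' @param featureType restrict to these feature types (default `"CDS"`).
#' @param ... unused.
#' @export
setMethod("geneOrder", "GenomeAnnotation",
  function(x, replicon = NULL, featureType = "CDS", ...) {
    g <- x@genes
    if (!is.null(replicon))
      g <- g[as.character(GenomeInfoDb::seqnames(g)) == replicon]
    if (!is.null(featureType))
      g <- g[S4Vectors::mcols(g)$feature_type %in% featureType]
    S4Vectors::mcols(g)$gene_id
  })

#' @rdname GenomeAnnotation-class
#' @export
setMethod("repliconLengths", "GenomeAnnotation",
  function(x) GenomeInfoDb::seqlengths(x@genes))

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation:", object@genomeId, "\n")
  cat(" ", length(object@genes), "genes on",
      length(GenomeInfoDb::seqlevels(object@genes)), "replicon(s)\n")
})

#' Ortholog cluster membership across a genome universe
#'
#' `ClusterSet` maps cluster ids to their member genes, each member a
#' (genome_id, gene_id) pair, together with the full genome universe
#' (`taxa`) — absence of a genome from a cluster is meaningful for
#' gene-content similarity, so the universe must be carried explicitly.
#' No (genome_id, gene_id) pair may appear in more than one cluster.
#'
#' @slot members data.frame with columns `cluster_id`, `genome_id`, `gene_id`.
#' @slot taxa character vector: the genome universe.
#'
#' @aliases clusterIds clusterTaxa clusterMembers nClusters genomeClusters
#'   copyCounts
#' @export
setClass("ClusterSet",
  representation(members = "data.frame", taxa = "character"))

setValidity("ClusterSet", function(object) {
  m <- object@members
  msg <- character()
  if (!all(c("cluster_id", "genome_id", "gene_id") %in% names(m)))
    msg <- c(msg, "members needs columns cluster_id, genome_id, gene_id")
  else {
    key <- paste(m$genome_id, m$gene_id, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "a (genome_id, gene_id) member appears in two clusters")
    if (!all(m$genome_id %in% object@taxa))
      msg <- c(msg, "member genome absent from taxa universe")
  }
  if (anyDuplicated(object@taxa)) msg <- c(msg, "duplicated taxa")
  if (length(msg)) msg else TRUE
})

#' Construct a ClusterSet
#'
#' @param members data.frame with columns `cluster_id`, `genome_id`,
#'   `gene_id`.
#' @param taxa genome universe; defaults to the genomes present in
#'   `members`.
#' @return a `ClusterSet`.
#' @export
ClusterSet <- function(members, taxa = NULL) {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  members <- members[order(members$cluster_id, members$genome_id,
                           members$gene_id, method = "radix"), , drop = FALSE]
  rownames(members) <- NULL
  if (is.null(taxa)) taxa <- sort(unique(members$genome_id))
  methods::new("ClusterSet", members = members, taxa = sort(taxa))
}

#' @rdname ClusterSet-class
#' @param x a `ClusterSet`.
#' @export
setMethod("clusterIds", "ClusterSet",
  function(x) sort(unique(x@members$cluster_id)))

#' @rdname ClusterSet-class
#' @export
setMethod("clusterTaxa", "ClusterSet", function(x) x@taxa)

#' @rdname ClusterSet-class
#' @export
setMethod("nClusters", "ClusterSet",
  function(x) length(unique(x@members$cluster_id)))

#' @rdname ClusterSet-class
#' @param id cluster id.
#' @param ... unused.
#' @export
setMethod("clusterMembers", "ClusterSet", function(x, id, ...) {
  m <- x@members[x@members$cluster_id == id, c("genome_id", "gene_id")]
  rownames(m) <- NULL
  m
})

#' @rdname ClusterSet-class
#' @param genome optional single genome id; if given, returns that genome's
#'   cluster ids, otherwise a named list over the whole universe.
#' @export
setMethod("genomeClusters", "ClusterSet", function(x, genome = NULL, ...) {
  if (!is.null(genome)) {
    ccAssert(genome %in% x@taxa, paste0("unknown genome: ", genome))
    return(sort(unique(x@members$cluster_id[x@members$genome_id == genome])))
  }
  out <- lapply(x@taxa, function(g)
    sort(unique(x@members$cluster_id[x@members$genome_id == g])))
  names(out) <- x@taxa
  out
})

#' @rdname ClusterSet-class
#' @export
setMethod("copyCounts", "ClusterSet", function(x) {
  table(factor(x@members$cluster_id),
        factor(x@members$genome_id, levels = x@taxa))
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet:", nClusters(object), "clusters,",
      nrow(object@members), "genes,", length(object@taxa), "taxa\n")
})

#' Gene-content similarity matrix
#'
#' Symmetric matrix of pairwise gene-content similarity values
#' (shared clusters / clusters of the genome with fewer clusters), with
#' per-genome cluster counts. Values lie in [0, 1]; the diagonal is 1.
#'
#' @slot values symmetric numeric matrix with genome ids as dimnames.
#' @slot clusterCounts named integer vector of per-genome cluster counts.
#'
#' @aliases similarityValues
#' @export
setClass("ContentSimilarityMatrix",
  representation(values = "matrix", clusterCounts = "integer"))

setValidity("ContentSimilarityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!isTRUE(all.equal(v, t(v)))) msg <- c(msg, "matrix not symmetric")
  if (any(v < 0 | v > 1)) msg <- c(msg, "values outside [0,1]")
  if (nrow(v) && any(abs(diag(v) - 1) > 0)) msg <- c(msg, "diagonal must be 1")
  if (!identical(rownames(v), names(object@clusterCounts)))
    msg <- c(msg, "clusterCounts names must match matrix dimnames")
  if (length(msg)) msg else TRUE
})

#' @rdname ContentSimilarityMatrix-class
#' @param x a `ContentSimilarityMatrix`.
#' @export
setMethod("similarityValues", "ContentSimilarityMatrix",
  function(x) x@values)

setMethod("show", "ContentSimilarityMatrix", function(object) {
  cat("ContentSimilarityMatrix:", nrow(object@values), "genomes\n")
})

#' An extracted chromosomal region
#'
#' A replicon interval in 0-based half-open coordinates, remembering the
#' anchoring features and any flank added. On circular replicons an
#' expanded region may wrap the origin; it is then re-linearised with
#' `end0 > repliconLength` and `wrapped = TRUE` (positions are read modulo
#' the replicon length).
#'
#' @slot genomeId,repliconId identifiers.
#' @slot start0,end0 0-based half-open interval.
#' @slot anchors description of the flanking features.
#' @slot flankBp flank added on each side (bp).
#' @slot repliconLength replicon length (NA if unknown).
#' @slot circular whether the replicon is circular.
#' @slot wrapped whether the interval wraps the origin.
#' @export
setClass("Region",
  representation(genomeId = "character", repliconId = "character",
                 start0 = "numeric", end0 = "numeric",
                 anchors = "character", flankBp = "numeric",
                 repliconLength = "numeric", circular = "logical",
                 wrapped = "logical"))

setValidity("Region", function(object) {
  msg <- character()
  if (object@start0 < 0) msg <- c(msg, "start0 < 0")
  if (object@start0 >= object@end0) msg <- c(msg, "start0 must be < end0")
  if (!is.na(object@repliconLength)) {
    if (!object@wrapped && object@end0 > object@repliconLength)
      msg <- c(msg, "end0 exceeds replicon length on unwrapped region")
    if (object@wrapped && !object@circular)
      msg <- c(msg, "wrapped region on a linear replicon")
  }
  if (length(msg)) msg else TRUE
})

Region <- function(genomeId, repliconId, start0, end0, anchors = character(),
                   flankBp = 0, repliconLength = NA_real_, circular = FALSE,
                   wrapped = FALSE) {
  methods::new("Region", genomeId = genomeId, repliconId = repliconId,
               start0 = as.numeric(start0), end0 = as.numeric(end0),
               anchors = anchors, flankBp = as.numeric(flankBp),
               repliconLength = as.numeric(repliconLength),
               circular = circular, wrapped = wrapped)
}

setMethod("show", "Region", function(object) {
  cat(sprintf("Region %s:%s [%d, %d)%s\n", object@genomeId,
              object@repliconId, as.integer(object@start0),
              as.integer(object@end0),
              if (object@wrapped) " (wraps origin)" else ""))
  if (length(object@anchors))
    cat("  anchors:", paste(object@anchors, collapse = " .. "), "\n")
})

#' Genome-evolution simulation settings
#'
#' All rates are per unit branch length; gain/loss/duplication are per gene,
#' rearrangement rates per genome, `substRate` is the per-site amino-acid
#' replacement rate. `gcBias` in [-1, 1] shifts substitution target
#' frequencies for the GC-rich amino-acid set {G, A, R, P}: negative values
#' emulate AT mutational bias (residues preferentially leave the set).
#' `lineageEffects` is a list of per-lineage overrides, each a list with a
#' `tips` element (a clade is addressed by the tips it spans; a single tip
#' addresses its terminal branch) and any of `substMult`, `gainMult`,
#' `lossMult`, `dupMult`, `invMult`, `translocMult`, `gcBias`.
#' The seed fixes the entire dataset.
#'
#' @export
setClass("SimulationConfig",
  representation(nTaxa = "integer", birthRate = "numeric",
                 rootGeneCount = "integer",
                 gainRate = "numeric", lossRate = "numeric",
                 dupRate = "numeric",
                 inversionRate = "numeric", translocationRate = "numeric",
                 substRate = "numeric", gcBias = "numeric",
                 geneRateShape = "numeric",
                 proteinLengthMean = "numeric", proteinLengthSd = "numeric",
                 lineageEffects = "list", secondReplicon = "logical",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  rates <- c(object@birthRate, object@gainRate, object@lossRate,
             object@dupRate, object@inversionRate, object@translocationRate,
             object@substRate)
  if (any(rates < 0)) msg <- c(msg, "all rates must be >= 0")
  if (object@nTaxa < 3L) msg <- c(msg, "nTaxa must be >= 3")
  if (abs(object@gcBias) > 1) msg <- c(msg, "gcBias must lie in [-1, 1]")
  if (object@geneRateShape <= 0) msg <- c(msg, "geneRateShape must be > 0")
  if (object@rootGeneCount < 1L) msg <- c(msg, "rootGeneCount must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package's tests: a 12-taxon birth tree carrying 100-gene genomes with
#' moderate turnover and rearrangement.
#'
#' @param nTaxa number of extant genomes.
#' @param birthRate speciation rate of the pure-birth species tree.
#' @param rootGeneCount genes in the root genome.
#' @param gainRate,lossRate,dupRate content-event rates (per gene per unit
#'   branch length).
#' @param inversionRate,translocationRate rearrangement rates (per genome
#'   per unit branch length).
#' @param substRate per-site amino-acid replacement rate.
#' @param gcBias baseline GC-rich amino-acid bias in [-1, 1].
#' @param geneRateShape shape of the gamma distribution (mean 1) of
#'   per-gene substitution-rate multipliers; smaller values give stronger
#'   among-gene rate heterogeneity (conserved vs fast-evolving genes),
#'   which is what lets lineage GC bias spread genes apart in aminoGC.
#' @param proteinLengthMean,proteinLengthSd protein length distribution (aa).
#' @param lineageEffects list of per-lineage overrides (see class docs).
#' @param secondReplicon add a second, linear replicon holding the last 20%
#'   of each genome.
#' @param seed integer seed fixing the whole dataset.
#' @return a `SimulationConfig`.
#' @export
simulationConfig <- function(nTaxa = 12, birthRate = 1, rootGeneCount = 100,
                             gainRate = 0.05, lossRate = 0.08, dupRate = 0.02,
                             inversionRate = 6, translocationRate = 1,
                             substRate = 0.4, gcBias = 0,
                             geneRateShape = 1.5,
                             proteinLengthMean = 200, proteinLengthSd = 50,
                             lineageEffects = list(),
                             secondReplicon = FALSE, seed = 1L) {
  methods::new("SimulationConfig", nTaxa = as.integer(nTaxa),
               birthRate = birthRate, rootGeneCount = as.integer(rootGeneCount),
               gainRate = gainRate, lossRate = lossRate, dupRate = dupRate,
               inversionRate = inversionRate,
               translocationRate = translocationRate,
               substRate = substRate, gcBias = gcBias,
               geneRateShape = geneRateShape,
               proteinLengthMean = proteinLengthMean,
               proteinLengthSd = proteinLengthSd,
               lineageEffects = lineageEffects,
               secondReplicon = secondReplicon, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d taxa, %d root genes, ",
                     "gain/loss/dup %.3g/%.3g/%.3g, inv/transloc %.3g/%.3g, ",
                     "subst %.3g, gcBias %.3g, seed %d\n"),
              object@nTaxa, object@rootGeneCount, object@gainRate,
              object@lossRate, object@dupRate, object@inversionRate,
              object@translocationRate, object@substRate, object@gcBias,
              object@seed))
  if (length(object@lineageEffects))
    cat(" ", length(object@lineageEffects), "lineage effect(s)\n")
})

#' A simulated pan-genome with ground truth
#'
#' Bundle returned by [simulateDataset()]: the species tree, per-genome
#' annotations and proteomes, the true ortholog clusters, a taxonomy derived
#' from tree cuts, the per-branch event log and the realised per-tip GC
#' bias.
#'
#' @export
setClass("SimulatedPangenome",
  representation(config = "SimulationConfig", tree = "ANY",
                 annotations = "list", proteomes = "list",
                 clusters = "ClusterSet", taxonomy = "data.frame",
                 eventLog = "data.frame", gcBiasRealized = "numeric"))

setMethod("show", "SimulatedPangenome", function(object) {
  cat("SimulatedPangenome:", length(object@annotations), "genomes,",
      nClusters(object@clusters), "true clusters, seed",
      object@config@seed, "\n")
})
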