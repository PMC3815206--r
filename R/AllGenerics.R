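#' @include utils.R
NULL

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("geneOrder", function(x, ...) standardGeneric("geneOrder"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("repliconLengths", function(x) standardGeneric("repliconLengths"))

#' @rdname ClusterSet-class
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname ClusterSet-class
#' @export
setGeneric("clusterTaxa", function(x) standardGeneric("clusterTaxa"))

#' @rdname ClusterSet-class
#' @export
setGeneric("clusterMembers", function(x, ...) standardGeneric("clusterMembers"))

#' @rdname ClusterSet-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname ClusterSet-class
#' @export
setGeneric("genomeClusters", function(x, ...) standardGeneric("genomeClusters"))

#' @rdname ClusterSet-class
#' @export
setGeneric("copyCounts", function(x) standardGeneric("copyCounts"))

#' @rdname ContentSimilarityMatrix-class
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))
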