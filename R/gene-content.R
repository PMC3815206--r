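#' Gene-content similarity between two genomes
#'
#' The similarity index is the number of shared ortholog clusters divided
#' by the number of clusters of the genome represented in fewer clusters:
#' \eqn{S = |A \cap B| / \min(|A|, |B|)}. A genome's cluster set counts
#' every cluster in which it has at least one member (copy number is
#' ignored); singleton clusters count towards their genome's total.
#'
#' @param clustersA,clustersB character vectors of cluster ids (one per
#'   genome).
#' @return similarity in [0, 1].
#' @export
contentSimilarity <- function(clustersA, clustersB) {
  clustersA <- unique(clustersA)
  clustersB <- unique(clustersB)
  ccAssert(length(clustersA) > 0 && length(clustersB) > 0,
           "empty cluster set for a genome")
  length(intersect(clustersA, clustersB)) /
    min(length(clustersA), length(clustersB))
}

#' Pairwise gene-content similarity matrix
#'
#' Applies [contentSimilarity()] to every genome pair of a cluster set.
#' Genomes of the universe with zero clusters are excluded with a warning.
#'
#' @param clusterSet a [ClusterSet].
#' @return a [ContentSimilarityMatrix].
#' @export
similarityMatrix <- function(clusterSet) {
  byGenome <- genomeClusters(clusterSet)
  empty <- names(byGenome)[lengths(byGenome) == 0]
  if (length(empty)) {
    warning("excluding genome(s) with zero clusters: ",
            paste(empty, collapse = ", "))
    byGenome <- byGenome[lengths(byGenome) > 0]
  }
  ccAssert(length(byGenome) >= 1, "no genomes with clusters")
  ids <- names(byGenome)
  n <- length(ids)
  v <- diag(nrow = n)
  dimnames(v) <- list(ids, ids)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        s <- contentSimilarity(byGenome[[i]], byGenome[[j]])
        v[i, j] <- s
        v[j, i] <- s
      }
    }
  }
  methods::new("ContentSimilarityMatrix", values = v,
               clusterCounts = stats::setNames(lengths(byGenome), ids))
}

#' Rank a genome's neighbours by gene-content similarity
#'
#' Descending by similarity; the focal genome is excluded from its own
#' ranking; ties share the smallest rank and are listed in lexicographic
#' genome order.
#'
#' @param x a [ContentSimilarityMatrix] or plain symmetric matrix.
#' @param focal focal genome id.
#' @return data.frame with columns `genome`, `similarity`, `rank`.
#' @export
rankNeighbors <- function(x, focal) {
  v <- if (methods::is(x, "ContentSimilarityMatrix")) similarityValues(x)
       else x
  ccAssert(focal %in% rownames(v), paste0("unknown focal genome: ", focal))
  s <- v[focal, setdiff(colnames(v), focal)]
  o <- order(-s, names(s), method = "radix")
  s <- s[o]
  data.frame(genome = names(s), similarity = unname(s),
             rank = rank(-s, ties.method = "min"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a similarity matrix as a square TSV table
#'
#' Genome ids appear as both row and column headers; optional provenance
#' comment lines are prefixed with `#`.
#'
#' @param x a [ContentSimilarityMatrix] or matrix.
#' @param path output path.
#' @param header optional comment lines.
#' @return `path`, invisibly.
#' @export
writeSimilarityMatrix <- function(x, path, header = NULL) {
  v <- if (methods::is(x, "ContentSimilarityMatrix")) similarityValues(x)
       else x
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(data.frame(genome_id = rownames(v), v,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a square similarity matrix TSV
#'
#' @param path file path.
#' @return numeric matrix with genome dimnames.
#' @export
readSimilarityMatrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
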