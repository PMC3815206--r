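#' Normalized bit score
#'
#' Divides a pairwise alignment bit score by the smaller of the two
#' self-alignment scores and clips to [0, 1]. The minimum-self denominator
#' keeps the statistic symmetric in the two genes.
#'
#' @param bitscoreAB pairwise score(s).
#' @param selfscoreA,selfscoreB self-alignment scores.
#' @return value(s) in [0, 1].
#' @export
normalizedBitscore <- function(bitscoreAB, selfscoreA, selfscoreB) {
  ccAssert(all(selfscoreA > 0) && all(selfscoreB > 0),
           "self scores must be positive")
  pmin(1, pmax(0, bitscoreAB / pmin(selfscoreA, selfscoreB)))
}

#' Average normalized bit score of a genome pair
#'
#' The identity axis of the synteny-identity comparison: the arithmetic
#' mean of [normalizedBitscore()] over all shared (orthologous) genes of a
#' genome pair.
#'
#' @param pairMap data.frame with columns `bitscore_ab`, `selfscore_a`,
#'   `selfscore_b` (one row per shared gene pair).
#' @return mean normalized bit score in [0, 1].
#' @export
pairIdentity <- function(pairMap) {
  ccAssert(nrow(pairMap) > 0, "no shared genes")
  mean(normalizedBitscore(pairMap$bitscore_ab, pairMap$selfscore_a,
                          pairMap$selfscore_b))
}

# Neighbour sets for each element of an ordered gene vector.
# Returns a list (by gene id) of character vectors of adjacent gene ids.
.adjacency <- function(ord, circular = FALSE) {
  n <- length(ord)
  out <- vector("list", n)
  names(out) <- ord
  if (n == 1) {
    out[[1]] <- character(0)
    return(out)
  }
  for (i in seq_len(n)) {
    nb <- character(0)
    if (i > 1) nb <- c(nb, ord[i - 1])
    if (i < n) nb <- c(nb, ord[i + 1])
    if (circular && n > 2) {
      if (i == 1) nb <- c(nb, ord[n])
      if (i == n) nb <- c(nb, ord[1])
    }
    if (circular && n == 2) nb <- ord[-i]
    out[[i]] <- unique(nb)
  }
  out
}

#' Synteny fraction of a genome pair
#'
#' The fraction of shared genes that keep at least one conserved nearest
#' neighbour: both gene orders are first restricted to the shared
#' (orthologous) genes, then a shared gene counts as syntenic when at least
#' one of its adjacent shared genes in genome A maps to a gene adjacent to
#' its ortholog in genome B. Adjacency is orientation- and strand-free
#' (a fully reversed order has synteny 1), and closes into a ring on
#' circular replicons. With `side = "both"`, every adjacent shared gene in
#' A must be conserved for the gene to count.
#'
#' @param orderA,orderB character vectors: gene ids of the two genomes in
#'   chromosomal order.
#' @param pairs optional data.frame with columns `gene_a`, `gene_b` giving
#'   the one-to-one ortholog map; defaults to matching identical gene ids.
#' @param circularA,circularB whether each replicon is circular.
#' @param side `"either"` (default) or `"both"`.
#' @return fraction in [0, 1].
#' @export
syntenyFraction <- function(orderA, orderB, pairs = NULL,
                            circularA = FALSE, circularB = FALSE,
                            side = c("either", "both")) {
  side <- match.arg(side)
  if (is.null(pairs)) {
    shared <- intersect(orderA, orderB)
    pairs <- data.frame(gene_a = shared, gene_b = shared,
                        stringsAsFactors = FALSE)
  }
  ccAssert(!anyDuplicated(pairs$gene_a) && !anyDuplicated(pairs$gene_b),
           "ortholog map must be one-to-one")
  ra <- orderA[orderA %in% pairs$gene_a]
  rb <- orderB[orderB %in% pairs$gene_b]
  nShared <- length(ra)
  ccAssert(nShared > 0, "no shared genes between the two genomes")
  ccAssert(nShared == length(rb), "ortholog map does not cover both orders")
  b2a <- stats::setNames(pairs$gene_a, pairs$gene_b)
  rbMapped <- unname(b2a[rb])
  adjA <- .adjacency(ra, circularA)
  adjB <- .adjacency(rbMapped, circularB)
  synt <- vapply(ra, function(g) {
    na <- adjA[[g]]
    nb <- adjB[[g]]
    if (length(na) == 0) return(FALSE)
    if (side == "either") length(intersect(na, nb)) > 0 else all(na %in% nb)
  }, logical(1))
  sum(synt) / nShared
}

#' Taxonomic class of a genome pair
#'
#' The most specific shared stratum: `within_genus`, `within_family`,
#' `within_order` or `between_orders`.
#'
#' @param genomeA,genomeB genome ids.
#' @param taxonomy data.frame with columns `genome_id`, `genus`, `family`,
#'   `order` (as from [readTaxonomy()]).
#' @return category string.
#' @export
classifyPair <- function(genomeA, genomeB, taxonomy) {
  i <- match(genomeA, taxonomy$genome_id)
  j <- match(genomeB, taxonomy$genome_id)
  ccAssert(!is.na(i) && !is.na(j), "genome missing from taxonomy table")
  if (taxonomy$genus[i] == taxonomy$genus[j]) return("within_genus")
  if (taxonomy$family[i] == taxonomy$family[j]) return("within_family")
  if (taxonomy$order[i] == taxonomy$order[j]) return("within_order")
  "between_orders"
}
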