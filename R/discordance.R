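#' Flag a gene tree as concordant or discordant with a species tree
#'
#' After pruning both trees to their shared leaf set, the gene tree is
#' called `discordant` when it contains at least one bipartition with
#' support at or above `supportThreshold` that is incompatible with some
#' bipartition of the species tree (two splits are incompatible when all
#' four of their side intersections are non-empty). Supports are read from
#' the gene tree's internal node labels; values on a 0-100 scale are
#' normalised to [0, 1]; unlabelled nodes count as unsupported, so only
#' strongly supported conflict can flag a tree. This is the standard
#' realisation of discordance filtering used to drop putatively
#' horizontally transferred genes before concatenation.
#'
#' @param clusterTree `phylo` gene tree with bootstrap/posterior node
#'   labels.
#' @param speciesTree `phylo` reference species tree.
#' @param supportThreshold minimum support for a conflicting bipartition to
#'   count (default 0.9; on the scale of the normalised supports).
#' @return `"concordant"` or `"discordant"`.
#' @export
discordanceFlag <- function(clusterTree, speciesTree,
                            supportThreshold = 0.9) {
  shared <- intersect(clusterTree$tip.label, speciesTree$tip.label)
  ccAssert(length(shared) >= 3, "fewer than 3 shared leaves")
  ct <- ape::keep.tip(clusterTree, shared)
  st <- ape::keep.tip(speciesTree, shared)
  n <- length(shared)
  if (n < 4) return("concordant")

  ctSplits <- .nontrivialSplits(ct)
  if (length(ctSplits$side) == 0) return("concordant")
  nTips <- length(ct$tip.label)
  lab <- ct$node.label
  support <- vapply(ctSplits$child, function(ch) {
    if (ch <= nTips || is.null(lab)) return(NA_real_)
    suppressWarnings(as.numeric(lab[ch - nTips]))
  }, numeric(1))
  if (any(!is.na(support)) && max(support, na.rm = TRUE) > 1)
    support <- support / 100
  support[is.na(support)] <- 0

  stSplits <- .nontrivialSplits(st)
  stKeys <- vapply(stSplits$side, .splitKey, "", tips = shared)
  for (k in seq_along(ctSplits$side)) {
    if (support[k] < supportThreshold) next
    side <- ctSplits$side[[k]]
    if (.splitKey(side, shared) %in% stKeys) next
    for (sSide in stSplits$side) {
      if (!.splitsCompatible(side, sSide, shared)) return("discordant")
    }
  }
  "concordant"
}
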