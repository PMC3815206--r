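# Bipartition utilities shared by paralog resolution and discordance
# flagging. Splits are handled in the unrooted sense: each edge of a tree
# defines a bipartition of the leaf set; a side is represented as the
# sorted character vector of tip labels below the edge's child.

# Tip set below every node; list indexed by node number.
.nodeTipSets <- function(tree) {
  n <- length(tree$tip.label)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]
    ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, sort)
}

# data.frame of one row per edge: child node, side size, plus a list of
# sides (sorted tip vectors, the child side of each edge).
.edgeSplits <- function(tree) {
  sets <- .nodeTipSets(tree)
  child <- tree$edge[, 2]
  list(child = child, side = sets[child])
}

# Canonical key of a split side over leaf universe `tips`.
.splitKey <- function(side, tips) {
  other <- setdiff(tips, side)
  a <- sort(side)
  b <- sort(other)
  pick <- if (min(a) <= min(b)) a else b
  paste(pick, collapse = "\r")
}

# Are two splits (given one side each, over the same leaf set) compatible?
# Incompatible iff all four pairwise intersections are non-empty.
.splitsCompatible <- function(sideA, sideB, tips) {
  a1 <- sideA
  a2 <- setdiff(tips, sideA)
  b1 <- sideB
  b2 <- setdiff(tips, sideB)
  !(length(intersect(a1, b1)) > 0 && length(intersect(a1, b2)) > 0 &&
      length(intersect(a2, b1)) > 0 && length(intersect(a2, b2)) > 0)
}

# Non-trivial splits of a tree as a list of sides.
.nontrivialSplits <- function(tree) {
  n <- length(tree$tip.label)
  es <- .edgeSplits(tree)
  keep <- vapply(es$side, function(s)
    length(s) >= 2 && length(s) <= n - 2, logical(1))
  list(child = es$child[keep], side = es$side[keep])
}

# Does `leaves` form one side of some edge (an unrooted clade)?
.isUnrootedClade <- function(tree, leaves) {
  tips <- tree$tip.label
  leaves <- sort(leaves)
  if (length(leaves) == length(tips)) return(TRUE)
  es <- .edgeSplits(tree)
  for (s in es$side) {
    if (identical(s, leaves) || identical(sort(setdiff(tips, s)), leaves))
      return(TRUE)
  }
  FALSE
}

# Terminal branch length of a tip (by label).
.terminalBranchLength <- function(tree, tip) {
  i <- match(tip, tree$tip.label)
  e <- which(tree$edge[, 2] == i)
  tree$edge.length[e]
}
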