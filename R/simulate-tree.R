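#' Simulate a pure-birth (Yule) species tree
#'
#' Lineages split at rate `birthRate` each, starting from a single lineage,
#' until `nTaxa` are alive; the tips are then extended by one further
#' exponential waiting time so all terminal branches are positive. The tree
#' is ultrametric, binary and rooted, with tips labelled `t1..tN`. The
#' expected root-to-tip depth is \eqn{(1/\lambda)\sum_{k=2}^{n} 1/k},
#' growing like \eqn{\log(n)/\lambda}.
#'
#' @param nTaxa number of tips (>= 3).
#' @param birthRate speciation rate.
#' @param seed optional seed (set only when non-NULL, so the function can
#'   also consume an ambient stream).
#' @return a `phylo` tree.
#' @export
simulateSpeciesTree <- function(nTaxa, birthRate = 1, seed = NULL) {
  ccAssert(nTaxa >= 3, "nTaxa must be >= 3")
  ccAssert(birthRate > 0, "birthRate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  .yuleTree(as.integer(nTaxa), birthRate)
}

.yuleTree <- function(n, lambda) {
  parent <- rep(NA_integer_, 2 * n - 1)
  birth <- rep(NA_real_, 2 * n - 1)
  splitTime <- rep(NA_real_, 2 * n - 1)
  birth[1] <- 0
  active <- 1L
  nextId <- 2L
  t <- 0
  splitters <- integer(0)
  while (length(active) < n) {
    k <- length(active)
    t <- t + stats::rexp(1, k * lambda)
    i <- active[sample.int(k, 1)]
    splitTime[i] <- t
    splitters <- c(splitters, i)
    for (s in 1:2) {
      parent[nextId] <- i
      birth[nextId] <- t
      active <- c(active, nextId)
      nextId <- nextId + 1L
    }
    active <- setdiff(active, i)
  }
  tEnd <- t + stats::rexp(1, n * lambda)

  tipsIds <- sort(active)
  intIds <- splitters[order(splitTime[splitters])]  # root first
  num <- integer(2 * n - 1)
  num[tipsIds] <- seq_len(n)
  num[intIds] <- n + seq_len(n - 1)
  edgeFrom <- integer(0)
  edgeTo <- integer(0)
  edgeLen <- numeric(0)
  for (id in c(tipsIds, intIds)) {
    p <- parent[id]
    if (is.na(p)) next  # root lineage has no parent edge
    endT <- if (id %in% tipsIds) tEnd else splitTime[id]
    edgeFrom <- c(edgeFrom, num[p])
    edgeTo <- c(edgeTo, num[id])
    edgeLen <- c(edgeLen, endT - birth[id])
  }
  tr <- structure(list(edge = cbind(edgeFrom, edgeTo),
                       edge.length = edgeLen,
                       tip.label = paste0("t", seq_len(n)),
                       Nnode = n - 1L),
                  class = "phylo")
  dimnames(tr$edge) <- NULL
  ape::reorder.phylo(tr, "cladewise")
}
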