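# Genome evolution along a species tree: gene gain/loss/duplication,
# segment inversion/translocation, and amino-acid substitution whose
# target frequencies shift with a per-lineage GC bias.

# substitution target weights over the 20 standard amino acids:
# members of the GC-rich set {G,A,R,P} get weight 1+b, others 1.
.aaWeights <- function(gcBias) {
  w <- rep(1, length(AA_STANDARD))
  names(w) <- AA_STANDARD
  w[AA_GC_SET] <- 1 + gcBias
  w / sum(w)
}

.randomProtein <- function(len, gcBias) {
  paste(sample(AA_STANDARD, len, replace = TRUE, prob = .aaWeights(gcBias)),
        collapse = "")
}

.drawLength <- function(config) {
  max(30L, as.integer(round(stats::rnorm(1, config@proteinLengthMean,
                                         config@proteinLengthSd))))
}

# tip sets below the MRCA of a set of tips (clade addressing for lineage
# effects); a single tip addresses only its terminal branch.
.cladeTipSet <- function(tree, tips) {
  ccAssert(all(tips %in% tree$tip.label),
           paste0("lineage effect names unknown tip(s): ",
                  paste(setdiff(tips, tree$tip.label), collapse = ", ")))
  if (length(tips) == 1) return(tips)
  node <- ape::getMRCA(tree, tips)
  sets <- .nodeTipSets(tree)
  sets[[node]]
}

# Per-edge effective rate multipliers and gcBias, honouring lineageEffects.
# An effect applies to every edge whose descendant tip set lies within the
# effect's clade (including the clade's stem edge). When several effects
# define gcBias for an edge, the innermost (smallest clade) wins;
# multipliers compose multiplicatively.
.edgeEffects <- function(tree, config) {
  nEdge <- nrow(tree$edge)
  sets <- .nodeTipSets(tree)
  childSets <- sets[tree$edge[, 2]]
  eff <- data.frame(substMult = rep(1, nEdge), gainMult = 1, lossMult = 1,
                    dupMult = 1, invMult = 1, translocMult = 1,
                    gcBias = config@gcBias)
  if (length(config@lineageEffects) == 0) return(eff)
  scopes <- lapply(config@lineageEffects, function(le)
    .cladeTipSet(tree, le$tips))
  biasSize <- rep(Inf, nEdge)
  for (k in seq_along(config@lineageEffects)) {
    le <- config@lineageEffects[[k]]
    scope <- scopes[[k]]
    inScope <- vapply(childSets, function(s) all(s %in% scope), logical(1))
    for (fld in c("substMult", "gainMult", "lossMult", "dupMult",
                  "invMult", "translocMult")) {
      if (!is.null(le[[fld]]))
        eff[[fld]][inScope] <- eff[[fld]][inScope] * le[[fld]]
    }
    if (!is.null(le$gcBias)) {
      upd <- inScope & length(scope) < biasSize
      eff$gcBias[upd] <- le$gcBias
      biasSize[upd] <- length(scope)
    }
  }
  eff
}

# Evolve one genome (list with integer vector $cluster and character
# vector $seq, in gene order) along a branch. Returns the evolved genome,
# the updated gain counter and the branch's event records.
.evolveBranch <- function(genome, t, rates, gcBias, config, gainCounter) {
  events <- list()
  log1 <- function(type, detail) {
    events[[length(events) + 1]] <<- data.frame(
      event = type, detail = detail, stringsAsFactors = FALSE)
  }
  # substitutions (per-gene gamma rate multipliers)
  if (rates$subst > 0 && length(genome$cluster)) {
    w <- .aaWeights(gcBias)
    pSub <- 1 - exp(-rates$subst * t * genome$rate)
    genome$seq <- mapply(function(s, p) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      nm <- stats::rbinom(1, length(ch), p)
      if (nm > 0) {
        pos <- sample.int(length(ch), nm)
        ch[pos] <- sample(AA_STANDARD, nm, replace = TRUE, prob = w)
      }
      paste(ch, collapse = "")
    }, genome$seq, pSub, USE.NAMES = FALSE)
  }
  # losses
  pLoss <- 1 - exp(-rates$loss * t)
  if (pLoss > 0 && length(genome$cluster)) {
    lost <- stats::runif(length(genome$cluster)) < pLoss
    if (any(lost)) {
      log1("loss", paste(genome$cluster[lost], collapse = ","))
      genome$cluster <- genome$cluster[!lost]
      genome$seq <- genome$seq[!lost]
      genome$rate <- genome$rate[!lost]
    }
  }
  # duplications
  pDup <- 1 - exp(-rates$dup * t)
  if (pDup > 0 && length(genome$cluster)) {
    dup <- which(stats::runif(length(genome$cluster)) < pDup)
    for (i in dup) {
      pos <- sample.int(length(genome$cluster) + 1, 1)
      genome$cluster <- append(genome$cluster, genome$cluster[i], after = pos - 1)
      genome$seq <- append(genome$seq, genome$seq[i], after = pos - 1)
      genome$rate <- append(genome$rate, genome$rate[i], after = pos - 1)
    }
    if (length(dup))
      log1("duplication", paste(genome$cluster[dup], collapse = ","))
  }
  # gains
  nGain <- stats::rpois(1, rates$gain * t * max(1, length(genome$cluster)))
  if (nGain > 0) {
    newIds <- gainCounter + seq_len(nGain)
    gainCounter <- gainCounter + nGain
    for (cid in newIds) {
      pos <- sample.int(length(genome$cluster) + 1, 1)
      genome$cluster <- append(genome$cluster, cid, after = pos - 1)
      genome$seq <- append(genome$seq, .randomProtein(.drawLength(config),
                                                      gcBias),
                           after = pos - 1)
      genome$rate <- append(genome$rate,
                            stats::rgamma(1, config@geneRateShape,
                                          rate = config@geneRateShape),
                           after = pos - 1)
    }
    log1("gain", paste(newIds, collapse = ","))
  }
  # inversions
  nInv <- stats::rpois(1, rates$inv * t)
  if (nInv > 0 && length(genome$cluster) >= 2) {
    for (k in seq_len(nInv)) {
      ij <- sort(sample.int(length(genome$cluster), 2))
      idx <- seq.int(ij[1], ij[2])
      genome$cluster[idx] <- rev(genome$cluster[idx])
      genome$seq[idx] <- rev(genome$seq[idx])
      genome$rate[idx] <- rev(genome$rate[idx])
      log1("inversion", paste(ij, collapse = ","))
    }
  }
  # translocations
  nTr <- stats::rpois(1, rates$transloc * t)
  if (nTr > 0 && length(genome$cluster) >= 3) {
    for (k in seq_len(nTr)) {
      len <- length(genome$cluster)
      ij <- sort(sample.int(len, 2))
      idx <- seq.int(ij[1], ij[2])
      if (length(idx) >= len) next
      segC <- genome$cluster[idx]
      segS <- genome$seq[idx]
      segR <- genome$rate[idx]
      genome$cluster <- genome$cluster[-idx]
      genome$seq <- genome$seq[-idx]
      genome$rate <- genome$rate[-idx]
      pos <- sample.int(length(genome$cluster) + 1, 1)
      genome$cluster <- append(genome$cluster, segC, after = pos - 1)
      genome$seq <- append(genome$seq, segS, after = pos - 1)
      genome$rate <- append(genome$rate, segR, after = pos - 1)
      log1("translocation", paste(c(ij, pos), collapse = ","))
    }
  }
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(event = character(0), detail = character(0),
                        stringsAsFactors = FALSE)
  list(genome = genome, gainCounter = gainCounter, events = ev)
}

# Full evolution of all genomes down the tree. Consumes the ambient RNG
# stream; callers are responsible for seeding.
.simulateCore <- function(tree, config) {
  nTips <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "cladewise")
  eff <- .edgeEffects(ord, config)
  root <- nTips + 1L
  rootBias <- config@gcBias
  rootGenome <- list(cluster = seq_len(config@rootGeneCount),
                     seq = vapply(seq_len(config@rootGeneCount), function(i)
                       .randomProtein(.drawLength(config), rootBias), ""),
                     rate = stats::rgamma(config@rootGeneCount,
                                          config@geneRateShape,
                                          rate = config@geneRateShape))
  gainCounter <- config@rootGeneCount
  states <- vector("list", nTips + tree$Nnode)
  states[[root]] <- rootGenome
  tipBias <- stats::setNames(rep(rootBias, nTips), tree$tip.label)
  logs <- list()
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]
    ch <- ord$edge[e, 2]
    t <- ord$edge.length[e]
    rates <- list(subst = config@substRate * eff$substMult[e],
                  gain = config@gainRate * eff$gainMult[e],
                  loss = config@lossRate * eff$lossMult[e],
                  dup = config@dupRate * eff$dupMult[e],
                  inv = config@inversionRate * eff$invMult[e],
                  transloc = config@translocationRate * eff$translocMult[e])
    res <- .evolveBranch(states[[p]], t, rates, eff$gcBias[e], config,
                         gainCounter)
    states[[ch]] <- res$genome
    gainCounter <- res$gainCounter
    if (nrow(res$events)) {
      lbl <- if (ch <= nTips) tree$tip.label[ch] else paste0("node", ch)
      res$events$branch <- lbl
      logs[[length(logs) + 1]] <- res$events
    }
    if (ch <= nTips) tipBias[tree$tip.label[ch]] <- eff$gcBias[e]
  }
  eventLog <- if (length(logs)) do.call(rbind, logs)[, c("branch", "event",
                                                         "detail")]
              else data.frame(branch = character(0), event = character(0),
                              detail = character(0), stringsAsFactors = FALSE)
  list(tips = stats::setNames(states[seq_len(nTips)], tree$tip.label),
       eventLog = eventLog, tipBias = tipBias)
}

# Assign tip gene ids and build the true ClusterSet.
.tipInventories <- function(core) {
  tips <- core$tips
  out <- lapply(names(tips), function(g) {
    n <- length(tips[[g]]$cluster)
    data.frame(genome_id = g,
               gene_id = paste0(g, "|g", zeroPad(seq_len(n), 4)),
               cluster = tips[[g]]$cluster,
               seq = tips[[g]]$seq, stringsAsFactors = FALSE)
  })
  names(out) <- names(tips)
  out
}

.trueClusterSet <- function(inventories, taxa) {
  m <- do.call(rbind, inventories)
  ClusterSet(data.frame(cluster_id = paste0("OC", zeroPad(m$cluster)),
                        genome_id = m$genome_id, gene_id = m$gene_id,
                        stringsAsFactors = FALSE),
             taxa = taxa)
}

#' Evolve gene content along a species tree
#'
#' Poisson gain, loss and duplication of genes along each branch. Every
#' extant gene traces back to a single root or gained ancestor;
#' duplications create same-cluster paralogs. Gene order and sequences are
#' evolved in the same pass; this function returns the content view.
#'
#' @param tree species tree (`phylo`).
#' @param config a [SimulationConfig]; `config@seed` seeds the process.
#' @return list with `inventories` (per-genome data.frame of gene_id and
#'   cluster), `clusters` (the true [ClusterSet]) and `eventLog`.
#' @export
evolveGeneContent <- function(tree, config) {
  set.seed(config@seed)
  core <- .simulateCore(tree, config)
  inv <- .tipInventories(core)
  list(inventories = lapply(inv, function(d) d[, c("gene_id", "cluster")]),
       clusters = .trueClusterSet(inv, tree$tip.label),
       eventLog = core$eventLog)
}

#' Evolve gene order along a species tree
#'
#' Same seeded process as [evolveGeneContent()]; returns the per-genome
#' gene orders (gene ids in chromosomal order).
#'
#' @inheritParams evolveGeneContent
#' @return named list of character vectors.
#' @export
evolveGeneOrder <- function(tree, config) {
  set.seed(config@seed)
  core <- .simulateCore(tree, config)
  lapply(.tipInventories(core), function(d) d$gene_id)
}

#' Evolve protein sequences along a species tree
#'
#' Same seeded process as [evolveGeneContent()]; returns the per-genome
#' proteomes. Substitution targets are drawn with the lineage's GC bias
#' applied to the {G,A,R,P} set, so biased lineages drift towards low (or
#' high) aminoGC.
#'
#' @inheritParams evolveGeneContent
#' @return named list of [Biostrings::AAStringSet].
#' @export
evolveSequences <- function(tree, config) {
  set.seed(config@seed)
  core <- .simulateCore(tree, config)
  lapply(.tipInventories(core), function(d)
    Biostrings::AAStringSet(stats::setNames(d$seq, d$gene_id)))
}
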