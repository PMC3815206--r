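#' Tree-based paralog resolution for one cluster
#'
#' Applies the four curation rules used when a cluster contains several
#' copies from one genome, judging each situation on the cluster's gene
#' tree:
#'
#' 1. When a genome's paralogs cluster together (they form a clade with no
#'    other genome's leaves, in the unrooted sense), the copy with the
#'    shortest terminal branch is retained (`keep_shortest_branch`; ties
#'    keep the lexicographically smallest gene id).
#' 2. Ingroup copies placed within the outgroup are removed
#'    (`remove_outgroup_copy`). The outgroup clade is taken as the minimal
#'    split side containing all outgroup leaves; if no such side exists the
#'    outgroup is irreparably mixed with the ingroup and an error is
#'    raised.
#' 3. When two or more paralogs of one genome sit at different positions in
#'    the ingroup tree, the whole cluster is removed (`remove_cluster`).
#' 4. When copies from the same outgroup species sit at different
#'    positions, all of that species' copies are removed
#'    (`remove_all_copies`).
#'
#' @param cluster data.frame with columns `genome_id`, `gene_id` (the
#'   cluster's members).
#' @param geneTree `phylo` gene tree; tip labels must be cluster gene ids
#'   (a subset of the members). Every multi-copy genome must have all of
#'   its copies in the tree.
#' @param ingroup character vector of ingroup genome ids.
#' @param outgroup character vector of outgroup genome ids (may be empty,
#'   in which case outgroup rules are skipped).
#' @param clusterId label used in the decision report.
#' @return list with `cluster` (pruned member data.frame; zero rows when
#'   the cluster was removed), `decisions` (data.frame: cluster_id, action,
#'   genome_id, genes, rule) and `removed` (logical).
#' @export
resolveParalogs <- function(cluster, geneTree, ingroup,
                            outgroup = character(), clusterId = "cluster") {
  ccAssert(all(c("genome_id", "gene_id") %in% names(cluster)),
           "cluster needs columns genome_id, gene_id")
  ccAssert(all(geneTree$tip.label %in% cluster$gene_id),
           "tree/cluster leaf mismatch: tree has leaves not in the cluster")
  mem <- cluster
  tr <- geneTree
  decisions <- list()
  note <- function(action, genome, genes, rule) {
    decisions[[length(decisions) + 1]] <<- data.frame(
      cluster_id = clusterId, action = action, genome_id = genome,
      genes = paste(sort(genes), collapse = ","), rule = rule,
      stringsAsFactors = FALSE)
  }
  dropFromTree <- function(tr, tips) {
    keep <- setdiff(tr$tip.label, tips)
    if (length(keep) < 2) return(NULL)
    ape::keep.tip(tr, keep)
  }
  genomeOf <- stats::setNames(mem$genome_id, mem$gene_id)
  # every multi-copy genome must be fully represented in the tree
  cnt <- table(mem$genome_id)
  multi <- names(cnt)[cnt > 1]
  for (g in multi) {
    genes <- mem$gene_id[mem$genome_id == g]
    ccAssert(all(genes %in% geneTree$tip.label),
             paste0("tree/cluster leaf mismatch: copies of ", g,
                    " missing from the gene tree"))
  }

  if (length(outgroup)) {
    ogLeaves <- tr$tip.label[genomeOf[tr$tip.label] %in% outgroup]
    if (length(ogLeaves) > 0 && length(ogLeaves) < length(tr$tip.label)) {
      es <- .edgeSplits(tr)
      tips <- tr$tip.label
      candidates <- c(es$side, lapply(es$side, function(s) setdiff(tips, s)))
      candidates <- Filter(function(s) all(ogLeaves %in% s), candidates)
      ccAssert(length(candidates) > 0,
               "outgroup is not monophyletic and cannot be rooted")
      ogClade <- candidates[[which.min(lengths(candidates))]]
      intruders <- setdiff(ogClade, ogLeaves)
      if (length(intruders)) {
        for (g in unique(genomeOf[intruders])) {
          genes <- intruders[genomeOf[intruders] == g]
          note("remove_outgroup_copy", g, genes,
               "ingroup copy placed within the outgroup")
        }
        mem <- mem[!mem$gene_id %in% intruders, , drop = FALSE]
        tr <- dropFromTree(tr, intruders)
      }
      # outgroup species with copies at different positions
      if (!is.null(tr)) {
        ogNow <- tr$tip.label[genomeOf[tr$tip.label] %in% outgroup]
        for (g in unique(genomeOf[ogNow])) {
          genes <- ogNow[genomeOf[ogNow] == g]
          if (length(genes) >= 2 && !.isUnrootedClade(tr, genes)) {
            note("remove_all_copies", g, genes,
                 "outgroup species copies at different positions")
            mem <- mem[!mem$gene_id %in% genes, , drop = FALSE]
            tr <- dropFromTree(tr, genes)
            if (is.null(tr)) break
          }
        }
      }
    }
  }

  removed <- FALSE
  cnt <- table(mem$genome_id[mem$genome_id %in% ingroup])
  for (g in names(cnt)[cnt > 1]) {
    genes <- mem$gene_id[mem$genome_id == g]
    inTree <- if (is.null(tr)) genes[genes %in% character(0)]
              else genes[genes %in% tr$tip.label]
    if (length(inTree) < 2) next
    if (!is.null(tr) && .isUnrootedClade(tr, inTree)) {
      bl <- vapply(inTree, function(tp) .terminalBranchLength(tr, tp),
                   numeric(1))
      o <- order(bl, inTree, method = "radix")
      keep <- inTree[o][1]
      drop <- setdiff(inTree, keep)
      note("keep_shortest_branch", g, drop,
           "paralogs clustered together; shortest branch retained")
      mem <- mem[!mem$gene_id %in% drop, , drop = FALSE]
      tr <- dropFromTree(tr, drop)
    } else {
      note("remove_cluster", g, mem$gene_id,
           "paralogs at different positions in the ingroup tree")
      mem <- mem[0, , drop = FALSE]
      removed <- TRUE
      break
    }
  }

  decisions <- if (length(decisions)) do.call(rbind, decisions)
               else data.frame(cluster_id = character(0),
                               action = character(0),
                               genome_id = character(0),
                               genes = character(0), rule = character(0),
                               stringsAsFactors = FALSE)
  rownames(mem) <- NULL
  list(cluster = mem, decisions = decisions, removed = removed)
}
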