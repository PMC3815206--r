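#' Reciprocal-best-hit clustering of proteomes
#'
#' A fallback clusterer so simulated or small datasets need no external
#' ortholog inference: every genome pair is scored all-vs-all with
#' `scoreFun`, mutual best hits become edges of a gene graph, and its
#' connected components are the clusters. Genes with no reciprocal best
#' hit form singleton clusters, so every gene of every proteome is
#' assigned to exactly one cluster. Ties are broken towards the
#' lexicographically smallest gene id, making the clustering deterministic.
#'
#' @param proteomes named list (genome id -> `AAStringSet` or named
#'   character vector; sequence names are gene ids, unique across the
#'   dataset).
#' @param scoreFun function(setA, setB) returning a genes(A) x genes(B)
#'   score matrix; defaults to [kmerScoreMatrix()].
#' @return a [ClusterSet] over the proteome genomes.
#' @export
rbhCluster <- function(proteomes, scoreFun = kmerScoreMatrix) {
  ccAssert(length(proteomes) >= 2, "need at least two proteomes")
  ccAssert(!is.null(names(proteomes)), "proteomes must be named by genome")
  proteomes <- lapply(proteomes, function(p) {
    p <- if (methods::is(p, "XStringSet")) as.character(p) else p
    p[order(names(p), method = "radix")]
  })
  genomeOf <- unlist(lapply(names(proteomes), function(g)
    stats::setNames(rep(g, length(proteomes[[g]])), names(proteomes[[g]]))))
  ccAssert(!anyDuplicated(names(genomeOf)),
           "gene ids must be unique across proteomes")
  gids <- sort(names(proteomes))
  # fast path for the default scorer: 3-mer counts once per genome
  kc <- if (identical(scoreFun, kmerScoreMatrix))
    lapply(proteomes, .kmerCounts) else NULL
  edges <- list()
  for (i in seq_len(length(gids) - 1)) {
    for (j in seq.int(i + 1, length(gids))) {
      A <- proteomes[[gids[i]]]
      B <- proteomes[[gids[j]]]
      S <- if (is.null(kc)) scoreFun(A, B)
           else kc[[gids[i]]] %*% t(kc[[gids[j]]])
      rownames(S) <- names(A)
      colnames(S) <- names(B)
      bestB <- apply(S, 1, which.max)   # first (lexicographic) on ties
      bestA <- apply(S, 2, which.max)
      mutual <- which(bestA[bestB] == seq_along(bestB))
      if (length(mutual))
        edges[[length(edges) + 1]] <- data.frame(
          from = names(A)[mutual], to = names(B)[bestB[mutual]],
          stringsAsFactors = FALSE)
    }
  }
  allGenes <- sort(names(genomeOf))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(allGenes), name = allGenes)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::add_edges(g, rbind(match(e$from, allGenes),
                                    match(e$to, allGenes)))
  }
  comp <- igraph::components(g)$membership
  sp <- split(allGenes, comp)
  sp <- sp[order(vapply(sp, min, ""))]
  members <- do.call(rbind, lapply(seq_along(sp), function(k)
    data.frame(cluster_id = paste0("RBH", zeroPad(k)),
               genome_id = unname(genomeOf[sp[[k]]]),
               gene_id = sp[[k]], stringsAsFactors = FALSE)))
  ClusterSet(members, taxa = gids)
}
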