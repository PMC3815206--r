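# Dataset assembly around the core simulator: annotations with synthetic
# coordinates, taxonomy from tree cuts, file output, and the rogue-lineage
# preset.

# Build a GenomeAnnotation from an inventory data.frame (gene_id, seq, in
# order). Genes are laid head-to-tail on one circular replicon ("chr"),
# 3*len+3 nt each with 50 bp spacers; with config@secondReplicon the last
# 20% of genes move to a linear replicon ("p1").
.inventoryAnnotation <- function(genomeIdStr, inv, secondReplicon = FALSE) {
  n <- nrow(inv)
  lens <- nchar(inv$seq) * 3L + 3L
  strands <- sample(c("+", "-"), n, replace = TRUE)
  repl <- rep("chr", n)
  if (secondReplicon && n >= 5) {
    cut <- floor(n * 0.8) + 1L
    repl[cut:n] <- "p1"
  }
  df <- do.call(rbind, lapply(split(seq_len(n), repl), function(idx) {
    starts <- 50L + c(0L, cumsum(lens[idx] + 50L))[seq_along(idx)]
    data.frame(i = idx, replicon = repl[idx][1], start = starts + 1L,
               end = starts + lens[idx], stringsAsFactors = FALSE)
  }))
  df <- df[order(df$i), ]
  repLens <- vapply(split(df$end, df$replicon), function(e) max(e) + 50,
                    numeric(1))
  gr <- GenomicRanges::GRanges(
    seqnames = df$replicon,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = strands[df$i])
  S4Vectors::mcols(gr)$gene_id <- inv$gene_id[df$i]
  S4Vectors::mcols(gr)$feature_type <- "CDS"
  S4Vectors::mcols(gr)$product <- "hypothetical protein"
  circ <- stats::setNames(names(repLens) == "chr", names(repLens))
  GenomeAnnotation(genomeIdStr, gr, repliconLengths = repLens,
                   circular = circ)
}

# Taxonomy strata from ultrametric tree cuts at three fixed depth
# fractions (order 0.3, family 0.55, genus 0.8 of the tree height):
# tips whose lineages have already diverged at the cut depth fall into
# different groups.
.taxonomyFromTree <- function(tree,
                              cuts = c(order = 0.3, family = 0.55,
                                       genus = 0.8)) {
  nTips <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(nTips)])
  pa <- rep(NA_integer_, nTips + tree$Nnode)
  pa[tree$edge[, 2]] <- tree$edge[, 1]
  groupAt <- function(d) {
    vapply(seq_len(nTips), function(tip) {
      node <- tip
      while (!is.na(pa[node]) && depth[pa[node]] > d) node <- pa[node]
      node
    }, integer(1))
  }
  lab <- function(ids, prefix) {
    paste0(prefix, as.integer(factor(ids, levels = unique(ids))))
  }
  data.frame(genome_id = tree$tip.label,
             genus = lab(groupAt(cuts["genus"] * height), "G"),
             family = lab(groupAt(cuts["family"] * height), "F"),
             order = lab(groupAt(cuts["order"] * height), "O"),
             stringsAsFactors = FALSE)
}

#' Simulate a complete ground-truthed dataset
#'
#' Runs the whole generative model under `config@seed`: species tree (or a
#' supplied one), gene gain/loss/duplication, genome rearrangement and
#' GC-biased sequence divergence; assembles per-genome annotations (with
#' synthetic coordinates on one circular replicon), proteomes, the true
#' ortholog clusters, a tree-cut taxonomy and the event log. The result is
#' a pure function of the configuration: equal seeds give byte-identical
#' datasets.
#'
#' @param config a [SimulationConfig].
#' @param tree optional species tree; simulated from the config when NULL.
#' @return a [SimulatedPangenome].
#' @export
simulateDataset <- function(config, tree = NULL) {
  set.seed(config@seed)
  if (is.null(tree))
    tree <- .yuleTree(config@nTaxa, config@birthRate)
  core <- .simulateCore(tree, config)
  inv <- .tipInventories(core)
  ann <- lapply(names(inv), function(g)
    .inventoryAnnotation(g, inv[[g]], config@secondReplicon))
  names(ann) <- names(inv)
  prot <- lapply(inv, function(d)
    Biostrings::AAStringSet(stats::setNames(d$seq, d$gene_id)))
  methods::new("SimulatedPangenome", config = config, tree = tree,
               annotations = ann, proteomes = prot,
               clusters = .trueClusterSet(inv, tree$tip.label),
               taxonomy = .taxonomyFromTree(tree),
               eventLog = core$eventLog,
               gcBiasRealized = core$tipBias)
}

#' Write a simulated dataset to a directory
#'
#' Emits, in the package's external dialects: one proteome FASTA per
#' genome, a combined gene table TSV, the true clusters as an
#' orthoMCL-style groups file, the species tree as Newick and the
#' taxonomy TSV. Output is deterministic: the same configuration yields
#' byte-identical files.
#'
#' @param sim a [SimulatedPangenome].
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeDataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (g in names(sim@proteomes)) {
    p <- file.path(outdir, paste0("proteome_", g, ".faa"))
    writeFasta(sim@proteomes[[g]], p)
    paths[paste0("proteome_", g)] <- p
  }
  paths["gene_tables"] <- writeGeneTable(sim@annotations,
                                         file.path(outdir, "gene_tables.tsv"))
  paths["clusters"] <- writeClusters(sim@clusters,
                                     file.path(outdir, "true_clusters.txt"))
  paths["tree"] <- writeNewick(sim@tree,
                               file.path(outdir, "species_tree.nwk"))
  paths["taxonomy"] <- writeTaxonomy(sim@taxonomy,
                                     file.path(outdir, "taxonomy.tsv"))
  invisible(paths)
}

#' Rogue-lineage preset
#'
#' The package's desk-scale analogue of the confound that motivates it:
#' a focal clade of related genomes evolves under strong AT bias
#' (gcBias -0.8), and a single fast-evolving lineage elsewhere in the tree
#' (3x substitution rate) convergently acquires the same bias. Gene
#' content and synteny carry no signal linking the rogue lineage to the
#' focal clade, so content/synteny metrics should keep them apart even
#' though their amino-acid compositions converge.
#'
#' The focal clade is the most distinct small clade of the tree (3-6 tips,
#' minimising the ratio of crown depth to stem branch length, so its
#' members are one another's closest relatives); the rogue is the tip
#' outside the clade with the greatest mean patristic distance to it.
#'
#' @param seed integer seed.
#' @param nTaxa taxa in the tree.
#' @param ... further arguments passed to [simulationConfig()].
#' @return list with `sim` (a [SimulatedPangenome]), `focalClade` (tip
#'   labels) and `rogue` (tip label).
#' @export
rogueLineagePreset <- function(seed = 101L, nTaxa = 12, ...) {
  set.seed(seed)
  tree <- .yuleTree(as.integer(nTaxa), 1)
  nTips <- length(tree$tip.label)
  sets <- .nodeTipSets(tree)
  depth <- ape::node.depth.edgelength(tree)
  stemLen <- rep(NA_real_, nTips + tree$Nnode)
  stemLen[tree$edge[, 2]] <- tree$edge.length
  inner <- (nTips + 2):(nTips + tree$Nnode)  # exclude root
  sizes <- lengths(sets[inner])
  ok <- inner[sizes >= 3 & sizes <= min(6, nTips - 3)]
  ccAssert(length(ok) > 0, "tree has no usable internal clade")
  crown <- vapply(ok, function(nd)
    max(depth[match(sets[[nd]], tree$tip.label)]) - depth[nd], numeric(1))
  pick <- ok[which.min(crown / stemLen[ok])]
  focal <- sets[[pick]]
  dmat <- stats::cophenetic(tree)
  outside <- setdiff(tree$tip.label, focal)
  meanD <- sort(colMeans(dmat[focal, outside, drop = FALSE]),
                decreasing = TRUE)
  rogue <- names(meanD)[1]
  cfg <- simulationConfig(
    nTaxa = nTaxa,
    lineageEffects = list(
      list(tips = focal, gcBias = -0.8),
      list(tips = rogue, substMult = 3, gcBias = -0.8)),
    seed = (seed + 54321L) %% 2147483647L, ...)
  list(sim = simulateDataset(cfg, tree = tree), focalClade = focal,
       rogue = rogue)
}
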