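Package: CladeCompare
Title: Comparative-Genomic Tests of Clade Membership: Gene Content,
    Synteny, Compositional Bias and Hypervariable Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether a divergent microbial genome truly
    belongs to a clade, beyond what a concatenated-alignment phylogeny can
    say. Implements ortholog-cluster curation (threshold filtering,
    pan-ortholog selection, gene-tree-based paralog resolution, discordance
    flagging), a gene-content similarity index with neighbour rankings,
    pairwise gene-order synteny against average normalized bit scores with
    taxonomic pair classes and outlier flagging, the aminoGC amino-acid
    compositional-bias statistic, and extraction plus translated (six-frame)
    comparison of hypervariable chromosomal regions. A genome-evolution
    simulator (gene gain/loss/duplication, rearrangement, per-lineage
    GC-biased sequence divergence on a birth tree) provides ground-truthed
    data so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    ape,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    igraph,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    withr,
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'CladeCompare-package.R'
    'RcppExports.R'
    'cli.R'
    'clustering.R'
    'composition.R'
    'discordance.R'
    'gene-content.R'
    'hvr-regions.R'
    'hvr-search.R'
    'io-clusters.R'
    'io-fasta.R'
    'io-newick.R'
    'io-tables.R'
    'pair-scan.R'
    'paralogs.R'
    'rbh.R'
    'scoring.R'
    'simulate-dataset.R'
    'simulate-genomes.R'
    'simulate-tree.R'
    'synteny.R'
    'tree-splits.R'
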