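---
title: "Testing clade membership with gene content, synteny and composition"
author: "CladeCompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing clade membership with gene content, synteny and composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CladeCompare)
```

## The problem

Concatenated-alignment phylogenies can group genomes for the wrong
reason. Lineages that independently evolved strong AT mutation bias shift
their protein composition in the same direction — towards amino acids
encoded by AT-rich codons — and fast-evolving, compositionally biased taxa
can then attract one another in a tree regardless of their true history
(long-branch attraction). The canonical case in marine microbiology is
whether the divergent isolate HIMB59 really belongs to the SAR11
(Pelagibacterales) clade: both have small, AT-rich genomes, and the answer
flips with the gene set and inference method used.

`CladeCompare` implements the lines of evidence that are *independent* of
sequence-composition artifacts, so that a claimed clade membership can be
cross-examined:

1. **Gene content.** For genomes `A`, `B` with ortholog-cluster sets
   `C(A)`, `C(B)`, the similarity is
   `S(A, B) = |C(A) ∩ C(B)| / min(|C(A)|, |C(B)|)`.
   A genome counts a cluster when it has at least one member in it; copy
   number is ignored (the index is defined over clusters, not genes), and
   singleton clusters count towards their genome's total. Ranking a focal
   genome's neighbours by `S` asks: are its closest gene-content
   relatives the clade it was placed in?
2. **Synteny against identity.** For each genome pair, protein identity
   is the average *normalized bit score* of the shared genes
   (`bits(A,B) / min(selfbits(A), selfbits(B))`, clipped to [0, 1]) and
   gene-order conservation is the *synteny fraction*: after restricting
   both gene orders to the shared genes, the fraction of shared genes
   that keep at least one of their adjacent shared genes ("same nearest
   neighbour"), orientation- and strand-free, with circular replicons
   closing the adjacency ring. Pairs are stratified into within-genus,
   within-family, within-order and between-orders classes; a taxon whose
   placement is real should be syntenically closer to its clade than to
   the background at a matched identity level.
3. **aminoGC.** The fraction of residues belonging to the amino acids
   whose codon families carry G or C in the first two codon positions:
   glycine (GGN), alanine (GCN), arginine (CGN) and proline (CCN). Gaps,
   stops and ambiguity codes are excluded from numerator and denominator.
   Low aminoGC is the protein-level fingerprint of AT mutational bias; a
   gene set whose aminoGC spread is wide is a gene set in which
   compositional attraction can override phylogenetic signal. Arginine is
   included by default although AGR codons exist; `gcSet = c("G","A","P")`
   computes the variant without it.
4. **Hypervariable regions.** A chromosomal interval is located by two
   anchoring features (for SAR11-like genomes, between the 23S and 5S
   rRNA genes; for genomes whose rRNA operon is colinear, between a
   tRNA-Ser and a tRNA-Ala), expanded by a flank (20 kb in the analyses
   this package was built for), and compared across genomes with a
   translated six-frame search at a strict E-value threshold (1e-10). If
   a genome's flank-defined region shares no translated similarity with
   the clade's hypervariable region, that region offers no support for
   membership.

Around these sit the curation steps that make cluster-based statistics
trustworthy: threshold filtering of ortholog clusters (minimum taxa,
maximum copies per genome, maximum cluster size), pan-ortholog selection
(exactly one copy in every genome), gene-tree-based paralog resolution and
discordance flagging.

## Paralog resolution rules

Given a cluster's gene tree, each genome with multiple copies receives
exactly one decision:

* copies that form a clade containing no other genome's leaves are
  *paralogs that clustered together*: the copy with the shortest terminal
  branch is kept (ties keep the lexicographically smallest gene id);
* ingroup copies placed inside the outgroup clade are removed; the
  outgroup clade is operationalised as the minimal unrooted split side
  containing all outgroup leaves, and an error is raised when no such
  side exists (outgroup hopelessly mixed);
* copies of one genome at different positions in the ingroup tree remove
  the whole cluster;
* copies of one outgroup species at different positions remove all of
  that species' copies.

"Clustered together" is deliberately the weakest reading — monophyly of
that genome's paralogs — so that the rule never removes more than the
text of the procedure demands.

Discordance flagging calls a gene tree discordant when it contains a
bipartition, supported at or above a configurable threshold (default
0.9; labels on a 0–100 scale are normalised), that is incompatible with
some bipartition of the species tree (all four side-intersections
non-empty). Unlabelled nodes count as unsupported: only strongly
supported conflict can flag a tree. The exact criterion used in the
literature varies; this realisation is the standard one and is
configurable rather than a claim about any particular study.

## The synthetic-data generator

Real ortholog sets for over a hundred genomes cannot ship with a package,
so every stage is exercised against a generator with known ground truth:

* a pure-birth (Yule) species tree (`simulateSpeciesTree`); expected
  root-to-tip depth `(1/λ) Σ_{k=2}^{n} 1/k`;
* gene gain, loss and duplication as per-gene Poisson processes along
  each branch (gains found new clusters; duplications create
  same-cluster paralogs);
* genome rearrangement by segmental inversions and translocations
  (per-genome Poisson processes);
* amino-acid sequence divergence in which each site substitutes with
  probability `1 − exp(−r·m·t)` (gene-specific gamma multiplier `m`) and
  the replacement is drawn from target frequencies tilted by a
  per-lineage GC bias `b ∈ [−1, 1]`: residues in {G, A, R, P} get weight
  `1 + b`, others 1. Negative `b` drives aminoGC down, emulating AT
  mutational bias at the protein level.

Default conditions (chosen once, used throughout the tests): 12 taxa,
birth rate 1, 100 root genes, gain/loss/duplication 0.05/0.08/0.02 per
gene per unit branch length, protein lengths 200 ± 50 aa, substitution
rate 0.4 per site per unit branch length, gamma shape 1.5 for among-gene
rate variation. Inversion and translocation rates (6 and 1 per genome per
unit branch length) were calibrated so that between-order pairs of the
default tree show substantially degraded gene order (synteny roughly
0.4–0.8) while close relatives stay near 1 — the regime in which gene
order conservation is actually informative; at much lower rates the
orientation-free synteny fraction saturates at 1 for every pair, because
a gene only stops counting as syntenic when *both* of its neighbours are
lost.

Gene-to-gene rate heterogeneity matters for the composition statistic:
lineage GC bias moves fast-evolving genes far and conserved genes hardly
at all, so a gene set evolved under heterogeneous lineage bias spreads
out in aminoGC — the property that makes "choose the less biased genes"
a meaningful curation step. With homogeneous rates the spread collapses
and the effect is invisible.

The generator emulates the *statistical* structure the comparisons
assume — clade-structured gene content, decaying synteny,
composition-shifted proteomes — not the biological texture of real
genomes: there are no intergenic regions or codon-level processes, no
horizontal transfer, no rate variation along a sequence, and proteins
are independent draws rather than homologs of real families. Passing
tests therefore validate the *computations* under known truth, not any
claim about real taxa.

### The rogue-lineage preset

`rogueLineagePreset()` reproduces the central confound at desk scale: a
tight focal clade (3–6 tips; chosen as the clade minimising crown depth
relative to stem length, so its members are one another's closest
relatives) evolves under `gcBias = −0.8`, and a single distant lineage
(the tip with the greatest mean patristic distance to the clade) evolves
at 3× the substitution rate with the same bias. Composition converges;
history does not. Gene content and synteny, computed from the ground
truth clusters, keep the rogue outside the clade's top-5 neighbours and
show no elevation of rogue-to-clade synteny over background — the
desk-scale analogue of finding that a compositionally attracted taxon is
not, in fact, a clade member. The elevation check is a one-sided rank
test read at a stringent α = 0.01 together with the fixed-seed
distributional check in the unit tests; with only a handful of
clade pairs the test statistic is coarse, and a lax α would flag
ordinary sampling noise as "elevation".

## Numerical and design choices

* **Coordinates.** The in-memory containers are Bioconductor-native:
  gene records live in a `GRanges` (1-based, closed) carried by
  `GenomeAnnotation`, with replicon length and circularity in its
  `Seqinfo`. The external TSV dialect and the `Region` class use 0-based
  half-open coordinates; GFF3 is converted at the boundary. Conversion
  is a bijection and is property-tested.
* **Gene order** is the sort by (start, end, gene_id); overlapping genes
  are permitted and ordered deterministically.
* **Scoring.** Pairwise protein scores come from Smith-Waterman local
  alignment (BLOSUM62, gap open 11 / extend 1) converted to bits with
  fixed Karlin-Altschul constants λ = 0.267, K = 0.041; the self-score
  is computed with the same aligner, so identical sequences score
  exactly 1 after normalization. A fast 3-mer count dot-product scorer
  backs reciprocal-best-hit clustering and large scans; it shares the
  self-normalization property.
* **Translated region search.** A deterministic seed-and-extend over all
  36 frame pairs: exact 3-mer words seed ungapped X-drop extensions
  (drop-off 18 raw ≈ 7 bits); E-values use
  `E = m·n·2^(−bits)` with `m`, `n` the summed translated lengths over
  the six frames of each region. Gapped extension is deliberately out of
  scope; at the E < 1e-10 threshold used for hypervariable-region
  comparisons, ungapped hits are what a conservative analysis should
  count. Seeds on a diagonal inside a previously extended hit are
  skipped, which both deduplicates and bounds the work.
* **Synteny neighbour rule.** "Same nearest neighbour" is read as
  "at least one adjacent shared gene conserved, on either side"
  (`side = "either"`); requiring both sides is available as a flag.
  The orientation-free reading makes a full reversal perfectly syntenic,
  which is the intended behaviour for an inversion-rich history.
* **Degenerate inputs.** Empty cluster sets, zero shared genes, regions
  shorter than one seed word, unknown strands and inverted intervals are
  errors, not silent zeros. Outlier flagging with degenerate (all-equal)
  categories flags nothing.
* **Determinism.** Every simulation is a pure function of its
  configuration (including the seed); tie-breaks throughout
  (shortest-branch ties, best-hit ties, hit ordering) are lexicographic.

## Problem sizes

The test suite and the acceptance script run the generator at 3–12 taxa
with 20–200 genes per genome, oracle cross-checks on up to 500 random
instances (permutations up to n = 200), and translated searches on
regions of 3–5 kb. These sizes were chosen so the full suite exercises
every code path in a few minutes while keeping Monte-Carlo standard
errors well below the effect sizes asserted.

## Known limitations

* The discordance criterion and the synteny neighbour rule are standard
  realisations of under-specified procedures; both are configurable and
  results should be reported with the setting used.
* The gene-content denominator uses the genome with fewer *clusters*,
  not fewer base pairs; for highly duplicated genomes the two readings
  can differ.
* The translated search is ungapped and word-exact; it will undercall
  weak similarity relative to a full tblastx with neighbourhood words
  and gapped extension. For the strict thresholds used here that bias is
  conservative.
* The simulator's taxonomy derives from fixed-depth tree cuts, which is
  a convenience, not a nomenclature model.
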