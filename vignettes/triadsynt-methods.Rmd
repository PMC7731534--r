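---
title: "Methods: synteny, fractionation and pseudochromosome analysis of mesohexaploid genomes"
author: "triadsynt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny, fractionation and pseudochromosome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

The Brassica diploids of U's triangle (*B. rapa*, AA; *B. nigra*, BB;
*B. oleracea*, CC) are mesohexaploids: their genomes descend from an
ancient whole-genome triplication followed by rediploidisation. Relative
to the crucifer ancestral gene-block catalogue (24 conserved blocks,
labelled A-X against *Arabidopsis thaliana*), each block is therefore
expected in three syntenic copies, and the three constituent paleogenomes
show differential gene loss ("fractionation"): a least-fractionated (LF),
a moderately (MF1) and a most fractionated (MF2) subgenome.

`triadsynt` implements the comparative stages of a chromosome-scale
analysis of such a genome as reusable, tested components:

1. a **synthetic mesohexaploid generator** with full ground truth;
2. **collinear chain detection** between two annotated genomes;
3. **Ks estimation** (Nei-Gojobori 1986) and **least-Ks ortholog calling**;
4. **block projection, retention profiling and LF/MF1/MF2 labelling**;
5. **genetic-map scaffold anchoring** into pseudochromosomes;
6. **k-mer genome-size estimation** and assembly statistics;
7. **homology-matrix based pseudochromosome renaming**.

Every analysis stage is exercised against the generator, whose planted
truth (subgenome of every gene, ortholog pairing, inversion intervals,
scaffold order and orientation) acts as the oracle.

# The synthetic genome generator

`simulate_mesohexaploid()` composes the elementary operations
(`build_ancestral_genome()`, `triplicate_and_fractionate()`,
`shuffle_blocks_into_chromosomes()`, `plant_inversions()`,
`evolve_sequences()`, `add_specific_genes()`,
`build_chromosome_sequences()`, `fragment_and_map()`). Its defaults are
the package's reference study conditions:

* 24 ancestral blocks of 50 genes (300 codons per CDS), giving a
  1,200-gene reference genome laid block-contiguously over 5 reference
  chromosomes;
* retention rates 0.55 / 0.45 / 0.40 for LF / MF1 / MF2, applied as
  independent Bernoulli losses per gene and paleogenome — the simplest
  model that reproduces differential retention;
* 8 target chromosomes assembled from contiguous segments of each
  paleogenome's block sequence (ancestral adjacency is preserved inside a
  segment, which is what makes subgenome recovery learnable), with one
  gene-free centromeric stretch per chromosome;
* 3 planted inversions on 3 distinct chromosomes, each inverting the
  central ~40% of one block copy so that forward synteny flanks the
  inverted run on both sides;
* planted synonymous divergences Ks = 0.1 for ortholog pairs and
  Ks = 0.4 for the other paleogenome copies, so that the least-Ks rule
  has a learnable signal (`ks_ortholog < ks_paralog`);
* 200 lineage-specific genes with no reference counterpart;
* a 15-scaffold fragmentation plan (five chromosomes stay single
  scaffolds; the others split into 2, 3 and 4 pieces) plus one
  marker-free organelle-like scaffold, 30 markers per chromosome with
  30 bp tags, and a genetic map accumulating 0.4 cM/kb suppressed
  10-fold inside centromeres.

Intergenic spacers are geometric (mean 200 bp, minimum 50 bp);
coordinates are 0-based half-open internally and 1-based on GFF3/AGP
emission. All randomness flows from one master seed through named
per-operation streams, so identical seeds give byte-identical output.

**Sequence evolution.** `DivergenceSpec` carries synonymous distances
only, so substitutions are placed exclusively at synonymous sites: each
codon is replaced by a random synonymous neighbour with probability
$p_S \cdot S_c$, where $S_c$ is the codon's fractional synonymous site
count and $p_S = \tfrac{3}{4}(1 - e^{-4K_s/3})$ inverts the Jukes-Cantor
correction. The expected NG86 estimate therefore recovers the planted
Ks, no internal stop codon can arise, and peptides of homologs stay
identical (Ka = 0).

**What the generator does not emulate.** No amino-acid divergence, no
transposable elements or repeat families, no read-level errors (the
k-mer histogram is drawn from the mixture model directly), no tandem
duplications, uniform codon usage, and exact marker tags. Passing
recovery tests therefore demonstrates correctness of the algorithms
under the stated statistical structure, not robustness to every artifact
of real assemblies; the one-mismatch marker mode and the configurable
anchor-similarity threshold are the knobs a real-data application would
touch first.

# Anchor scoring and collinear chains

`score_gene_pairs()` stands in for an all-against-all protein search:
CDS are translated and compared by shared peptide 5-mers; similarity is
the shared count over the smaller k-mer set and pairs under the
threshold (default 0.2) are excluded. With synonymous-only divergence
this surrogate is near-lossless; it is deliberately free of external
aligner dependencies, and the threshold is exposed.

`chain_anchors()` finds maximal-scoring collinear runs by dynamic
programming under MCScanX-style parameters (`match_score = 50`,
`match_size = 5`, `gap_penalty = -1`, `max_gaps = 25`): each anchor adds
`match_score`; a step between consecutive anchors advances both genomes'
gene ranks and costs `gap_penalty` times the larger advance; steps
skipping more than `max_gaps` intervening ranks are forbidden. Gaps are
measured in gene-rank units, not bp, making chains robust to intergenic
length variation. Ten collinear anchors at unit spacing thus score
$10 \times 50 - 9 = 491$. Chains are extracted greedily — the best chain
(score, then anchor count, then lexicographically smallest anchor
sequence) is reported and its anchors removed, in both orientations,
until no chain with `match_size` anchors remains. On small instances the
extraction provably equals exhaustive enumeration (a property test);
under exact score ties the decomposition is deterministic but depends on
the canonical anchor order. Chains never bridge anchor deserts larger
than `max_gaps` — centromeres need no special handling.

`detect_inversions()` reports every `-` chain flanked within `max_gaps`
target ranks on both sides by `+` anchors of the same chromosome pair,
innermost-first for nested cases. Note that the flanking `+` chain
usually captures one anchor of the inverted run (a single inverted
anchor is still collinear with the flanks), so an inversion of $g$ genes
typically yields a `-` chain of $g - 1$ anchors; planted inversions must
be comfortably larger than `match_size` to be recoverable.

# Ks and ortholog calling

`ks_ng86()` implements Nei-Gojobori (1986) with fractional site counting
and equal weighting of mutational paths for multi-difference codons;
paths through stop codons are excluded (if every path is blocked, stop
crossings count as nonsynonymous). Proportions are corrected with
$K = -\tfrac{3}{4}\ln(1 - \tfrac{4p}{3})$; saturation ($p \ge 3/4$) is
flagged, never clipped. The estimator is validated two ways: against an
independent path-enumeration oracle on codon pairs, and as a round-trip
against the generator (unbiased within 10% at Ks $\le$ 0.5 for
300-codon genes).

`call_orthologs()` applies the least-Ks rule within chains: for each
target gene the syntenic partner with the smallest defined Ks is
flagged, ties resolved toward the smallest reference gene id and logged;
mutual minima are flagged separately and constitute the ortholog set
used in recovery tests. Restricting candidates to within-chain pairs is
one of two defensible readings of "least Ks among all combinations"; the
all-significant-pairs alternative would only add partners outside
syntenic context and is intentionally not the default.

# Block projection and subgenome labelling

`project_blocks()` transfers reference block labels along chains,
splitting any chain that crosses a block boundary at the boundary, and
merges same-label chains on the same target chromosome whose intervals
lie within `merge_gap` (default 50) gene ranks — so the 2-3 chains that
an inversion carves out of one block copy re-unite into a single copy.
On clean triplicated input every label yields three copies.

`label_subgenomes()` partitions copies into paleogenome groups using two
facts: a paleogenome contributes at most one copy per label, and
reshuffling preserves ancestral adjacency inside segments. The problem
is solved exactly by dynamic programming along the ancestral label
sequence: the state at label $k$ is the injective assignment of label
$k$'s copies to the three groups, and transitions reward chromosome
adjacencies between copies of consecutive labels that land in the same
group. Because two paleogenomes occasionally break at the same ancestral
position, several assignments can tie on adjacency; all tied optima are
enumerated (bounded at 512) and the assignment with the most homogeneous
within-group retention rates wins. Copies in excess of three per label
(fragments of a split copy) inherit a group from their chromosome
neighbourhood afterwards, the larger fragment having driven the DP.
Groups are finally ranked by total retained genes: LF $\ge$ MF1 $\ge$
MF2, ties broken deterministically and flagged. Across seeded replicates
at the default rates the ranking is recovered essentially always; the
residual per-copy errors sit exactly at tied cut points, where adjacency
carries no information and retention noise must decide.

`retention_profile()` computes, for every reference gene, the fraction
of genes in a window of 500 flanking genes (250 per side, truncated at
chromosome ends) with a retained syntenic homolog per subgenome — all
syntenic pairs count as retention evidence, not only least-Ks pairs,
since MF copies are by construction not the least-Ks partner. At desk
scale the 500-gene window exceeds a 240-gene reference chromosome, so
the profile degrades to full-chromosome windows with a warning; the
window semantics are still exercised by smaller-window tests.
`find_lineage_specific_genes()` reports the complement of the anchored
gene set.

# Scaffold anchoring

`locate_markers()` does exact (optionally one-mismatch) tag search on
both strands, through a constant-width dictionary scan; a marker is
placed only if it matches exactly one locus genome-wide, multi-locus
markers are dropped and logged. Tags being exact in the generator, an
alignment heuristic would add dependencies without adding signal.
`assign_scaffolds()` uses majority vote over linkage groups with
`min_markers = 2`; `order_and_orient()` orders scaffolds by median
marker cM (ties by scaffold id, logged) and orients each by the sign of
the Spearman correlation between cM and bp within the scaffold
(single-marker scaffolds default to `+` and are flagged
"orientation-unknown"). The layout is emitted as AGP v2.1 with fixed
100 bp `U` gaps. `detect_misassembly()` flags scaffolds spanning two
linkage groups, or whose cM sequence runs against its dominant monotone
trend more than `tolerance = 2` times — enough slack to absorb local
genotyping noise without masking real chimeras.

# K-mer statistics

`build_kmer_histogram()` counts canonical k-mers (lexicographic minimum
of k-mer and reverse complement). `estimate_genome_size()` is a
transparent valley/peak estimator: the valley is the first upturn of the
multiplicity spectrum, the peak the modal multiplicity above it (ties
toward lower multiplicity), and the estimate is the k-mer mass above the
valley divided by the peak depth. The design trades the sophistication
of parametric spectrum fitting for a dependency-free closed form whose
accuracy contract is the generator round-trip (within 5% at 40x
coverage, 1% error); it is scale-equivariant in the counts and
coverage-invariant up to peak discretisation. Heterozygosity and repeat
decomposition are out of scope. `assigned_fraction()` encodes the
assigned-length over genome-size convention (percentage truncated, not
rounded, to one decimal), which absorbs both quoted precisions of a
genome-size estimate.

# Pseudochromosome nomenclature

`build_homology_matrix()` sums reference-side chain spans per
chromosome pair after merging overlaps on the reference (rows can never
exceed 100%); stretch lengths are measured on the reference side, and
cells carry bp plus percent of the reference chromosome.
`parse_homology_table()` / `write_homology_table()` round-trip the
printed-table dialect so a published homology grid can be used as
direct input; `inst/extdata/brassica_homology_table.tsv` is a
transcription of such a grid for the *B. rapa* (A01-A10) versus
*B. nigra* (B01-B08) comparison — the bp and percentage values are
transcribed verbatim, while the assignment of cells to target columns,
which the flattened source table does not preserve, was reconstructed to
satisfy the published naming narrative and is synthetic in that limited
sense.

`assign_names()` names target chromosomes by maximum homology. A naive
per-target argmax cannot guarantee an injective naming (two targets may
prefer the same reference), so the default is a global maximum-weight
one-to-one matching (exact subset dynamic programming, validated against
exhaustive search up to 8 targets x 10 references); unmatched references
are reported as excluded, and any target whose matched name differs from
its per-target argmax is logged as a forced exception rather than
silently renamed. Where a published procedure excluded surplus reference
chromosomes a priori, the `exclude` argument reproduces that convention;
by default exclusions fall out of the matching.

# Problem sizes, tolerances and seeds

The test-suite and acceptance runs use the generator defaults above
(about 1,800 target genes, 2.3 Mb of target sequence, 240 markers, 15
scaffolds), sizes chosen so the full pipeline runs in minutes on one
core while keeping every per-stage signal (binomial retention contrasts,
Ks separation, marker density) comfortably above its decision threshold.
Stochastic recovery tests fix their seeds and state their tolerances in
units of the underlying noise (binomial standard deviations, fractions
of the planted value); exhaustive oracles replace tolerances wherever
enumeration is feasible (chains at $\le$ 12 anchors, matchings at
$\le 8 \times 10$, codon paths).

# Known limitations

* The anchor-similarity surrogate presumes conserved peptides; at high
  Ka it would need recalibration against a real aligner.
* Greedy chain extraction is order-dependent under exact score ties;
  only the tie-break, not the score, is affected.
* Subgenome labelling relies on preserved local ancestral adjacency; a
  genome shattered below the block scale would leave the DP without
  signal, and copies at tied cut points are resolved by noisy retention
  rates.
* The genome-size estimator requires a detectable non-error peak and
  underestimates repeat-rich genomes, as all unique-k-mer methods do.
* `parse_homology_table()` trusts its input's percentages unless
  reference lengths are supplied for cross-checking.
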