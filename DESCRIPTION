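Package: triadsynt
Title: Synteny, Fractionation and Pseudochromosome Tools for Mesohexaploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for the comparative analysis of
    mesohexaploid plant genomes such as the Brassica species of U's
    triangle. Provides a synthetic mesohexaploid genome generator with
    known ground truth (whole-genome triplication of an ancestral
    gene-block catalogue, differential subgenome fractionation, block
    reshuffling, planted inversions, scaffold fragmentation and a genetic
    map with centromeric recombination suppression); collinear chain
    detection by dynamic programming with MCScanX-style parameters;
    Nei-Gojobori (1986) synonymous substitution (Ks) estimation and
    least-Ks ortholog calling; triplicated gene-block projection with
    sliding-window retention profiling and LF/MF1/MF2 subgenome
    labelling; genetic-map based scaffold anchoring into
    pseudochromosomes with AGP output; k-mer histogram construction and
    genome-size estimation; and homology-matrix based pseudochromosome
    renaming by maximum-weight matching.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
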