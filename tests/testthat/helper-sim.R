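# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# The reference study conditions: 24 blocks x 50 genes, retention
# 0.55/0.45/0.40, Ks 0.1 vs 0.4, 8 chromosomes, 3 planted inversions,
# 15 scaffolds (5 single-scaffold chromosomes + 1 organelle).
shared_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- simulate_mesohexaploid(seed = 2024)
  }
  .fixture_cache$sim
}

shared_chains <- function() {
  if (is.null(.fixture_cache$chains)) {
    sim <- shared_sim()
    anchors <- score_gene_pairs(sim$reference$cds, sim$target$cds)
    .fixture_cache$anchors <- anchors
    .fixture_cache$chains <- chain_anchors(anchors, sim$reference$genes,
                                           sim$target$genes)
  }
  .fixture_cache$chains
}

shared_anchors <- function() {
  shared_chains()
  .fixture_cache$anchors
}

shared_calls <- function() {
  if (is.null(.fixture_cache$calls)) {
    sim <- shared_sim()
    .fixture_cache$calls <- call_orthologs(shared_chains(), sim$reference$cds,
                                           sim$target$cds)
  }
  .fixture_cache$calls
}

shared_copies <- function() {
  if (is.null(.fixture_cache$copies)) {
    sim <- shared_sim()
    ref_blocks <- data.frame(gene_id = sim$reference$genes$gene_id,
                             block = sim$reference$genes$block,
                             stringsAsFactors = FALSE)
    .fixture_cache$copies <- project_blocks(shared_chains(), ref_blocks,
                                            sim$target$genes)
  }
  .fixture_cache$copies
}

table2_path <- function() {
  system.file("extdata", "brassica_homology_table.tsv", package = "triadsynt")
}
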