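#' Simulate a mesohexaploid genome pair with ground truth
#'
#' End-to-end generator: builds an ancestral gene-block catalogue,
#' triplicates and fractionates it into three paleogenomes, reshuffles the
#' block copies into target chromosomes, plants segmental inversions,
#' inserts lineage-specific genes, evolves coding sequences so that
#' ortholog pairs sit at `ks_ortholog` and paralog copies at `ks_paralog`,
#' assembles chromosome sequences for both genomes, fragments the target
#' into scaffolds and samples a genetic-marker map with centromeric
#' recombination suppression. Every stochastic choice is recorded in the
#' returned truth tables, which downstream recovery tests compare against.
#'
#' The defaults are the package's reference study conditions: 24 blocks of
#' 50 genes, retention rates 0.55/0.45/0.40, Ks 0.1 (orthologs) versus 0.4
#' (paralogs), 8 target and 5 reference chromosomes, 3 planted inversions,
#' and a 15-scaffold fragmentation plan (five single-scaffold chromosomes;
#' one marker-free organelle scaffold).
#'
#' @param n_blocks,genes_per_block,cds_codons Ancestral catalogue (see
#'   [build_ancestral_genome()]).
#' @param retention Retention rates LF/MF1/MF2.
#' @param n_chrom,n_ref_chrom Target and reference chromosome counts.
#' @param n_inversions Planted inversions (distinct chromosomes).
#' @param inversion_min_genes Minimum surviving genes a block copy needs to
#'   host an inversion.
#' @param n_specific Lineage-specific genes inserted into the target.
#' @param ks_ortholog,ks_paralog Planted synonymous divergences.
#' @param scaffold_plan Scaffolds per target chromosome (length `n_chrom`).
#' @param markers_per_chrom,centromere_suppression,organelle_scaffold
#'   Genetic-map parameters (see [fragment_and_map()]).
#' @param seed Master seed; every operation derives its own stream from it.
#' @param sequences Assemble bp-level sequences, scaffolds and markers?
#'   (`FALSE` gives a fast gene-level simulation for layout-only studies.)
#' @return An object of class `mesohexaploid_sim`: a list with `reference`
#'   (gene table, `cds`, `blocks`, optional `seqs`), `target` (gene table,
#'   `cds`, optional `seqs` and `centromeres`), `scaffolds`, `markers`,
#'   `truth` (subgenome/block per gene, ortholog pairs, inversions,
#'   scaffold placements, marker positions, genome size) and `params`.
#' @export
simulate_mesohexaploid <- function(n_blocks = 24, genes_per_block = 50,
                                   cds_codons = 300,
                                   retention = c(0.55, 0.45, 0.40),
                                   n_chrom = 8, n_ref_chrom = 5,
                                   n_inversions = 3, inversion_min_genes = 15,
                                   n_specific = 200,
                                   ks_ortholog = 0.1, ks_paralog = 0.4,
                                   scaffold_plan = c(1, 1, 1, 1, 1, 2, 3, 4),
                                   markers_per_chrom = 30,
                                   centromere_suppression = 0.1,
                                   organelle_scaffold = TRUE,
                                   seed = 1, sequences = TRUE) {
  params <- as.list(environment())

  anc <- build_ancestral_genome(n_blocks, genes_per_block, cds_codons, seed)
  fr <- triplicate_and_fractionate(anc, retention, seed)
  layout <- shuffle_blocks_into_chromosomes(fr, n_chrom, seed)
  if (n_inversions > 0) {
    layout <- plant_inversions(layout, n_inversions, seed,
                               min_genes = inversion_min_genes)
  }
  evo <- evolve_sequences(layout, anc, ks_ortholog, ks_paralog, seed)
  sp <- add_specific_genes(layout, n_specific, cds_codons, seed)
  layout <- sp$layout
  tgt_cds <- c(evo$tgt_cds, sp$cds)

  # reference genome: ancestral genes laid block-contiguously over
  # n_ref_chrom chromosomes
  blocks_per_ref <- rep(ceiling(n_blocks / n_ref_chrom), n_ref_chrom)
  over <- sum(blocks_per_ref) - n_blocks
  if (over > 0) {
    blocks_per_ref[seq_len(over)] <- blocks_per_ref[seq_len(over)] - 1L
  }
  ref_chrom_of_block <- rep(sprintf("R%02d", seq_len(n_ref_chrom)),
                            blocks_per_ref)
  ref_genes <- anc$genes
  ref_genes$chrom <- ref_chrom_of_block[match(ref_genes$block,
                                              anc$blocks$label)]
  ref_genes$rank <- stats::ave(seq_len(nrow(ref_genes)), ref_genes$chrom,
                               FUN = seq_along)
  ref_genes$strand <- "+"

  tgt_genes <- layout$genes
  tgt_genes$rank <- tgt_genes$index

  reference <- list(genes = ref_genes, cds = evo$ref_cds,
                    blocks = anc$blocks)
  target <- list(genes = tgt_genes, cds = tgt_cds)
  scaffolds <- NULL
  markers <- NULL
  truth_scaffolds <- NULL
  truth_markers <- NULL
  genome_size <- NA_real_

  if (sequences) {
    # target chromosomes (with centromeres), then scaffolds and the map
    ref_layout <- structure(list(
      genes = data.frame(ref_genes[, c("gene_id", "block")],
                         anc_id = ref_genes$gene_id,
                         rank_in_block = ref_genes$rank_in_block,
                         subgenome = NA_character_,
                         chrom = ref_genes$chrom,
                         index = ref_genes$rank,
                         strand = "+", stringsAsFactors = FALSE),
      centromeres = data.frame(chrom = character(0), after_index = integer(0)),
      n_chrom = n_ref_chrom, seed = seed
    ), class = "genome_layout")
    ref_set <- build_chromosome_sequences(ref_layout, evo$ref_cds,
                                          seed = derive_seed(seed, "refseq"))
    tgt_set <- build_chromosome_sequences(layout, tgt_cds, seed = seed)
    fm <- fragment_and_map(tgt_set, scaffold_plan,
                           n_markers = markers_per_chrom,
                           centromere_suppression = centromere_suppression,
                           organelle_scaffold = organelle_scaffold,
                           seed = seed)
    ref_bp <- ref_set$genes[match(ref_genes$gene_id, ref_set$genes$gene_id), ]
    ref_genes$start0 <- ref_bp$start0
    ref_genes$end0 <- ref_bp$end0
    tgt_bp <- tgt_set$genes[match(tgt_genes$gene_id, tgt_set$genes$gene_id), ]
    tgt_genes$start0 <- tgt_bp$start0
    tgt_genes$end0 <- tgt_bp$end0
    reference$genes <- ref_genes
    reference$seqs <- ref_set$seqs
    target$genes <- tgt_genes
    target$seqs <- tgt_set$seqs
    target$centromeres <- tgt_set$centromeres
    scaffolds <- fm$scaffolds
    markers <- fm$markers
    truth_scaffolds <- fm$scaffold_truth
    truth_markers <- fm$marker_truth
    genome_size <- tgt_set$genome_size
  }

  truth <- list(
    genes = tgt_genes[, intersect(c("gene_id", "anc_id", "block", "subgenome",
                                    "chrom", "index", "strand"),
                                  names(tgt_genes))],
    orthologs = evo$orthologs,
    inversions = layout$inversions,
    segments = layout$segments,
    centromeres = layout$centromeres,
    scaffolds = truth_scaffolds,
    markers = truth_markers,
    specific_genes = names(sp$cds),
    genome_size = genome_size
  )
  structure(list(reference = reference, target = target,
                 scaffolds = scaffolds, markers = markers,
                 truth = truth, params = params),
            class = "mesohexaploid_sim")
}

#' @export
print.mesohexaploid_sim <- function(x, ...) {
  cat(sprintf("Synthetic mesohexaploid: %d target genes on %d chromosomes; %d reference genes\n",
              nrow(x$target$genes), x$params$n_chrom, nrow(x$reference$genes)))
  cat(sprintf("  retention LF/MF1/MF2 = %s; Ks ortholog/paralog = %g/%g; %d inversion(s)\n",
              paste(x$params$retention, collapse = "/"),
              x$params$ks_ortholog, x$params$ks_paralog,
              nrow(x$truth$inversions)))
  if (!is.null(x$scaffolds)) {
    cat(sprintf("  %d scaffold(s), %d marker(s), genome size %.0f bp\n",
                length(x$scaffolds), nrow(x$markers), x$truth$genome_size))
  }
  invisible(x)
}
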