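# File emission for simulated genomes: FASTA, GFF3, marker/truth TSVs and
# a config JSON capturing every generator parameter.

gene_table_to_gff3 <- function(genes, path, source = "triadsynt") {
  stopifnot(all(c("gene_id", "chrom", "start0", "end0", "strand") %in%
                  names(genes)))
  mk <- function(type, id, parent = NA_character_) {
    gr <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = genes$start0 + 1L, end = genes$end0),
      strand = genes$strand
    )
    S4Vectors::mcols(gr)$source <- source
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$phase <- NA_integer_
    S4Vectors::mcols(gr)$ID <- id
    S4Vectors::mcols(gr)$Parent <- parent
    gr
  }
  g <- mk("gene", genes$gene_id)
  m <- mk("mRNA", paste0(genes$gene_id, ".1"), genes$gene_id)
  cds <- mk("CDS", paste0(genes$gene_id, ".1.cds"), paste0(genes$gene_id, ".1"))
  S4Vectors::mcols(cds)$phase <- 0L
  all <- c(g, m, cds)
  all <- all[order(as.character(GenomicRanges::seqnames(all)),
                   GenomicRanges::start(all))]
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

read_gene_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  data.frame(
    gene_id = S4Vectors::mcols(gr)$ID,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a simulated genome pair to disk
#'
#' Emits genome and CDS FASTA, gene-model GFF3 (gene/mRNA/CDS features,
#' 1-based), scaffold FASTA, marker TSV (`marker_id`, `lg`, `cM`,
#' `tag_seq`), truth tables as TSV, and a config JSON capturing every
#' generator parameter.
#'
#' @param sim A `mesohexaploid_sim` built with `sequences = TRUE`.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "mesohexaploid_sim"))
  if (is.null(sim$target$seqs)) {
    stop_invalid("simulation was built with sequences = FALSE")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  write_fasta(sim$reference$seqs, p("reference_genome.fasta"))
  write_fasta(sim$target$seqs, p("target_genome.fasta"))
  write_fasta(sim$reference$cds, p("reference_cds.fasta"))
  write_fasta(sim$target$cds, p("target_cds.fasta"))
  write_fasta(sim$scaffolds, p("scaffolds.fasta"))
  gene_table_to_gff3(sim$reference$genes, p("reference_genes.gff3"))
  gene_table_to_gff3(sim$target$genes, p("target_genes.gff3"))
  tsv <- function(df, name) {
    write.table(df, p(name), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tsv(sim$markers, "markers.tsv")
  tsv(sim$truth$genes, "truth_genes.tsv")
  tsv(sim$truth$orthologs, "truth_orthologs.tsv")
  tsv(sim$truth$inversions, "truth_inversions.tsv")
  tsv(sim$truth$scaffolds, "truth_scaffolds.tsv")
  tsv(sim$truth$markers, "truth_markers.tsv")
  cfg <- sim$params
  cfg$genome_size <- sim$truth$genome_size
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
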