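#' Evolve coding sequences for a synthetic genome pair
#'
#' Produces the coding sequences of the target (mesohexaploid) genome from
#' the ancestral catalogue. The reference genome keeps the ancestral
#' sequences. For every ancestral gene with at least one surviving copy, one
#' surviving copy is designated the true ortholog and diverged from the
#' reference at `ks_ortholog`; the remaining copies diverge at
#' `ks_paralog`. Substitutions are synonymous and placed per site so that
#' the expected NG86 estimate recovers the planted value; no internal stop
#' codons are ever introduced.
#'
#' @param layout A `genome_layout`.
#' @param anc The `ancestral_genome` the layout derives from.
#' @param ks_ortholog Expected synonymous distance of ortholog pairs
#'   (`0 <= ks_ortholog < ks_paralog`).
#' @param ks_paralog Expected synonymous distance of the non-ortholog
#'   paleogenome copies from the reference lineage.
#' @param seed Integer seed.
#' @return A list with `tgt_cds` (named character vector over the layout's
#'   genes), `ref_cds` (the ancestral sequences), and `orthologs` (truth
#'   table: `ref_gene`, `tgt_gene`).
#' @export
evolve_sequences <- function(layout, anc, ks_ortholog = 0.1, ks_paralog = 0.4,
                             seed = 1) {
  stopifnot(inherits(layout, "genome_layout"), inherits(anc, "ancestral_genome"))
  if (ks_ortholog < 0 || ks_paralog < 0) stop_invalid("ks values must be >= 0")
  if (ks_ortholog >= ks_paralog) {
    stop_invalid("ks_ortholog must be strictly less than ks_paralog")
  }
  genes <- layout$genes
  with_op_seed(seed, "evolve_sequences", {
    # designate one surviving copy per ancestral gene as the true ortholog
    by_anc <- split(genes$gene_id, genes$anc_id)
    designated <- vapply(by_anc, function(ids) {
      ids[[sample.int(length(ids), 1L)]]
    }, character(1))
    orthologs <- data.frame(ref_gene = names(designated),
                            tgt_gene = unname(designated),
                            stringsAsFactors = FALSE)
    is_ortho <- genes$gene_id %in% designated
    tgt_cds <- setNames(character(nrow(genes)), genes$gene_id)
    for (i in seq_len(nrow(genes))) {
      ks <- if (is_ortho[i]) ks_ortholog else ks_paralog
      tgt_cds[[genes$gene_id[i]]] <- mutate_synonymous(anc$cds[[genes$anc_id[i]]], ks)
    }
    list(tgt_cds = tgt_cds, ref_cds = anc$cds, orthologs = orthologs)
  })
}
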