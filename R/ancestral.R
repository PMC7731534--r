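#' Build an ancestral genome of labelled gene blocks
#'
#' Constructs the ancestral gene-block catalogue that the synthetic
#' mesohexaploid is triplicated from: an ordered set of up to 26 blocks
#' labelled `A`, `B`, ... (the crucifer A-X convention), each holding a
#' run of genes with random coding sequences.
#'
#' @param n_blocks Number of blocks (1-26; default 24, the crucifer A-X
#'   catalogue).
#' @param genes_per_block Either a single count applied to every block or a
#'   vector of per-block counts (all `>= 1`).
#' @param cds_codons CDS length per gene, in codons.
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return An object of class `ancestral_genome`: a list with `blocks`
#'   (data frame of `label`, `n_genes`), `genes` (data frame of `gene_id`,
#'   `block`, `rank_in_block`, `rank`), and `cds` (named character vector).
#' @examples
#' anc <- build_ancestral_genome(n_blocks = 3, genes_per_block = 5, seed = 1)
#' anc$blocks
#' @export
build_ancestral_genome <- function(n_blocks = 24, genes_per_block = 50,
                                   cds_codons = 300, seed = 1) {
  if (n_blocks <= 0) stop_invalid("n_blocks must be positive")
  if (n_blocks > 26) stop_invalid("n_blocks must be <= 26 (single-letter labels)")
  if (length(genes_per_block) == 1L) {
    genes_per_block <- rep(genes_per_block, n_blocks)
  }
  if (length(genes_per_block) != n_blocks) {
    stop_invalid("genes_per_block must have length 1 or n_blocks")
  }
  if (any(genes_per_block < 1)) stop_invalid("per-block gene counts must be >= 1")
  labels <- LETTERS[seq_len(n_blocks)]
  blocks <- data.frame(label = labels, n_genes = as.integer(genes_per_block),
                       stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = unlist(lapply(seq_len(n_blocks), function(i) {
      sprintf("anc_%s%03d", labels[i], seq_len(genes_per_block[i]))
    })),
    block = rep(labels, genes_per_block),
    rank_in_block = unlist(lapply(genes_per_block, seq_len)),
    stringsAsFactors = FALSE
  )
  genes$rank <- seq_len(nrow(genes))
  cds <- with_op_seed(seed, "ancestral_cds", {
    setNames(vapply(seq_len(nrow(genes)), function(i) random_cds(cds_codons),
                    character(1)), genes$gene_id)
  })
  structure(list(blocks = blocks, genes = genes, cds = cds,
                 cds_codons = cds_codons, seed = seed),
            class = "ancestral_genome")
}

#' @export
print.ancestral_genome <- function(x, ...) {
  cat(sprintf("Ancestral genome: %d blocks (%s..%s), %d genes, %d codons/CDS\n",
              nrow(x$blocks), x$blocks$label[1],
              x$blocks$label[nrow(x$blocks)], nrow(x$genes), x$cds_codons))
  invisible(x)
}

#' Triplicate an ancestral genome and fractionate the copies
#'
#' Models the whole-genome triplication of a mesohexaploid: every ancestral
#' gene is copied into three paleogenomes and then each copy is retained
#' independently with its paleogenome's retention rate (Bernoulli per gene).
#' The rates must be ordered so that the least-fractionated paleogenome (LF)
#' retains at least as many genes as MF1, and MF1 at least as many as MF2.
#'
#' @param anc An `ancestral_genome`.
#' @param rates Numeric vector of three retention probabilities, in the order
#'   LF, MF1, MF2; must satisfy `1 >= LF >= MF1 >= MF2 >= 0`.
#' @param seed Integer seed.
#' @return An object of class `fractionated_genes`: a list with `genes`
#'   (data frame: `gene_id`, `anc_id`, `block`, `rank_in_block`,
#'   `subgenome`) recording every surviving copy, and `rates`.
#' @export
triplicate_and_fractionate <- function(anc, rates = c(0.55, 0.45, 0.40),
                                       seed = 1) {
  stopifnot(inherits(anc, "ancestral_genome"))
  if (length(rates) != 3L) stop_invalid("rates must have length 3 (LF, MF1, MF2)")
  if (any(rates < 0) || any(rates > 1)) stop_invalid("rates must lie in [0, 1]")
  if (rates[1] < rates[2] || rates[2] < rates[3]) {
    stop_invalid("retention rates must be ordered LF >= MF1 >= MF2")
  }
  subg <- c("LF", "MF1", "MF2")
  genes <- with_op_seed(seed, "fractionate", {
    out <- lapply(1:3, function(s) {
      keep <- runif(nrow(anc$genes)) < rates[s]
      g <- anc$genes[keep, , drop = FALSE]
      if (nrow(g) == 0L) return(NULL)
      data.frame(
        gene_id = sprintf("tg_%s_%s", subg[s], sub("^anc_", "", g$gene_id)),
        anc_id = g$gene_id,
        block = g$block,
        rank_in_block = g$rank_in_block,
        subgenome = subg[s],
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
  rownames(genes) <- NULL
  structure(list(genes = genes, rates = setNames(rates, subg), seed = seed),
            class = "fractionated_genes")
}
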