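#' Call orthologs by least Ks within syntenic chains
#'
#' Computes NG86 Ks (and Ka) for every anchor pair inside the chains and,
#' for each target gene, flags the syntenic partner with the smallest
#' defined Ks as its ortholog (the least-Ks rule). Ties are broken toward
#' the lexicographically smallest reference gene id and logged; target
#' genes whose partners are all saturated are left uncalled and logged.
#' Pairs that are each other's minimum are additionally flagged `mutual`.
#'
#' @param chains A `collinear_chains` object.
#' @param cds_ref,cds_tgt Named CDS vectors covering the anchor genes.
#' @return An object of class `ortholog_calls`: a data frame with
#'   `gene_ref`, `gene_tgt`, `chain_id`, `ks`, `ka`, `least_ks`, `mutual`.
#'   Attributes `ties` and `uncalled` carry the logs.
#' @export
call_orthologs <- function(chains, cds_ref, cds_tgt) {
  stopifnot(inherits(chains, "collinear_chains"))
  a <- chains$anchors
  if (nrow(a) == 0L) {
    out <- data.frame(gene_ref = character(0), gene_tgt = character(0),
                      chain_id = integer(0), ks = numeric(0), ka = numeric(0),
                      least_ks = logical(0), mutual = logical(0))
    return(structure(out, class = c("ortholog_calls", "data.frame"),
                     ties = character(0), uncalled = character(0)))
  }
  ks <- numeric(nrow(a))
  ka <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    est <- ks_ng86(cds_ref[[a$gene_ref[i]]], cds_tgt[[a$gene_tgt[i]]])
    ks[i] <- est$ks
    ka[i] <- est$ka
  }
  out <- data.frame(gene_ref = a$gene_ref, gene_tgt = a$gene_tgt,
                    chain_id = a$chain_id, ks = ks, ka = ka,
                    least_ks = FALSE, mutual = FALSE,
                    stringsAsFactors = FALSE)
  ties <- character(0)
  uncalled <- character(0)
  # least-Ks partner per target gene
  for (tg in unique(out$gene_tgt)) {
    rows <- which(out$gene_tgt == tg)
    defined <- rows[!is.na(out$ks[rows])]
    if (length(defined) == 0L) {
      uncalled <- c(uncalled, tg)
      next
    }
    mn <- min(out$ks[defined])
    winners <- defined[out$ks[defined] == mn]
    if (length(winners) > 1L) {
      ties <- c(ties, tg)
      winners <- winners[order(out$gene_ref[winners])][1L]
    }
    out$least_ks[winners] <- TRUE
  }
  # mutual minima: the flagged pair is also the minimum for its ref gene
  for (i in which(out$least_ks)) {
    rows <- which(out$gene_ref == out$gene_ref[i] & !is.na(out$ks))
    if (length(rows) > 0L && out$ks[i] <= min(out$ks[rows])) {
      out$mutual[i] <- TRUE
    }
  }
  structure(out, class = c("ortholog_calls", "data.frame"),
            ties = ties, uncalled = uncalled)
}

#' Detect inversions from collinear chains
#'
#' Reports every `-` oriented chain that is flanked, within `max_gaps`
#' target gene ranks on both sides, by anchors of `+` chains of the same
#' chromosome pair: the signature of a segmental inversion. Nested cases
#' are reported innermost-first.
#'
#' @param chains A `collinear_chains` object.
#' @return A data frame with `tgt_chrom`, `ref_chrom`, `chain_id`,
#'   `tgt_rank_min`, `tgt_rank_max`, `n_anchors` (empty when no inversion
#'   is found).
#' @export
detect_inversions <- function(chains) {
  stopifnot(inherits(chains, "collinear_chains"))
  ch <- chains$chains
  empty <- data.frame(tgt_chrom = character(0), ref_chrom = character(0),
                      chain_id = integer(0), tgt_rank_min = integer(0),
                      tgt_rank_max = integer(0), n_anchors = integer(0))
  if (nrow(ch) == 0L) return(empty)
  mg <- chains$params$max_gaps
  out <- list()
  for (i in which(ch$orientation == "-")) {
    mates <- ch$chain_id[ch$orientation == "+" &
                           ch$ref_chrom == ch$ref_chrom[i] &
                           ch$tgt_chrom == ch$tgt_chrom[i]]
    if (length(mates) == 0L) next
    plus_ranks <- chains$anchors$tgt_rank[chains$anchors$chain_id %in% mates]
    lo <- ch$tgt_rank_min[i]
    hi <- ch$tgt_rank_max[i]
    left <- any(plus_ranks < lo & plus_ranks >= lo - mg - 1L)
    right <- any(plus_ranks > hi & plus_ranks <= hi + mg + 1L)
    if (left && right) {
      out[[length(out) + 1L]] <- data.frame(
        tgt_chrom = ch$tgt_chrom[i], ref_chrom = ch$ref_chrom[i],
        chain_id = ch$chain_id[i], tgt_rank_min = lo, tgt_rank_max = hi,
        n_anchors = ch$n_anchors[i], stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$tgt_chrom, res$tgt_rank_max - res$tgt_rank_min,
                   res$tgt_rank_min), ]
  rownames(res) <- NULL
  res
}

#' Export syntenic pairs as dot-plot data
#'
#' One row per anchor pair with reference and target positions and a class
#' column separating least-Ks orthologs from other syntenic pairs (the
#' blue/green dot convention of whole-genome dot plots).
#'
#' @param chains A `collinear_chains` object.
#' @param calls Optional `ortholog_calls`; without it every pair is classed
#'   `other-syntenic`.
#' @param genes_a,genes_b Optional gene tables with `gene_id`, `start0`,
#'   `end0` to add bp midpoints.
#' @return A data frame with `ref_chrom`, `ref_rank`, `tgt_chrom`,
#'   `tgt_rank`, optional `ref_bp`/`tgt_bp`, and `class`.
#' @export
export_dotplot <- function(chains, calls = NULL, genes_a = NULL, genes_b = NULL) {
  stopifnot(inherits(chains, "collinear_chains"))
  a <- chains$anchors
  ch <- chains$chains
  df <- data.frame(
    ref_chrom = ch$ref_chrom[match(a$chain_id, ch$chain_id)],
    ref_rank = a$ref_rank,
    tgt_chrom = ch$tgt_chrom[match(a$chain_id, ch$chain_id)],
    tgt_rank = a$tgt_rank,
    class = rep("other-syntenic", nrow(a)),
    stringsAsFactors = FALSE
  )
  if (!is.null(calls) && nrow(df) > 0L) {
    key <- paste(a$gene_ref, a$gene_tgt)
    ortho <- paste(calls$gene_ref, calls$gene_tgt)[calls$least_ks]
    df$class[key %in% ortho] <- "ortholog"
  }
  if (!is.null(genes_a) && nrow(df) > 0L &&
      all(c("start0", "end0") %in% names(genes_a))) {
    i <- match(a$gene_ref, genes_a$gene_id)
    df$ref_bp <- (genes_a$start0[i] + genes_a$end0[i]) / 2
  }
  if (!is.null(genes_b) && nrow(df) > 0L &&
      all(c("start0", "end0") %in% names(genes_b))) {
    i <- match(a$gene_tgt, genes_b$gene_id)
    df$tgt_bp <- (genes_b$start0[i] + genes_b$end0[i]) / 2
  }
  df
}
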