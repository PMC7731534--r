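#' Score gene pairs by translated-CDS similarity
#'
#' All-against-all similarity surrogate for a protein database search:
#' coding sequences are translated and compared by shared peptide k-mers.
#' The similarity of a pair is the number of distinct shared peptide
#' k-mers divided by the smaller k-mer set, and pairs below `threshold`
#' are excluded. Scores are symmetric. Genes whose CDS length is not a
#' multiple of 3 are skipped with a warning.
#'
#' @param cds_a,cds_b Named character vectors of CDS (reference and target).
#' @param threshold Minimum similarity for a retained pair (the analog of a
#'   search significance cutoff; default 0.2).
#' @param kmer_size Peptide k-mer length.
#' @return An object of class `anchor_pairs`: a data frame with `gene_a`,
#'   `gene_b`, `score` (shared k-mer count) and `similarity`, ordered by
#'   `gene_a`, `gene_b`.
#' @export
score_gene_pairs <- function(cds_a, cds_b, threshold = 0.2, kmer_size = 5) {
  peptide_kmers <- function(cds, side) {
    bad <- nchar(cds) %% 3L != 0L
    if (any(bad)) {
      warning(sum(bad), " untranslatable CDS skipped on side ", side)
      cds <- cds[!bad]
    }
    if (length(cds) == 0L) stop_invalid("no translatable CDS on side ", side)
    pep <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(cds), no.init.codon = TRUE
    ))
    names(pep) <- names(cds)
    sets <- lapply(pep, function(p) {
      n <- nchar(p)
      if (n < kmer_size) return(character(0))
      starts <- seq_len(n - kmer_size + 1L)
      unique(substring(p, starts, starts + kmer_size - 1L))
    })
    sets
  }
  sets_a <- peptide_kmers(cds_a, "a")
  sets_b <- peptide_kmers(cds_b, "b")
  idx_a <- data.frame(
    kmer = unlist(sets_a, use.names = FALSE),
    gene = rep(names(sets_a), lengths(sets_a)),
    stringsAsFactors = FALSE
  )
  idx_b <- data.frame(
    kmer = unlist(sets_b, use.names = FALSE),
    gene = rep(names(sets_b), lengths(sets_b)),
    stringsAsFactors = FALSE
  )
  hits <- merge(idx_a, idx_b, by = "kmer", suffixes = c("_a", "_b"))
  if (nrow(hits) == 0L) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      score = integer(0), similarity = numeric(0))
    return(structure(out, class = c("anchor_pairs", "data.frame"),
                     threshold = threshold, kmer_size = kmer_size))
  }
  key <- paste(hits$gene_a, hits$gene_b, sep = "\r")
  shared <- table(key)
  parts <- strsplit(names(shared), "\r", fixed = TRUE)
  gene_a <- vapply(parts, `[[`, character(1), 1L)
  gene_b <- vapply(parts, `[[`, character(1), 2L)
  n_a <- lengths(sets_a)[gene_a]
  n_b <- lengths(sets_b)[gene_b]
  similarity <- as.integer(shared) / pmin(n_a, n_b)
  keep <- similarity >= threshold
  out <- data.frame(gene_a = gene_a[keep], gene_b = gene_b[keep],
                    score = as.integer(shared)[keep],
                    similarity = unname(similarity[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  structure(out, class = c("anchor_pairs", "data.frame"),
            threshold = threshold, kmer_size = kmer_size)
}
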