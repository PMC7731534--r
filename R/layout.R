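#' Shuffle block copies into chromosomes
#'
#' Reshuffles the surviving block copies of the three paleogenomes into a
#' set of target chromosomes, emulating the chromosomal rearrangements that
#' follow a whole-genome triplication. Each paleogenome's block copies are
#' kept in ancestral order, cut into a small number of contiguous segments,
#' and the segments are dealt across chromosomes; local ancestral adjacency
#' within a segment is therefore preserved, which is the signal the
#' subgenome-labelling stage relies on. One gene-free centromere position is
#' chosen per chromosome at a segment boundary near its middle.
#'
#' @param fr A `fractionated_genes` object.
#' @param n_chrom Number of target chromosomes (`>= 1`).
#' @param seed Integer seed.
#' @param segments_per_subgenome Number of contiguous segments each
#'   paleogenome is cut into (default `max(2, ceiling(n_chrom/2))`).
#' @return An object of class `genome_layout`: a list with `genes` (data
#'   frame ordered by chromosome and position: `gene_id`, `anc_id`, `block`,
#'   `rank_in_block`, `subgenome`, `chrom`, `index`, `strand`),
#'   `centromeres` (data frame: `chrom`, `after_index`), `segments` (truth
#'   table of segment placements) and `inversions` (empty until
#'   [plant_inversions()] is applied).
#' @export
shuffle_blocks_into_chromosomes <- function(fr, n_chrom = 8, seed = 1,
                                            segments_per_subgenome = NULL) {
  stopifnot(inherits(fr, "fractionated_genes"))
  if (n_chrom < 1) stop_invalid("n_chrom must be >= 1")
  genes <- fr$genes
  # a block copy = all surviving genes of one (block, subgenome)
  copies <- unique(genes[, c("block", "subgenome")])
  copies <- copies[order(copies$subgenome, copies$block), ]
  if (n_chrom > nrow(copies)) {
    stop_invalid("more chromosomes (", n_chrom, ") than block copies (",
                 nrow(copies), ")")
  }
  if (is.null(segments_per_subgenome)) {
    segments_per_subgenome <- max(2L, ceiling(n_chrom / 2))
  }

  with_op_seed(seed, "shuffle_blocks", {
    seg_list <- list()
    for (sg in unique(copies$subgenome)) {
      labs <- sort(copies$block[copies$subgenome == sg])
      n_seg <- min(segments_per_subgenome, length(labs))
      cuts <- if (n_seg > 1L) {
        sort(sample(seq_len(length(labs) - 1L), n_seg - 1L))
      } else integer(0)
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, length(labs))
      for (i in seq_along(starts)) {
        seg_list[[length(seg_list) + 1L]] <- list(
          subgenome = sg, labels = labs[starts[i]:ends[i]]
        )
      }
    }
    if (length(seg_list) < n_chrom) {
      stop_invalid("fewer segments (", length(seg_list), ") than chromosomes (",
                   n_chrom, "); raise segments_per_subgenome")
    }
    # deal segments across chromosomes: each chromosome gets at least one
    perm <- sample(seq_along(seg_list))
    chrom_of_seg <- integer(length(seg_list))
    chrom_of_seg[perm[seq_len(min(n_chrom, length(seg_list)))]] <- seq_len(min(n_chrom, length(seg_list)))
    rest <- perm[-seq_len(min(n_chrom, length(seg_list)))]
    if (length(rest) > 0L) {
      chrom_of_seg[rest] <- sample(seq_len(n_chrom), length(rest), replace = TRUE)
    }

    chrom_names <- sprintf("T%02d", seq_len(n_chrom))
    placed <- list()
    segments <- list()
    centromeres <- list()
    for (ch in seq_len(n_chrom)) {
      segs <- which(chrom_of_seg == ch)
      segs <- segs[sample.int(length(segs))]
      rows <- list()
      seg_sizes <- integer(0)
      for (si in seq_along(segs)) {
        sg <- seg_list[[segs[si]]]
        g <- genes[genes$subgenome == sg$subgenome & genes$block %in% sg$labels, ]
        g <- g[order(match(g$block, sg$labels), g$rank_in_block), ]
        rows[[si]] <- g
        seg_sizes <- c(seg_sizes, nrow(g))
        segments[[length(segments) + 1L]] <- data.frame(
          chrom = chrom_names[ch], seg_order = si, subgenome = sg$subgenome,
          first_block = sg$labels[1], last_block = sg$labels[length(sg$labels)],
          n_genes = nrow(g), stringsAsFactors = FALSE
        )
      }
      g <- do.call(rbind, rows)
      g$chrom <- chrom_names[ch]
      g$index <- seq_len(nrow(g))
      g$strand <- "+"
      placed[[ch]] <- g
      # centromere at the segment boundary nearest the middle; with a single
      # segment, between the two central block copies
      bnd <- cumsum(seg_sizes)
      bnd <- bnd[-length(bnd)]
      if (length(bnd) == 0L) {
        copy_sizes <- rle(paste(g$block, g$subgenome))$lengths
        bnd <- cumsum(copy_sizes)
        bnd <- bnd[-length(bnd)]
        if (length(bnd) == 0L) bnd <- floor(nrow(g) / 2)
      }
      after <- bnd[which.min(abs(bnd - nrow(g) / 2))]
      centromeres[[ch]] <- data.frame(chrom = chrom_names[ch],
                                      after_index = after,
                                      stringsAsFactors = FALSE)
    }
    genes_out <- do.call(rbind, placed)
    rownames(genes_out) <- NULL
    structure(list(
      genes = genes_out,
      centromeres = do.call(rbind, centromeres),
      segments = do.call(rbind, segments),
      inversions = data.frame(chrom = character(0), start = integer(0),
                              end = integer(0), block = character(0),
                              subgenome = character(0),
                              stringsAsFactors = FALSE),
      n_chrom = n_chrom, seed = seed
    ), class = "genome_layout")
  })
}

#' Invert a gene interval on one chromosome
#'
#' Reverses gene order and flips strands within `[start, end]` (1-based gene
#' indices on the chromosome). Applying the same inversion twice restores
#' the original layout.
#'
#' @param layout A `genome_layout`.
#' @param chrom Chromosome name.
#' @param start,end Gene indices on the chromosome (inclusive).
#' @return The modified `genome_layout`.
#' @export
apply_inversion <- function(layout, chrom, start, end) {
  stopifnot(inherits(layout, "genome_layout"))
  sel <- which(layout$genes$chrom == chrom)
  if (length(sel) == 0L) stop_invalid("unknown chromosome: ", chrom)
  n <- length(sel)
  if (start < 1 || end > n || start > end) {
    stop_invalid("inversion interval [", start, ", ", end,
                 "] is not inside chromosome ", chrom, " (", n, " genes)")
  }
  idx <- sel[start:end]
  block <- layout$genes[rev(idx), ]
  block$strand <- ifelse(block$strand == "+", "-", "+")
  block$index <- layout$genes$index[idx]
  layout$genes[idx, ] <- block
  layout
}

#' Plant segmental inversions into a genome layout
#'
#' Chooses `n_inversions` distinct chromosomes and, on each, inverts the
#' central portion of one block copy large enough to leave syntenic flanks
#' on both sides. The planted intervals are recorded in the layout's
#' `inversions` truth table.
#'
#' @param layout A `genome_layout`.
#' @param n_inversions Number of inversions to plant (0 leaves the layout
#'   unchanged).
#' @param seed Integer seed.
#' @param min_genes Minimum surviving genes a block copy must have to host
#'   an inversion.
#' @param fraction Fraction of the copy's genes that is inverted (centred).
#' @return The modified `genome_layout` with an updated `inversions` table.
#' @export
plant_inversions <- function(layout, n_inversions = 3, seed = 1,
                             min_genes = 15, fraction = 0.4) {
  stopifnot(inherits(layout, "genome_layout"))
  if (n_inversions == 0) return(layout)
  chroms <- unique(layout$genes$chrom)
  if (n_inversions > length(chroms)) {
    stop_invalid("n_inversions exceeds the number of chromosomes")
  }
  with_op_seed(seed, "plant_inversions", {
    chosen <- sample(chroms, n_inversions)
    inv_rows <- list()
    for (ch in chosen) {
      g <- layout$genes[layout$genes$chrom == ch, ]
      runs <- rle(paste(g$block, g$subgenome, sep = ":"))
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      ok <- which(runs$lengths >= min_genes)
      if (length(ok) == 0L) {
        stop_invalid("no block copy with >= ", min_genes, " genes on ", ch)
      }
      pick <- ok[sample.int(length(ok), 1L)]
      len <- max(2L, round(runs$lengths[pick] * fraction))
      off <- floor((runs$lengths[pick] - len) / 2)
      s <- starts[pick] + off
      e <- s + len - 1L
      layout <- apply_inversion(layout, ch, s, e)
      parts <- strsplit(runs$values[pick], ":")[[1]]
      inv_rows[[length(inv_rows) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e, block = parts[1],
        subgenome = parts[2], stringsAsFactors = FALSE
      )
    }
    layout$inversions <- rbind(layout$inversions, do.call(rbind, inv_rows))
    layout
  })
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("Genome layout: %d genes on %d chromosomes, %d planted inversion(s)\n",
              nrow(x$genes), x$n_chrom, nrow(x$inversions)))
  invisible(x)
}
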