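# Sequence-level emission of the synthetic genome: chromosome assembly,
# insertion of lineage-specific genes, scaffold fragmentation and the
# genetic-marker map.

#' Insert lineage-specific genes into a layout
#'
#' Adds `n_specific` genes with random coding sequences and no reference
#' counterpart at random positions of the target chromosomes (the analog of
#' genome-specific genes absent from the syntenic regions of related
#' genomes).
#'
#' @param layout A `genome_layout`.
#' @param n_specific Number of genes to insert.
#' @param cds_codons CDS length in codons.
#' @param seed Integer seed.
#' @return A list with the modified `layout` and `cds` (named character
#'   vector of the new sequences). Inserted genes carry `subgenome =
#'   "specific"` and an `NA` block.
#' @export
add_specific_genes <- function(layout, n_specific = 200, cds_codons = 300,
                               seed = 1) {
  stopifnot(inherits(layout, "genome_layout"))
  if (n_specific == 0) return(list(layout = layout, cds = character(0)))
  with_op_seed(seed, "specific_genes", {
    genes <- layout$genes
    ids <- sprintf("sp_%04d", seq_len(n_specific))
    cds <- setNames(vapply(ids, function(i) random_cds(cds_codons),
                           character(1)), ids)
    chroms <- unique(genes$chrom)
    pick_chrom <- sample(chroms, n_specific, replace = TRUE)
    new_rows <- data.frame(
      gene_id = ids, anc_id = NA_character_, block = NA_character_,
      rank_in_block = NA_integer_, subgenome = "specific",
      chrom = pick_chrom, index = NA_integer_,
      strand = sample(c("+", "-"), n_specific, replace = TRUE),
      stringsAsFactors = FALSE
    )
    out <- list()
    for (ch in chroms) {
      g <- genes[genes$chrom == ch, ]
      ins <- new_rows[new_rows$chrom == ch, ]
      if (nrow(ins) > 0L) {
        # slot each inserted gene after a uniformly chosen existing position
        slot <- sample(0:nrow(g), nrow(ins), replace = TRUE)
        ord <- order(c(seq_len(nrow(g)), slot + 0.5))
        g <- rbind(g, ins)[ord, ]
      }
      g$index <- seq_len(nrow(g))
      out[[ch]] <- g
    }
    layout$genes <- do.call(rbind, out)
    rownames(layout$genes) <- NULL
    list(layout = layout, cds = cds)
  })
}

#' Assemble chromosome sequences from a layout
#'
#' Concatenates gene coding sequences with random intergenic spacers drawn
#' from a geometric distribution, inserting a gene-free centromeric stretch
#' at each chromosome's recorded centromere position. Coordinates are
#' 0-based half-open internally (1-based on GFF3 emission).
#'
#' @param layout A `genome_layout`.
#' @param cds Named character vector covering every gene in the layout.
#' @param spacer_mean,spacer_min Geometric mean and minimum intergenic
#'   spacer length (bp).
#' @param centromere_bp Length of the gene-free centromere stretch (bp).
#' @param seed Integer seed.
#' @return A list of class `chromosome_set`: `seqs` (named character),
#'   `genes` (layout genes with `start0`, `end0`), `centromeres` (data
#'   frame with `chrom`, `start0`, `end0`) and `genome_size` (total bp).
#' @export
build_chromosome_sequences <- function(layout, cds, spacer_mean = 200,
                                       spacer_min = 50, centromere_bp = 20000,
                                       seed = 1) {
  stopifnot(inherits(layout, "genome_layout"))
  missing <- setdiff(layout$genes$gene_id, names(cds))
  if (length(missing) > 0L) {
    stop_invalid("missing CDS for ", length(missing), " genes (e.g. ",
                 missing[1], ")")
  }
  with_op_seed(seed, "chromosome_sequences", {
    genes <- layout$genes
    chroms <- unique(genes$chrom)
    seqs <- setNames(character(length(chroms)), chroms)
    cent_rows <- list()
    genes$start0 <- NA_integer_
    genes$end0 <- NA_integer_
    for (ch in chroms) {
      sel <- which(genes$chrom == ch)
      cen_after <- layout$centromeres$after_index[layout$centromeres$chrom == ch]
      if (length(cen_after) == 0L) cen_after <- -1L
      parts <- character(0)
      pos <- 0L
      for (j in seq_along(sel)) {
        spacer <- spacer_min + rgeom(1L, 1 / (spacer_mean + 1))
        parts <- c(parts, random_dna(spacer))
        pos <- pos + spacer
        i <- sel[j]
        s <- cds[[genes$gene_id[i]]]
        if (genes$strand[i] == "-") s <- revcomp(s)
        parts <- c(parts, s)
        genes$start0[i] <- pos
        pos <- pos + nchar(s)
        genes$end0[i] <- pos
        if (j == cen_after) {
          parts <- c(parts, random_dna(centromere_bp))
          cent_rows[[length(cent_rows) + 1L]] <- data.frame(
            chrom = ch, start0 = pos, end0 = pos + centromere_bp,
            stringsAsFactors = FALSE
          )
          pos <- pos + centromere_bp
        }
      }
      spacer <- spacer_min + rgeom(1L, 1 / (spacer_mean + 1))
      parts <- c(parts, random_dna(spacer))
      seqs[[ch]] <- paste(parts, collapse = "")
    }
    structure(list(
      seqs = seqs, genes = genes,
      centromeres = if (length(cent_rows)) do.call(rbind, cent_rows) else
        data.frame(chrom = character(0), start0 = integer(0), end0 = integer(0)),
      genome_size = sum(nchar(seqs))
    ), class = "chromosome_set")
  })
}

#' Fragment chromosomes into scaffolds and simulate a genetic map
#'
#' Cuts each chromosome into the planned number of scaffolds (random cut
#' points subject to a minimum piece size), shuffles scaffold identities,
#' reverse-complements a random subset, and samples genetic markers along
#' each chromosome. Marker cM positions accumulate a constant per-bp
#' recombination rate that is multiplied by `centromere_suppression` inside
#' the centromere interval, reproducing the reduced recombination observed
#' around centromeres. Optionally adds one marker-free scaffold (an
#' organelle analog).
#'
#' @param chromset A `chromosome_set` from [build_chromosome_sequences()].
#' @param scaffold_plan Named (or positional) integer vector: scaffolds per
#'   chromosome, all `>= 1`.
#' @param n_markers Markers per chromosome (`>= 2`).
#' @param centromere_suppression Multiplier (< 1) applied to the
#'   recombination rate inside centromeres.
#' @param organelle_scaffold Add one scaffold carrying no markers?
#' @param seed Integer seed.
#' @param tag_len Marker tag length (bp, `>= 20`).
#' @param cm_per_kb Baseline recombination rate (cM per kb).
#' @param min_frac Minimum scaffold size as a fraction of its chromosome.
#' @param organelle_bp Length of the organelle scaffold.
#' @return A list: `scaffolds` (named character), `markers` (data frame:
#'   `marker_id`, `lg`, `cM`, `tag_seq`), `marker_truth` (source chromosome
#'   and 0-based position per marker), `scaffold_truth` (data frame:
#'   `scaffold_id`, `lg`, `order`, `orientation`, `start0`, `end0`) and
#'   `organelle` (scaffold id or `NA`).
#' @export
fragment_and_map <- function(chromset, scaffold_plan, n_markers = 30,
                             centromere_suppression = 0.1,
                             organelle_scaffold = TRUE, seed = 1,
                             tag_len = 30, cm_per_kb = 0.4, min_frac = 0.15,
                             organelle_bp = 25000) {
  stopifnot(inherits(chromset, "chromosome_set"))
  chroms <- names(chromset$seqs)
  if (is.null(names(scaffold_plan))) {
    if (length(scaffold_plan) != length(chroms)) {
      stop_invalid("scaffold_plan must have one count per chromosome")
    }
    names(scaffold_plan) <- chroms
  }
  if (any(scaffold_plan < 1)) stop_invalid("scaffold counts must be >= 1")
  if (n_markers < 2) stop_invalid("need >= 2 markers per chromosome")
  if (tag_len < 20) stop_invalid("tag length must be >= 20 bp")

  with_op_seed(seed, "fragment_and_map", {
    subjects <- Biostrings::DNAStringSet(unname(chromset$seqs))

    ## --- markers -----------------------------------------------------------
    # oversample candidate positions per chromosome (in random order so the
    # retained markers are uniform along the chromosome), then keep only
    # tags that occur exactly once in the genome over both strands
    cand <- do.call(rbind, lapply(chroms, function(ch) {
      len <- nchar(chromset$seqs[[ch]])
      pos <- sample.int(len - tag_len, min(4L * n_markers, len - tag_len))
      data.frame(chrom = ch, pos0 = pos,
                 tag = substring(chromset$seqs[[ch]], pos + 1L, pos + tag_len),
                 stringsAsFactors = FALSE)
    }))
    cand <- cand[!grepl("[^ACGT]", cand$tag), ]
    utags <- unique(cand$tag)
    pd <- Biostrings::PDict(utags)
    hit_count <- integer(length(utags))
    for (sj in seq_along(subjects)) {
      hit_count <- hit_count +
        Biostrings::countPDict(pd, subjects[[sj]]) +
        Biostrings::countPDict(pd, Biostrings::reverseComplement(subjects[[sj]]))
    }
    unique_tag <- utags[hit_count == 1L]
    cand <- cand[cand$tag %in% unique_tag & !duplicated(cand$tag), ]

    marker_rows <- list()
    truth_rows <- list()
    mk <- 0L
    for (ch in chroms) {
      sel <- cand[cand$chrom == ch, ]
      if (nrow(sel) < n_markers) {
        stop_invalid("could not place ", n_markers, " unique markers on ", ch)
      }
      sel <- sel[seq_len(n_markers), ]
      sel <- sel[order(sel$pos0), ]
      cen <- chromset$centromeres[chromset$centromeres$chrom == ch, ]
      inside <- 0
      if (nrow(cen) == 1L) {
        inside <- pmax(0, pmin(sel$pos0, cen$end0) - cen$start0)
      }
      cm <- cm_per_kb / 1000 *
        ((sel$pos0 - inside) + centromere_suppression * inside)
      for (j in seq_len(nrow(sel))) {
        mk <- mk + 1L
        marker_rows[[mk]] <- data.frame(
          marker_id = sprintf("M%04d", mk), lg = ch,
          cM = round(cm[j], 4), tag_seq = sel$tag[j],
          stringsAsFactors = FALSE
        )
        truth_rows[[mk]] <- data.frame(
          marker_id = sprintf("M%04d", mk), chrom = ch, pos0 = sel$pos0[j],
          stringsAsFactors = FALSE
        )
      }
    }
    markers <- do.call(rbind, marker_rows)
    marker_truth <- do.call(rbind, truth_rows)

    ## --- scaffolds ---------------------------------------------------------
    pieces <- list()
    for (ch in chroms) {
      len <- nchar(chromset$seqs[[ch]])
      k <- scaffold_plan[[ch]]
      cuts <- if (k > 1L) {
        repeat {
          cand <- sort(runif(k - 1L))
          gaps <- diff(c(0, cand, 1))
          if (all(gaps >= min_frac)) break
        }
        round(cand * len)
      } else integer(0)
      bounds <- c(0L, as.integer(cuts), len)
      for (j in seq_len(k)) {
        pieces[[length(pieces) + 1L]] <- list(
          chrom = ch, order = j, start0 = bounds[j], end0 = bounds[j + 1L],
          seq = substr(chromset$seqs[[ch]], bounds[j] + 1L, bounds[j + 1L])
        )
      }
    }
    if (organelle_scaffold) {
      pieces[[length(pieces) + 1L]] <- list(
        chrom = NA_character_, order = NA_integer_, start0 = NA_integer_,
        end0 = NA_integer_, seq = random_dna(organelle_bp)
      )
    }
    n_sc <- length(pieces)
    ids <- sprintf("S%02d", sample.int(n_sc))
    flip <- runif(n_sc) < 0.5
    scaffolds <- setNames(character(n_sc), ids)
    truth <- list()
    organelle <- NA_character_
    for (i in seq_len(n_sc)) {
      s <- pieces[[i]]$seq
      ori <- "+"
      if (!is.na(pieces[[i]]$chrom) && flip[i]) {
        s <- revcomp(s)
        ori <- "-"
      }
      scaffolds[[ids[i]]] <- s
      if (is.na(pieces[[i]]$chrom)) organelle <- ids[i]
      truth[[i]] <- data.frame(
        scaffold_id = ids[i], lg = pieces[[i]]$chrom,
        order = pieces[[i]]$order, orientation = ifelse(is.na(pieces[[i]]$chrom),
                                                        NA_character_, ori),
        start0 = pieces[[i]]$start0, end0 = pieces[[i]]$end0,
        stringsAsFactors = FALSE
      )
    }
    scaffold_truth <- do.call(rbind, truth)
    list(scaffolds = scaffolds, markers = markers, marker_truth = marker_truth,
         scaffold_truth = scaffold_truth, organelle = organelle)
  })
}
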