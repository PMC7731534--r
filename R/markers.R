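#' Locate genetic-marker tags on scaffolds
#'
#' Exact (optionally one-mismatch) search of marker tag sequences against
#' both strands of a scaffold set. Markers matching a single locus are
#' reported as hits; markers matching several loci are dropped and logged;
#' unmatched markers are logged.
#'
#' @param scaffolds Named character vector (or `DNAStringSet`) of scaffold
#'   sequences.
#' @param markers Data frame with `marker_id`, `lg`, `cM`, `tag_seq`
#'   (tags `>= 20` bp, unique ids).
#' @param max_mismatch Allowed mismatches in the tag match (default 0).
#' @return An object of class `marker_hits`: a data frame with
#'   `marker_id`, `lg`, `cM`, `scaffold_id`, `pos0` (0-based match start)
#'   and `strand`. Attributes `ambiguous` and `unmatched` list the dropped
#'   marker ids.
#' @export
locate_markers <- function(scaffolds, markers, max_mismatch = 0) {
  if (anyDuplicated(markers$marker_id)) stop_invalid("duplicate marker ids")
  if (any(nchar(markers$tag_seq) < 20)) {
    stop_invalid("marker tags must be >= 20 bp")
  }
  subjects <- Biostrings::DNAStringSet(as.character(scaffolds))
  if (is.null(names(subjects))) names(subjects) <- names(scaffolds)
  n <- nrow(markers)
  n_hits <- integer(n)
  hit_scaffold <- character(n)
  hit_pos0 <- integer(n)
  hit_strand <- character(n)
  record <- function(i, sc, starts, strand) {
    k <- length(starts)
    if (k == 0L) return()
    if (n_hits[i] == 0L && k == 1L) {
      hit_scaffold[i] <<- sc
      hit_pos0[i] <<- starts[1] - 1L
      hit_strand[i] <<- strand
    }
    n_hits[i] <<- n_hits[i] + k
  }
  same_width <- length(unique(nchar(markers$tag_seq))) == 1L
  if (same_width && max_mismatch == 0) {
    # constant-width exact search: one preprocessed dictionary pass per strand
    pd_f <- Biostrings::PDict(markers$tag_seq)
    pd_r <- Biostrings::PDict(revcomp(markers$tag_seq))
    for (j in seq_along(subjects)) {
      mf <- Biostrings::matchPDict(pd_f, subjects[[j]])
      mr <- Biostrings::matchPDict(pd_r, subjects[[j]])
      for (i in which(S4Vectors::elementNROWS(mf) > 0L)) {
        record(i, names(subjects)[j], IRanges::start(mf[[i]]), "+")
      }
      for (i in which(S4Vectors::elementNROWS(mr) > 0L)) {
        record(i, names(subjects)[j], IRanges::start(mr[[i]]), "-")
      }
    }
  } else {
    for (i in seq_len(n)) {
      tag <- markers$tag_seq[i]
      fwd <- Biostrings::vmatchPattern(tag, subjects, max.mismatch = max_mismatch)
      rev <- Biostrings::vmatchPattern(revcomp(tag), subjects,
                                       max.mismatch = max_mismatch)
      for (j in seq_along(subjects)) {
        record(i, names(subjects)[j], IRanges::start(fwd[[j]]), "+")
        record(i, names(subjects)[j], IRanges::start(rev[[j]]), "-")
      }
    }
  }
  unmatched <- markers$marker_id[n_hits == 0L]
  ambiguous <- markers$marker_id[n_hits > 1L]
  ok <- which(n_hits == 1L)
  out <- data.frame(marker_id = markers$marker_id[ok], lg = markers$lg[ok],
                    cM = markers$cM[ok], scaffold_id = hit_scaffold[ok],
                    pos0 = hit_pos0[ok], strand = hit_strand[ok],
                    stringsAsFactors = FALSE)
  structure(out, class = c("marker_hits", "data.frame"),
            ambiguous = ambiguous, unmatched = unmatched)
}

#' Assign scaffolds to linkage groups
#'
#' Each scaffold is assigned to the linkage group contributing the majority
#' of its marker hits; scaffolds with fewer than `min_markers` hits are
#' left unassigned (the fate of, e.g., an organelle scaffold carrying no
#' markers).
#'
#' @param hits A `marker_hits` data frame.
#' @param scaffold_ids Optional character vector of all scaffold ids, so
#'   that hit-less scaffolds appear as unassigned rows.
#' @param min_markers Minimum hits for assignment (default 2).
#' @return A data frame of class `scaffold_placements`: `scaffold_id`,
#'   `lg` (`NA` when unassigned), `n_hits`, `assigned`.
#' @export
assign_scaffolds <- function(hits, scaffold_ids = NULL, min_markers = 2) {
  ids <- unique(c(hits$scaffold_id, scaffold_ids))
  rows <- lapply(ids, function(sc) {
    h <- hits[hits$scaffold_id == sc, ]
    if (nrow(h) < min_markers) {
      return(data.frame(scaffold_id = sc, lg = NA_character_,
                        n_hits = nrow(h), assigned = FALSE,
                        stringsAsFactors = FALSE))
    }
    tab <- sort(table(h$lg), decreasing = TRUE)
    data.frame(scaffold_id = sc, lg = names(tab)[1], n_hits = nrow(h),
               assigned = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$scaffold_id), ]
  rownames(out) <- NULL
  structure(out, class = c("scaffold_placements", "data.frame"))
}

#' Order and orient scaffolds into pseudochromosomes
#'
#' Within each linkage group, scaffolds are ordered by the median genetic
#' position (cM) of their marker hits (ties broken by scaffold id and
#' logged) and oriented by the sign of the Spearman rank correlation
#' between cM and physical position within the scaffold; single-marker
#' scaffolds default to `+` and are flagged. The layout is emitted as an
#' AGP v2.1 table with fixed 100 bp gaps, and the per-linkage-group
#' Spearman correlation between genetic and assembled physical positions
#' is reported.
#'
#' @param placements A `scaffold_placements` data frame.
#' @param hits The `marker_hits` the placements derive from.
#' @param scaffold_lengths Named vector of scaffold lengths (bp).
#' @param gap_bp Gap length between consecutive scaffolds (default 100).
#' @return An object of class `pseudochromosome_layout`: a list with
#'   `placements` (scaffold_id, lg, order_index, orientation, flags),
#'   `agp` (AGP v2.1 data frame), `lg_correlation` (named numeric) and
#'   `marker_positions` (marker cM vs assembled bp, for correlation plots).
#' @export
order_and_orient <- function(placements, hits, scaffold_lengths, gap_bp = 100) {
  asg <- placements[placements$assigned, ]
  out_rows <- list()
  agp_rows <- list()
  cors <- numeric(0)
  marker_pos <- list()
  for (lg in sort(unique(asg$lg))) {
    scs <- asg$scaffold_id[asg$lg == lg]
    med <- vapply(scs, function(sc) {
      median(hits$cM[hits$scaffold_id == sc & hits$lg == lg])
    }, numeric(1))
    ord <- order(med, scs)
    tie <- any(duplicated(med))
    scs <- scs[ord]
    offset <- 0
    part <- 0L
    for (k in seq_along(scs)) {
      sc <- scs[k]
      h <- hits[hits$scaffold_id == sc & hits$lg == lg, ]
      flags <- character(0)
      if (nrow(h) < 2L) {
        ori <- "+"
        flags <- c(flags, "orientation-unknown")
      } else {
        rho <- suppressWarnings(cor(h$cM, h$pos0, method = "spearman"))
        ori <- if (!is.na(rho) && rho < 0) "-" else "+"
      }
      if (tie) flags <- c(flags, "median-tie")
      len <- scaffold_lengths[[sc]]
      if (is.null(len) || is.na(len)) stop_invalid("missing length for ", sc)
      out_rows[[length(out_rows) + 1L]] <- data.frame(
        scaffold_id = sc, lg = lg, order_index = k, orientation = ori,
        flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE
      )
      if (k > 1L) {
        part <- part + 1L
        agp_rows[[length(agp_rows) + 1L]] <- data.frame(
          object = lg, object_beg = offset + 1, object_end = offset + gap_bp,
          part_number = part, component_type = "U", component_id = as.character(gap_bp),
          component_beg = "scaffold", component_end = "yes", orientation = "na",
          stringsAsFactors = FALSE
        )
        offset <- offset + gap_bp
      }
      part <- part + 1L
      agp_rows[[length(agp_rows) + 1L]] <- data.frame(
        object = lg, object_beg = offset + 1, object_end = offset + len,
        part_number = part, component_type = "W", component_id = sc,
        component_beg = "1", component_end = as.character(len),
        orientation = ori, stringsAsFactors = FALSE
      )
      # assembled positions of this scaffold's markers
      glob <- if (ori == "+") offset + h$pos0 + 1 else offset + len - h$pos0
      marker_pos[[length(marker_pos) + 1L]] <- data.frame(
        marker_id = h$marker_id, lg = lg, cM = h$cM, assembled_bp = glob,
        stringsAsFactors = FALSE
      )
      offset <- offset + len
    }
    mp <- do.call(rbind, marker_pos[vapply(marker_pos, function(m) m$lg[1] == lg,
                                           logical(1))])
    cors[lg] <- suppressWarnings(cor(mp$cM, mp$assembled_bp, method = "spearman"))
  }
  structure(list(
    placements = do.call(rbind, out_rows),
    agp = do.call(rbind, agp_rows),
    lg_correlation = cors,
    marker_positions = do.call(rbind, marker_pos)
  ), class = "pseudochromosome_layout")
}

#' @export
print.pseudochromosome_layout <- function(x, ...) {
  cat(sprintf("Pseudochromosome layout: %d scaffolds on %d linkage groups\n",
              nrow(x$placements), length(x$lg_correlation)))
  cat(sprintf("  per-LG Spearman cM~bp: min %.4f, median %.4f\n",
              min(x$lg_correlation), median(x$lg_correlation)))
  invisible(x)
}

#' Flag putative scaffold misassemblies from marker hits
#'
#' A scaffold is flagged as a chimera when its markers span more than one
#' linkage group, or as internally inconsistent when the cM sequence along
#' the scaffold deviates from its dominant monotone trend by more than
#' `tolerance` sign changes (absorbing local genotyping noise).
#'
#' @param hits A `marker_hits` data frame.
#' @param tolerance Allowed sign changes against the dominant trend
#'   (default 2).
#' @return A data frame: `scaffold_id`, `flagged`, `reason`.
#' @export
detect_misassembly <- function(hits, tolerance = 2) {
  rows <- lapply(unique(hits$scaffold_id), function(sc) {
    h <- hits[hits$scaffold_id == sc, ]
    h <- h[order(h$pos0), ]
    if (length(unique(h$lg)) > 1L) {
      return(data.frame(scaffold_id = sc, flagged = TRUE, reason = "chimera",
                        stringsAsFactors = FALSE))
    }
    if (nrow(h) >= 3L) {
      d <- sign(diff(h$cM))
      d <- d[d != 0]
      if (length(d) > 0L) {
        dominant <- if (sum(d > 0) >= sum(d < 0)) 1 else -1
        against <- sum(d != dominant)
        if (against > tolerance) {
          return(data.frame(scaffold_id = sc, flagged = TRUE,
                            reason = "non-monotone", stringsAsFactors = FALSE))
        }
      }
    }
    data.frame(scaffold_id = sc, flagged = FALSE, reason = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write AGP v2.1
#'
#' @param agp An AGP data frame as produced by [order_and_orient()].
#' @param path File path.
#' @return `read_agp` returns the AGP data frame; `write_agp` returns
#'   `path` invisibly.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  write.table(agp, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_agp
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  df <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("object", "object_beg", "object_end",
                                 "part_number", "component_type",
                                 "component_id", "component_beg",
                                 "component_end", "orientation"),
                   colClasses = c("character", "numeric", "numeric", "integer",
                                  "character", "character", "character",
                                  "character", "character"))
  df
}
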