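#' Project ancestral gene blocks onto a target genome
#'
#' Assigns every collinear chain the block label of its reference-side
#' genes, splitting chains that span a block boundary at the boundary, and
#' merges same-label chains whose target intervals overlap or lie within
#' `merge_gap` gene ranks on the same target chromosome into block copies.
#' On a clean triplicated genome every block label is expected to yield
#' three copies.
#'
#' @param chains A `collinear_chains` object (reference vs target).
#' @param ref_blocks Data frame with `gene_id`, `block` labelling the
#'   reference genes.
#' @param genes_b Optional target gene table with `gene_id`, `start0`,
#'   `end0` to attach bp coordinates to the copies.
#' @param merge_gap Maximum target gene-rank separation for merging chains
#'   of the same label (default 50).
#' @return An object of class `block_copies`: a data frame with `copy_id`,
#'   `block`, `tgt_chrom`, `rank_min`, `rank_max`, `retained`, `reference`,
#'   `subgenome` (initially `"unassigned"`), and bp columns when available.
#'   The attribute `gene_map` maps each target gene to its copy; `splits`
#'   logs chains split across block boundaries.
#' @export
project_blocks <- function(chains, ref_blocks, genes_b = NULL, merge_gap = 50) {
  stopifnot(inherits(chains, "collinear_chains"))
  a <- chains$anchors
  if (nrow(a) == 0L) stop_invalid("no chains to project")
  lab <- ref_blocks$block[match(a$gene_ref, ref_blocks$gene_id)]
  if (anyNA(lab)) {
    stop_invalid("reference genes without block labels (e.g. ",
                 a$gene_ref[which(is.na(lab))[1]], ")")
  }
  ch <- chains$chains
  a$block <- lab
  a$tgt_chrom <- ch$tgt_chrom[match(a$chain_id, ch$chain_id)]
  ref_count <- table(ref_blocks$block)

  # split each chain into runs of constant block label along the reference
  splits <- integer(0)
  runs <- list()
  for (cid in unique(a$chain_id)) {
    sub <- a[a$chain_id == cid, ]
    sub <- sub[order(sub$ref_rank), ]
    r <- rle(sub$block)
    if (length(r$lengths) > 1L) splits <- c(splits, cid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(starts)) {
      seg <- sub[starts[k]:ends[k], ]
      runs[[length(runs) + 1L]] <- seg
    }
  }

  # merge runs per (block, target chromosome) when target intervals are
  # within merge_gap ranks
  copies <- list()
  gene_map <- list()
  key <- vapply(runs, function(s) paste(s$block[1], s$tgt_chrom[1], sep = "\r"),
                character(1))
  for (kk in unique(key)) {
    rs <- runs[key == kk]
    ivs <- data.frame(
      lo = vapply(rs, function(s) min(s$tgt_rank), numeric(1)),
      hi = vapply(rs, function(s) max(s$tgt_rank), numeric(1))
    )
    ord <- order(ivs$lo, ivs$hi)
    rs <- rs[ord]
    ivs <- ivs[ord, ]
    grp <- integer(nrow(ivs))
    g <- 1L
    grp[1] <- g
    if (nrow(ivs) > 1L) {
      hi <- ivs$hi[1]
      for (i in 2:nrow(ivs)) {
        if (ivs$lo[i] > hi + merge_gap) g <- g + 1L
        grp[i] <- g
        hi <- max(hi, ivs$hi[i])
      }
    }
    for (gi in unique(grp)) {
      seg <- do.call(rbind, rs[grp == gi])
      copies[[length(copies) + 1L]] <- seg
    }
  }

  out <- data.frame(
    copy_id = seq_along(copies),
    block = vapply(copies, function(s) s$block[1], character(1)),
    tgt_chrom = vapply(copies, function(s) s$tgt_chrom[1], character(1)),
    rank_min = vapply(copies, function(s) min(s$tgt_rank), numeric(1)),
    rank_max = vapply(copies, function(s) max(s$tgt_rank), numeric(1)),
    retained = vapply(copies, function(s) length(unique(s$gene_tgt)), numeric(1)),
    stringsAsFactors = FALSE
  )
  out$reference <- as.integer(ref_count[out$block])
  out$subgenome <- "unassigned"
  if (!is.null(genes_b) && all(c("start0", "end0") %in% names(genes_b))) {
    out$start0 <- vapply(copies, function(s) {
      min(genes_b$start0[match(unique(s$gene_tgt), genes_b$gene_id)])
    }, numeric(1))
    out$end0 <- vapply(copies, function(s) {
      max(genes_b$end0[match(unique(s$gene_tgt), genes_b$gene_id)])
    }, numeric(1))
  }
  gene_map <- do.call(rbind, lapply(seq_along(copies), function(i) {
    data.frame(gene_tgt = unique(copies[[i]]$gene_tgt), copy_id = i,
               stringsAsFactors = FALSE)
  }))
  structure(out, class = c("block_copies", "data.frame"),
            gene_map = gene_map, splits = splits)
}

#' Label subgenomes from projected block copies
#'
#' Partitions block copies into paleogenome groups and ranks the groups by
#' total retained genes into LF (least fractionated), MF1 and MF2.
#' Grouping exploits the ancestral adjacency preserved through block
#' reshuffling: copies that sit next to each other on a target chromosome
#' and carry consecutive ancestral block labels are evidence of a common
#' paleogenome. Because every ancestral label contributes at most one copy
#' per paleogenome, the grouping is solved exactly by dynamic programming
#' along the ancestral label sequence: the state at label k is the
#' injective assignment of label k's copies to the (up to three) groups,
#' and transitions score the chromosome adjacencies between copies of
#' labels k and k+1 that land in the same group. The maximum-adjacency
#' assignment is recovered by backtracking; surplus copies of an
#' over-represented label (fragments of a split copy) inherit a group from
#' their chromosome neighbourhood afterwards.
#'
#' @param copies A `block_copies` object.
#' @return The copies with `subgenome` filled in, plus attributes
#'   `summary` (a `fractionation_summary`: per-subgenome retained totals,
#'   reference total) and `rank_ties` (flag for tie-broken rankings).
#' @export
label_subgenomes <- function(copies) {
  stopifnot(inherits(copies, "block_copies"))
  if (nrow(copies) == 0L) stop_invalid("no block copies")
  labels <- sort(unique(copies$block))
  L <- length(labels)
  copies$label_idx <- match(copies$block, labels)
  mult <- table(copies$block)
  n_groups <- min(max(mult), 3L)
  if (max(mult) < 3L) {
    warning("fewer than 3 copies for every block; partial labelling")
  }

  # chromosome adjacencies between copies with consecutive ancestral labels
  ord <- order(copies$tgt_chrom, copies$rank_min)
  adj_lo <- integer(0) # copy index carrying label k
  adj_hi <- integer(0) # adjacent copy carrying label k + 1
  if (length(ord) > 1L) {
    for (i in 2:length(ord)) {
      a <- ord[i - 1L]
      b <- ord[i]
      if (copies$tgt_chrom[a] != copies$tgt_chrom[b]) next
      d <- copies$label_idx[b] - copies$label_idx[a]
      if (d == 1L) {
        adj_lo <- c(adj_lo, a); adj_hi <- c(adj_hi, b)
      } else if (d == -1L) {
        adj_lo <- c(adj_lo, b); adj_hi <- c(adj_hi, a)
      }
    }
  }

  # primaries: up to n_groups copies per label, largest retained first
  primaries <- lapply(seq_len(L), function(k) {
    idx <- which(copies$label_idx == k)
    idx[order(-copies$retained[idx], copies$copy_id[idx])][
      seq_len(min(length(idx), n_groups))]
  })
  # states per label: injective assignments of its primaries to groups
  inj_maps <- function(m, G) {
    if (m == 0L) return(list(integer(0)))
    out <- list()
    rec <- function(chosen) {
      if (length(chosen) == m) {
        out[[length(out) + 1L]] <<- chosen
        return()
      }
      for (g in setdiff(seq_len(G), chosen)) rec(c(chosen, g))
    }
    rec(integer(0))
    out
  }
  states <- lapply(primaries, function(p) inj_maps(length(p), n_groups))

  # DP along the label sequence, maximising same-group adjacency bonuses;
  # all argmax predecessors are kept so that tied optima (e.g. two
  # paleogenomes cut at the same ancestral position) can be enumerated and
  # resolved by retention-rate homogeneity below
  V <- vector("list", L)
  back <- vector("list", L)
  V[[1]] <- numeric(length(states[[1]]))
  if (L > 1L) {
    for (k in 2:L) {
      ns <- length(states[[k]])
      V[[k]] <- numeric(ns)
      back[[k]] <- vector("list", ns)
      # adjacency pairs between labels k-1 and k, as primary slot indices
      sel <- which(copies$label_idx[adj_lo] == k - 1L &
                     copies$label_idx[adj_hi] == k)
      pa <- match(adj_lo[sel], primaries[[k - 1L]])
      pb <- match(adj_hi[sel], primaries[[k]])
      keep <- !is.na(pa) & !is.na(pb)
      pa <- pa[keep]; pb <- pb[keep]
      for (s in seq_len(ns)) {
        cur <- states[[k]][[s]]
        vals <- vapply(seq_along(states[[k - 1L]]), function(sp) {
          prev <- states[[k - 1L]][[sp]]
          bonus <- if (length(pa)) sum(prev[pa] == cur[pb]) else 0
          V[[k - 1L]][sp] + bonus
        }, numeric(1))
        V[[k]][s] <- max(vals)
        back[[k]][[s]] <- which(vals == max(vals))
      }
    }
  }
  # enumerate optimal state paths (bounded), then pick the assignment whose
  # groups have the most homogeneous per-copy retention rates
  rate <- copies$retained / pmax(copies$reference, 1L)
  max_paths <- 512L
  finals <- which(V[[L]] == max(V[[L]]))
  paths <- lapply(finals, function(s) s)
  if (L > 1L) {
    for (k in L:2) {
      new_paths <- list()
      for (p in paths) {
        for (sp in back[[k]][[p[1L]]]) {
          new_paths[[length(new_paths) + 1L]] <- c(sp, p)
          if (length(new_paths) >= max_paths) break
        }
        if (length(new_paths) >= max_paths) break
      }
      paths <- new_paths
    }
  }
  path_score <- vapply(paths, function(p) {
    grp <- integer(nrow(copies))
    for (k in seq_len(L)) grp[primaries[[k]]] <- states[[k]][[p[k]]]
    sum(vapply(seq_len(n_groups), function(g) {
      x <- rate[grp == g]
      if (length(x) > 1L) var(x) * length(x) else 0
    }, numeric(1)))
  }, numeric(1))
  best_path <- paths[[which.min(path_score)]]
  group_of_copy <- integer(nrow(copies))
  for (k in seq_len(L)) {
    group_of_copy[primaries[[k]]] <- states[[k]][[best_path[k]]]
  }
  # surplus copies (beyond n_groups per label): inherit from an adjacent
  # assigned copy with consecutive label, else from the largest same-label
  # primary
  surplus <- which(group_of_copy == 0L)
  for (i in surplus) {
    nb <- c(adj_hi[adj_lo == i], adj_lo[adj_hi == i])
    nb <- nb[group_of_copy[nb] > 0L]
    group_of_copy[i] <- if (length(nb) > 0L) group_of_copy[nb[1L]] else
      group_of_copy[primaries[[copies$label_idx[i]]][1L]]
  }
  totals <- vapply(seq_len(n_groups), function(g) {
    sum(copies$retained[group_of_copy == g])
  }, numeric(1))
  rk <- order(-totals, seq_len(n_groups))
  rank_ties <- any(duplicated(totals))
  subg_names <- c("LF", "MF1", "MF2")[seq_len(n_groups)]
  name_of_group <- character(n_groups)
  name_of_group[rk] <- subg_names
  copies$subgenome <- ifelse(group_of_copy == 0L, "unassigned",
                             name_of_group[pmax(group_of_copy, 1L)])
  copies$label_idx <- NULL
  summary <- structure(list(
    retained = setNames(totals[rk], subg_names),
    reference_total = sum(copies$reference[!duplicated(copies$block)]),
    rank_ties = rank_ties
  ), class = "fractionation_summary")
  attr(copies, "summary") <- summary
  attr(copies, "rank_ties") <- rank_ties
  copies
}

#' @export
print.fractionation_summary <- function(x, ...) {
  cat("Subgenome fractionation (retained genes):\n")
  for (nm in names(x$retained)) {
    cat(sprintf("  %-4s %6.0f / %.0f (%.1f%%)\n", nm, x$retained[[nm]],
                x$reference_total, 100 * x$retained[[nm]] / x$reference_total))
  }
  if (isTRUE(x$rank_ties)) cat("  (ranking tie broken deterministically)\n")
  invisible(x)
}

#' Sliding-window gene retention profile
#'
#' For every reference gene position, the fraction of reference genes in a
#' window of `window` flanking genes (half on each side, truncated at
#' chromosome ends) that retain a syntenic homolog in each subgenome.
#'
#' @param copies A labelled `block_copies` object (see
#'   [label_subgenomes()]).
#' @param calls An `ortholog_calls` data frame (all syntenic pairs are
#'   used, not only least-Ks pairs).
#' @param ref_genes Reference gene table (`gene_id`, `chrom`) in gene
#'   order.
#' @param window Window size in flanking genes (default 500, i.e. 250 per
#'   side; `>= 2`).
#' @return An object of class `retention_profile`: a data frame with one
#'   row per reference gene (`gene_id`, `chrom`) and one retention-fraction
#'   column per subgenome.
#' @export
retention_profile <- function(copies, calls, ref_genes, window = 500) {
  stopifnot(inherits(copies, "block_copies"))
  if (window < 2) stop_invalid("window must be >= 2")
  gene_map <- attr(copies, "gene_map")
  sub_of_tgt <- setNames(copies$subgenome[gene_map$copy_id], gene_map$gene_tgt)
  subgenomes <- intersect(c("LF", "MF1", "MF2"),
                          unique(copies$subgenome))
  if (length(subgenomes) == 0L) subgenomes <- unique(copies$subgenome)
  half <- floor(window / 2)
  if (half >= max(table(ref_genes$chrom))) {
    warning("window exceeds the largest chromosome; using full-chromosome windows")
  }
  out <- ref_genes[, c("gene_id", "chrom")]
  for (sg in subgenomes) {
    tgt_in <- names(sub_of_tgt)[sub_of_tgt == sg]
    retained_refs <- unique(calls$gene_ref[calls$gene_tgt %in% tgt_in])
    ind <- as.numeric(out$gene_id %in% retained_refs)
    frac <- numeric(nrow(out))
    for (ch in unique(out$chrom)) {
      sel <- which(out$chrom == ch)
      x <- ind[sel]
      n <- length(x)
      cs <- c(0, cumsum(x))
      lo <- pmax(seq_len(n) - half, 1L)
      hi <- pmin(seq_len(n) + half, n)
      frac[sel] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
    out[[sg]] <- frac
  }
  structure(out, class = c("retention_profile", "data.frame"), window = window)
}

#' Find lineage-specific genes
#'
#' Target genes that appear in no collinear chain (and hence have no
#' syntenic homolog in the reference) are reported as genome-specific.
#'
#' @param tgt_gene_ids Character vector of all target gene ids.
#' @param chains A `collinear_chains` object.
#' @param calls Optional `ortholog_calls`; any gene appearing there is
#'   considered retained as well.
#' @return A list with `genes` (character vector) and `count`.
#' @export
find_lineage_specific_genes <- function(tgt_gene_ids, chains, calls = NULL) {
  stopifnot(inherits(chains, "collinear_chains"))
  anchored <- unique(chains$anchors$gene_tgt)
  if (!is.null(calls)) anchored <- unique(c(anchored, calls$gene_tgt))
  specific <- setdiff(tgt_gene_ids, anchored)
  list(genes = specific, count = length(specific))
}
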