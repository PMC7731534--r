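#' Chaining parameters
#'
#' MCScanX-style collinearity parameters: `match_score` added per anchor,
#' `gap_penalty` (negative) applied per unit gene-rank gap (the larger of
#' the two sides' rank advances between consecutive anchors), `max_gaps`
#' bounding the intervening gene ranks a chain may skip, and `match_size`,
#' the minimum number of anchors per reported chain.
#'
#' @param match_score Score per anchor (default 50).
#' @param match_size Minimum anchors per chain (default 5).
#' @param gap_penalty Penalty per unit gap (default -1).
#' @param max_gaps Maximum intervening gene ranks between consecutive
#'   anchors (default 25).
#' @return A `chain_params` list.
#' @export
chain_params <- function(match_score = 50, match_size = 5, gap_penalty = -1,
                         max_gaps = 25) {
  if (match_size < 1) stop_invalid("match_size must be >= 1")
  if (max_gaps < 0) stop_invalid("max_gaps must be >= 0")
  structure(list(match_score = match_score, match_size = as.integer(match_size),
                 gap_penalty = gap_penalty, max_gaps = as.integer(max_gaps)),
            class = "chain_params")
}

# One DP pass over anchors (r, t strictly increasing both sides).
# Returns per-anchor, per capped-count-class matrices of best score and the
# anchor count achieving it (lexicographic (score, len) maximum).
# `r`, `t` must be in canonical order (ascending r, then t).
chain_dp <- function(r, t, params) {
  n <- length(r)
  K <- params$match_size
  ms <- params$match_score
  gp <- params$gap_penalty
  mg <- params$max_gaps
  f_score <- matrix(-Inf, n, K)
  f_len <- matrix(0L, n, K)
  for (i in seq_len(n)) {
    f_score[i, 1L] <- ms
    f_len[i, 1L] <- 1L
    if (i == 1L) next
    j <- seq_len(i - 1L)
    dr <- r[i] - r[j]
    dt <- t[i] - t[j]
    g <- pmax(dr, dt)
    ok <- dr >= 1L & dt >= 1L & (g - 1L) <= mg
    if (!any(ok)) next
    j <- j[ok]
    pen <- gp * g[ok]
    for (kp in seq_len(K)) {
      k <- min(kp + 1L, K)
      cand <- f_score[j, kp] + ms + pen
      lens <- f_len[j, kp] + 1L
      fin <- which(is.finite(cand))
      if (length(fin) == 0L) next
      best <- fin[order(-cand[fin], -lens[fin])[1L]]
      if (cand[best] > f_score[i, k] ||
          (cand[best] == f_score[i, k] && lens[best] > f_len[i, k])) {
        f_score[i, k] <- cand[best]
        f_len[i, k] <- lens[best]
      }
    }
  }
  list(score = f_score, len = f_len)
}

# Best (score, len) of chains *starting* at each anchor with at least `k`
# anchors, for every k: run the DP on the reversed, negated coordinates and
# cumulate classes from above.
chain_suffix <- function(r, t, params) {
  n <- length(r)
  rev_idx <- n:1
  dp <- chain_dp(-r[rev_idx], -t[rev_idx], params)
  s_score <- dp$score[rev_idx, , drop = FALSE]
  s_len <- dp$len[rev_idx, , drop = FALSE]
  K <- params$match_size
  ge_score <- s_score
  ge_len <- s_len
  if (K > 1L) {
    for (k in (K - 1L):1L) {
      take <- ge_score[, k + 1L] > ge_score[, k] |
        (ge_score[, k + 1L] == ge_score[, k] & ge_len[, k + 1L] > ge_len[, k])
      ge_score[take, k] <- ge_score[take, k + 1L]
      ge_len[take, k] <- ge_len[take, k + 1L]
    }
  }
  list(score = ge_score, len = ge_len)
}

# Extract the single best chain from one anchor set (already restricted to a
# chromosome pair and orientation, i.e. t ascending). Tie-break: maximum
# score, then maximum anchor count, then the lexicographically smallest
# sequence of canonical anchor indices. Returns NULL if no chain reaches
# match_size anchors.
best_chain_one <- function(r, t, params) {
  n <- length(r)
  if (n < params$match_size) return(NULL)
  K <- params$match_size
  ms <- params$match_score
  gp <- params$gap_penalty
  mg <- params$max_gaps
  sfx <- chain_suffix(r, t, params)
  starts <- which(is.finite(sfx$score[, K]))
  if (length(starts) == 0L) return(NULL)
  best <- starts[order(-sfx$score[starts, K], -sfx$len[starts, K], starts)[1L]]
  target_score <- sfx$score[best, K]
  target_len <- sfx$len[best, K]
  # among equal-optimum starts, the smallest index gives the lex-min chain
  first <- min(starts[sfx$score[starts, K] == target_score &
                        sfx$len[starts, K] == target_len])
  chain <- first
  need_score <- target_score - ms
  need_len <- target_len - 1L
  k_rem <- max(K - 1L, 1L)
  cur <- first
  while (need_len > 0L) {
    js <- which(seq_len(n) > cur)
    dr <- r[js] - r[cur]
    dt <- t[js] - t[cur]
    g <- pmax(dr, dt)
    ok <- dr >= 1L & dt >= 1L & (g - 1L) <= mg
    js <- js[ok]
    pen <- gp * g[ok]
    hit <- js[sfx$score[js, k_rem] == (need_score - pen) &
                sfx$len[js, k_rem] == need_len]
    nxt <- min(hit)
    pen_used <- gp * max(r[nxt] - r[cur], t[nxt] - t[cur])
    chain <- c(chain, nxt)
    need_score <- need_score - pen_used - ms
    need_len <- need_len - 1L
    k_rem <- max(k_rem - 1L, 1L)
    cur <- nxt
  }
  list(idx = chain, score = target_score, n_anchors = target_len)
}

#' Detect collinear chains between two genomes
#'
#' Finds maximal-scoring runs of collinear anchors between every chromosome
#' pair by dynamic programming under the parameters of [chain_params()]:
#' each anchor adds `match_score`, each step between consecutive anchors
#' costs `gap_penalty` per unit gene-rank gap (the larger of the two sides'
#' advances), steps skipping more than `max_gaps` intervening ranks are
#' forbidden, and chains with fewer than `match_size` anchors are
#' discarded. Chains are extracted greedily (best chain first, its anchors
#' removed, repeat) in both orientations; anchors of a `-` chain descend in
#' target rank. Overlapping candidates are thereby resolved by score, then
#' anchor count, then lexicographic anchor order.
#'
#' @param anchors An `anchor_pairs` data frame (or any data frame with
#'   `gene_a`, `gene_b`).
#' @param genes_a,genes_b Gene tables for the two genomes: data frames with
#'   `gene_id`, `chrom`, and gene order given either by a `rank` column
#'   (rank within chromosome) or by row order; optional `start0`/`end0`
#'   give bp spans.
#' @param params A `chain_params` object.
#' @return An object of class `collinear_chains`: a list with `chains`
#'   (data frame: `chain_id`, `ref_chrom`, `tgt_chrom`, `orientation`,
#'   `score`, `n_anchors`, and bp spans when coordinates are available) and
#'   `anchors` (data frame: `chain_id`, `gene_ref`, `gene_tgt`, `ref_rank`,
#'   `tgt_rank`).
#' @export
chain_anchors <- function(anchors, genes_a, genes_b, params = chain_params()) {
  ga <- normalize_gene_table(genes_a, "genes_a")
  gb <- normalize_gene_table(genes_b, "genes_b")
  miss_a <- setdiff(anchors$gene_a, ga$gene_id)
  miss_b <- setdiff(anchors$gene_b, gb$gene_id)
  if (length(miss_a) || length(miss_b)) {
    stop_invalid("anchors reference genes absent from the gene tables (e.g. ",
                 c(miss_a, miss_b)[1], ")")
  }
  ia <- match(anchors$gene_a, ga$gene_id)
  ib <- match(anchors$gene_b, gb$gene_id)
  tab <- data.frame(
    gene_ref = anchors$gene_a, gene_tgt = anchors$gene_b,
    ref_chrom = ga$chrom[ia], tgt_chrom = gb$chrom[ib],
    ref_rank = ga$rank[ia], tgt_rank = gb$rank[ib],
    stringsAsFactors = FALSE
  )
  has_bp <- all(c("start0", "end0") %in% names(ga)) &&
    all(c("start0", "end0") %in% names(gb))
  if (has_bp) {
    tab$ref_start0 <- ga$start0[ia]; tab$ref_end0 <- ga$end0[ia]
    tab$tgt_start0 <- gb$start0[ib]; tab$tgt_end0 <- gb$end0[ib]
  }

  chain_rows <- list()
  anchor_rows <- list()
  chain_id <- 0L
  groups <- split(seq_len(nrow(tab)), paste(tab$ref_chrom, tab$tgt_chrom, sep = "\r"))
  for (grp in groups) {
    sub <- tab[grp, ]
    # canonical anchor order within the chromosome pair
    ord <- order(sub$ref_rank, sub$tgt_rank, sub$gene_ref, sub$gene_tgt)
    sub <- sub[ord, ]
    active <- rep(TRUE, nrow(sub))
    repeat {
      idx <- which(active)
      if (length(idx) < params$match_size) break
      r <- sub$ref_rank[idx]
      t <- sub$tgt_rank[idx]
      plus <- best_chain_one(r, t, params)
      minus <- best_chain_one(r, -t, params)
      pick <- NULL
      ori <- "+"
      if (!is.null(plus) && !is.null(minus)) {
        if (minus$score > plus$score ||
            (minus$score == plus$score && minus$n_anchors > plus$n_anchors)) {
          pick <- minus; ori <- "-"
        } else {
          pick <- plus
        }
      } else if (!is.null(plus)) {
        pick <- plus
      } else if (!is.null(minus)) {
        pick <- minus; ori <- "-"
      }
      if (is.null(pick)) break
      members <- idx[pick$idx]
      chain_id <- chain_id + 1L
      row <- data.frame(
        chain_id = chain_id, ref_chrom = sub$ref_chrom[1],
        tgt_chrom = sub$tgt_chrom[1], orientation = ori,
        score = pick$score, n_anchors = pick$n_anchors,
        ref_rank_min = min(sub$ref_rank[members]),
        ref_rank_max = max(sub$ref_rank[members]),
        tgt_rank_min = min(sub$tgt_rank[members]),
        tgt_rank_max = max(sub$tgt_rank[members]),
        stringsAsFactors = FALSE
      )
      if (has_bp) {
        row$ref_start0 <- min(sub$ref_start0[members])
        row$ref_end0 <- max(sub$ref_end0[members])
        row$tgt_start0 <- min(sub$tgt_start0[members])
        row$tgt_end0 <- max(sub$tgt_end0[members])
      }
      chain_rows[[chain_id]] <- row
      anchor_rows[[chain_id]] <- data.frame(
        chain_id = chain_id,
        gene_ref = sub$gene_ref[members], gene_tgt = sub$gene_tgt[members],
        ref_rank = sub$ref_rank[members], tgt_rank = sub$tgt_rank[members],
        stringsAsFactors = FALSE
      )
      active[members] <- FALSE
    }
  }
  chains <- if (length(chain_rows)) do.call(rbind, chain_rows) else
    data.frame(chain_id = integer(0), ref_chrom = character(0),
               tgt_chrom = character(0), orientation = character(0),
               score = numeric(0), n_anchors = integer(0),
               ref_rank_min = integer(0), ref_rank_max = integer(0),
               tgt_rank_min = integer(0), tgt_rank_max = integer(0))
  anchor_df <- if (length(anchor_rows)) do.call(rbind, anchor_rows) else
    data.frame(chain_id = integer(0), gene_ref = character(0),
               gene_tgt = character(0), ref_rank = integer(0),
               tgt_rank = integer(0))
  rownames(chains) <- rownames(anchor_df) <- NULL
  structure(list(chains = chains, anchors = anchor_df, params = params),
            class = "collinear_chains")
}

# Accept a gene table with or without an explicit within-chromosome rank.
normalize_gene_table <- function(g, what) {
  need <- c("gene_id", "chrom")
  if (!all(need %in% names(g))) {
    stop_invalid(what, " must have columns gene_id and chrom")
  }
  if (!"rank" %in% names(g)) {
    if ("start0" %in% names(g)) {
      g <- g[order(g$chrom, g$start0), ]
    }
    # ranks follow row order within each chromosome
    g$rank <- stats::ave(seq_len(nrow(g)), g$chrom, FUN = seq_along)
  }
  g
}

#' @export
print.collinear_chains <- function(x, ...) {
  cat(sprintf("%d collinear chain(s), %d anchors (match_size = %d, max_gaps = %d)\n",
              nrow(x$chains), nrow(x$anchors), x$params$match_size,
              x$params$max_gaps))
  if (nrow(x$chains) > 0) {
    tab <- table(x$chains$orientation)
    cat("  orientation: ", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}
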