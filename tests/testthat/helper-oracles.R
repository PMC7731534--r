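# Independent brute-force oracles, kept free of the package's DP code paths.

# Enumerate every collinear subsequence of the anchors (both orientations)
# and replay the greedy best-chain extraction exhaustively.
oracle_chains <- function(r, t, params) {
  ms <- params$match_score
  gp <- params$gap_penalty
  mg <- params$max_gaps
  K <- params$match_size
  ord <- order(r, t)
  r <- r[ord]
  t <- t[ord]
  n <- length(r)

  step_ok <- function(i, j, sign_t) {
    dr <- r[j] - r[i]
    dt <- sign_t * (t[j] - t[i])
    dr >= 1 && dt >= 1 && (max(dr, dt) - 1) <= mg
  }
  chain_score <- function(idx, sign_t) {
    s <- ms * length(idx)
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        g <- max(r[idx[k]] - r[idx[k - 1]],
                 sign_t * (t[idx[k]] - t[idx[k - 1]]))
        s <- s + gp * g
      }
    }
    s
  }
  all_chains <- function(active, sign_t) {
    out <- list()
    grow <- function(idx) {
      out[[length(out) + 1L]] <<- idx
      last <- idx[length(idx)]
      for (j in active[active > last]) {
        if (step_ok(last, j, sign_t)) grow(c(idx, j))
      }
    }
    for (i in active) grow(i)
    out
  }
  lex_less <- function(a, b) { # TRUE if a < b lexicographically
    for (k in seq_len(min(length(a), length(b)))) {
      if (a[k] != b[k]) return(a[k] < b[k])
    }
    length(a) < length(b)
  }

  chains <- list()
  active <- seq_len(n)
  repeat {
    if (length(active) < K) break
    best <- NULL
    for (sign_t in c(1, -1)) {
      for (idx in all_chains(active, sign_t)) {
        if (length(idx) < K) next
        sc <- chain_score(idx, sign_t)
        cand <- list(idx = idx, score = sc, len = length(idx),
                     orientation = if (sign_t == 1) "+" else "-")
        if (is.null(best) ||
            cand$score > best$score ||
            (cand$score == best$score && cand$len > best$len) ||
            (cand$score == best$score && cand$len == best$len &&
             best$orientation == "-" && cand$orientation == "+") ||
            (cand$score == best$score && cand$len == best$len &&
             cand$orientation == best$orientation &&
             lex_less(cand$idx, best$idx))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    chains[[length(chains) + 1L]] <- best
    active <- setdiff(active, best$idx)
  }
  list(chains = chains, order = ord)
}

# Exhaustive maximum-weight injective assignment of targets to references,
# fully enumerating reference permutations.
oracle_matching <- function(w) {
  n_ref <- nrow(w)
  n_tgt <- ncol(w)
  perms <- function(v) {
    if (length(v) <= 1L) return(matrix(v, ncol = length(v)))
    out <- NULL
    for (i in seq_along(v)) {
      sub <- perms(v[-i])
      out <- rbind(out, cbind(v[i], sub))
    }
    out
  }
  best <- -Inf
  combos <- utils::combn(n_ref, n_tgt)
  for (ci in seq_len(ncol(combos))) {
    refs <- combos[, ci]
    pm <- perms(refs)
    sc <- numeric(nrow(pm))
    for (i in seq_len(n_tgt)) sc <- sc + w[pm[, i] + (i - 1L) * n_ref]
    best <- max(best, max(sc))
  }
  best
}

# Independent NG86 single-pair computation used to cross-check the
# estimator: path enumeration written from scratch against the genetic code.
oracle_ng86_counts <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn_sites <- function(cd) {
    sp <- strsplit(cd, "")[[1]]
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, sp[p])) {
        alt <- sp; alt[p] <- b
        if (gc[[paste(alt, collapse = "")]] == gc[[cd]]) s <- s + 1 / 3
      }
    }
    s
  }
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- if (length(pos) == 0) list() else
    asplit(as.matrix(expand.grid(rep(list(pos), length(pos)))), 1)
  paths <- Filter(function(p) length(unique(p)) == length(pos), paths)
  res <- list()
  for (p in paths) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    sd <- 0; nd <- 0; blocked <- FALSE
    for (q in p) {
      prev <- paste(cur, collapse = "")
      cur[q] <- tgt[q]
      nxt <- paste(cur, collapse = "")
      if (gc[[nxt]] == "*" && nxt != c2) { blocked <- TRUE; break }
      if (gc[[prev]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
    }
    if (!blocked) res[[length(res) + 1L]] <- c(sd, nd)
  }
  if (length(pos) == 0) res <- list(c(0, 0))
  m <- do.call(rbind, res)
  list(S = (syn_sites(c1) + syn_sites(c2)) / 2,
       sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# Naive dictionary k-mer counter (canonical), for small sequences.
oracle_kmer_hist <- function(seqs, k) {
  counts <- new.env(parent = emptyenv())
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1L)) {
      km <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", km)) next
      rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(km, "")[[1]])),
                  collapse = "")
      can <- min(km, rc)
      counts[[can]] <- (if (is.null(counts[[can]])) 0L else counts[[can]]) + 1L
    }
  }
  mult <- unlist(as.list(counts))
  tab <- table(mult)
  data.frame(multiplicity = as.integer(names(tab)), count = as.integer(tab))
}
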