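# Codon-level machinery shared by the sequence generator and the NG86
# Ks/Ka estimator: synonymous-site counts, synonymous neighbour sets and
# evolutionary path classification.

.gc_cache <- new.env(parent = emptyenv())

genetic_code_tables <- function() {
  if (!is.null(.gc_cache$tab)) return(.gc_cache$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  sense <- codons[gc != "*"]
  bases <- c("A", "C", "G", "T")
  syn_neighbors <- vector("list", length(sense))
  names(syn_neighbors) <- sense
  syn_changes <- setNames(integer(length(sense)), sense)
  for (cd in sense) {
    nb <- character(0)
    sp <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(bases, sp[pos])) {
        alt <- sp
        alt[pos] <- b
        alt_cd <- paste(alt, collapse = "")
        if (gc[[alt_cd]] == gc[[cd]]) nb <- c(nb, alt_cd)
      }
    }
    syn_neighbors[[cd]] <- nb
    syn_changes[[cd]] <- length(nb)
  }
  tab <- list(
    code = gc,
    sense = sense,
    syn_neighbors = syn_neighbors,
    # NG86 fractional synonymous sites per codon: synonymous single-base
    # changes / 3 possible changes per position; changes to stop codons
    # count as nonsynonymous.
    syn_sites = syn_changes / 3
  )
  .gc_cache$tab <- tab
  tab
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop_invalid("CDS length ", n, " is not a multiple of 3")
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a coding sequence
#'
#' @param cds A single CDS string (length a multiple of 3, `ACGT` alphabet).
#' @return The peptide as a single string; stop codons are rendered as `*`.
#' @export
translate_cds <- function(cds) {
  tab <- genetic_code_tables()
  cods <- split_codons(cds)
  aa <- tab$code[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# A random CDS of `n_codons` sense codons (no internal stops).
random_cds <- function(n_codons) {
  tab <- genetic_code_tables()
  paste(sample(tab$sense, n_codons, replace = TRUE), collapse = "")
}

# Apply synonymous substitutions to one CDS so that the expected NG86
# proportion of synonymous differences against the original equals the
# proportion implied by `ks` under the Jukes-Cantor correction.
mutate_synonymous <- function(cds, ks) {
  if (ks < 0) stop_invalid("ks must be >= 0")
  if (ks == 0) return(cds)
  tab <- genetic_code_tables()
  p_s <- 0.75 * (1 - exp(-4 * ks / 3))
  cods <- split_codons(cds)
  prob <- p_s * tab$syn_sites[cods]
  prob[is.na(prob)] <- 0 # codons outside the sense table are left untouched
  prob <- pmin(prob, 1)
  fire <- runif(length(cods)) < prob
  if (any(fire)) {
    idx <- which(fire)
    cods[idx] <- vapply(cods[idx], function(cd) {
      nb <- tab$syn_neighbors[[cd]]
      nb[[sample.int(length(nb), 1L)]]
    }, character(1))
  }
  paste(cods, collapse = "")
}

# Enumerate mutational paths between two codons (equal path weighting),
# excluding paths through stop codons, and return the average synonymous /
# nonsynonymous difference counts. Memoised: the codon-pair space is tiny.
codon_path_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .gc_cache[[key]]
  if (!is.null(hit)) return(hit)
  tab <- genetic_code_tables()
  gc <- tab$code
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  count_path <- function(order) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    sd <- 0
    nd <- 0
    for (p in order) {
      prev <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      nxt <- paste(cur, collapse = "")
      if (gc[[nxt]] == "*" && nxt != c2) return(NULL) # path through a stop
      if (gc[[prev]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd, nd)
  }
  orders <- if (length(pos) == 1L) list(pos) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
      }
      out
    }
    perms(pos)
  }
  counts <- Filter(Negate(is.null), lapply(orders, count_path))
  if (length(counts) == 0L) {
    # every path runs through a stop codon; fall back to counting all paths
    # with stop-crossing steps classified as nonsynonymous
    counts <- lapply(orders, function(order) {
      cur <- strsplit(c1, "")[[1]]
      tgt <- strsplit(c2, "")[[1]]
      sd <- 0; nd <- 0
      for (p in order) {
        prev <- paste(cur, collapse = "")
        cur[p] <- tgt[p]
        nxt <- paste(cur, collapse = "")
        if (gc[[prev]] != "*" && gc[[nxt]] != "*" && gc[[prev]] == gc[[nxt]]) {
          sd <- sd + 1
        } else nd <- nd + 1
      }
      c(sd, nd)
    })
  }
  m <- do.call(rbind, counts)
  res <- colMeans(m)
  assign(key, res, envir = .gc_cache)
  res
}
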