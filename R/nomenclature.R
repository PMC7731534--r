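#' Build a reference-by-target homology matrix from chains
#'
#' For every (reference chromosome, target chromosome) pair, sums the
#' reference-side bp spans of the collinear chains linking them after
#' merging overlapping spans on the reference (so a reference stretch is
#' never counted twice), and expresses each cell additionally as a
#' percentage of the reference chromosome length.
#'
#' @param chains A `collinear_chains` object whose chains carry reference
#'   bp spans (gene tables with `start0`/`end0` were supplied to
#'   [chain_anchors()]).
#' @param ref_lengths Named numeric vector: reference chromosome lengths
#'   (bp).
#' @return An object of class `homology_matrix`: a list with `bp` (matrix,
#'   rows = reference chromosomes, columns = target chromosomes), `pct`
#'   and `ref_lengths`.
#' @export
build_homology_matrix <- function(chains, ref_lengths) {
  stopifnot(inherits(chains, "collinear_chains"))
  ch <- chains$chains
  if (nrow(ch) == 0L) stop_invalid("no chains")
  if (!all(c("ref_start0", "ref_end0") %in% names(ch))) {
    stop_invalid("chains carry no bp spans; supply gene coordinates to chain_anchors")
  }
  unknown <- setdiff(unique(ch$ref_chrom), names(ref_lengths))
  if (length(unknown) > 0L) {
    stop_invalid("chains reference unknown chromosome(s): ",
                 paste(unknown, collapse = ", "))
  }
  refs <- names(ref_lengths)
  tgts <- sort(unique(ch$tgt_chrom))
  bp <- matrix(0, length(refs), length(tgts), dimnames = list(refs, tgts))
  for (r in refs) {
    for (t in tgts) {
      sel <- ch$ref_chrom == r & ch$tgt_chrom == t
      if (!any(sel)) next
      ir <- IRanges::reduce(IRanges::IRanges(start = ch$ref_start0[sel] + 1L,
                                             end = ch$ref_end0[sel]))
      bp[r, t] <- sum(IRanges::width(ir))
    }
  }
  pct <- sweep(bp, 1, ref_lengths[refs], "/") * 100
  structure(list(bp = bp, pct = pct, ref_lengths = ref_lengths[refs]),
            class = "homology_matrix")
}

#' Parse a printed homology table
#'
#' Reads the tab-separated dialect of a published chromosome-homology
#' grid: one row per reference chromosome, and per target chromosome an
#' alternating pair of columns `<target>_bp` and `<target>_pct`. Empty
#' cells are zero. When reference lengths are supplied the percentages are
#' cross-checked against `bp / length`.
#'
#' @param path File path (or a data frame already in the dialect).
#' @param ref_lengths Optional named lengths for cross-checking.
#' @param tol Relative tolerance of the percentage cross-check.
#' @return A `homology_matrix` (with `NA` lengths when not supplied).
#' @export
parse_homology_table <- function(path, ref_lengths = NULL, tol = 0.05) {
  df <- if (is.data.frame(path)) path else {
    read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
               stringsAsFactors = FALSE)
  }
  if (names(df)[1] != "ref") {
    stop_invalid("malformed homology table: first column must be 'ref'")
  }
  cols <- names(df)[-1]
  bp_cols <- grep("_bp$", cols, value = TRUE)
  pct_cols <- grep("_pct$", cols, value = TRUE)
  tgts_bp <- sub("_bp$", "", bp_cols)
  tgts_pct <- sub("_pct$", "", pct_cols)
  if (!identical(sort(tgts_bp), sort(tgts_pct))) {
    stop_invalid("malformed homology table: bp/pct columns do not pair up")
  }
  tgts <- tgts_bp
  refs <- as.character(df$ref)
  to_num <- function(x, what) {
    x[is.na(x) | x == ""] <- "0"
    v <- suppressWarnings(as.numeric(gsub(",", "", x)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop_invalid("malformed cell in column ", what, ", row ", refs[bad])
    }
    v
  }
  bp <- sapply(tgts, function(t) to_num(df[[paste0(t, "_bp")]], paste0(t, "_bp")))
  pct <- sapply(tgts, function(t) to_num(df[[paste0(t, "_pct")]], paste0(t, "_pct")))
  if (is.null(dim(bp))) {
    bp <- matrix(bp, nrow = length(refs))
    pct <- matrix(pct, nrow = length(refs))
    colnames(bp) <- colnames(pct) <- tgts
  }
  rownames(bp) <- rownames(pct) <- refs
  if (!is.null(ref_lengths)) {
    expected <- sweep(bp, 1, ref_lengths[refs], "/") * 100
    off <- abs(expected - pct) > tol * pmax(pct, 1)
    if (any(off & bp > 0)) {
      warning(sum(off & bp > 0), " cell(s) fail the bp/length percentage cross-check")
    }
    lens <- ref_lengths[refs]
  } else {
    lens <- setNames(rep(NA_real_, length(refs)), refs)
  }
  structure(list(bp = bp, pct = pct, ref_lengths = lens),
            class = "homology_matrix")
}

#' Write a homology matrix in the printed-table dialect
#'
#' @param mat A `homology_matrix`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_homology_table <- function(mat, path) {
  stopifnot(inherits(mat, "homology_matrix"))
  df <- data.frame(ref = rownames(mat$bp), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (t in colnames(mat$bp)) {
    df[[paste0(t, "_bp")]] <- format(mat$bp[, t], trim = TRUE, scientific = FALSE)
    df[[paste0(t, "_pct")]] <- format(mat$pct[, t], trim = TRUE,
                                      scientific = FALSE, digits = 15)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.homology_matrix <- function(x, ...) {
  cat(sprintf("Homology matrix: %d reference x %d target chromosomes; max cell %.1f%%\n",
              nrow(x$bp), ncol(x$bp), max(x$pct)))
  invisible(x)
}

# Exact maximum-weight one-to-one assignment of targets to references via
# DP over reference subsets (feasible for the chromosome-count scale).
max_weight_matching <- function(w) {
  n_ref <- nrow(w)
  n_tgt <- ncol(w)
  if (n_ref > 20L) stop_invalid("matching supports at most 20 reference chromosomes")
  full <- bitwShiftL(1L, n_ref) - 1L
  n_states <- full + 1L
  # g[i, S]: best total for targets i..n_tgt using references in S
  g <- matrix(-Inf, n_tgt + 1L, n_states)
  g[n_tgt + 1L, ] <- 0
  for (i in n_tgt:1L) {
    for (S in 0:full) {
      best <- -Inf
      for (r in seq_len(n_ref)) {
        bit <- bitwShiftL(1L, r - 1L)
        if (bitwAnd(S, bit) == 0L) next
        v <- w[r, i] + g[i + 1L, bitwXor(S, bit) + 1L]
        if (v > best) best <- v
      }
      g[i, S + 1L] <- best
    }
  }
  # reconstruct, preferring the smallest reference index at each target
  S <- full
  pick <- integer(n_tgt)
  for (i in seq_len(n_tgt)) {
    for (r in seq_len(n_ref)) {
      bit <- bitwShiftL(1L, r - 1L)
      if (bitwAnd(S, bit) == 0L) next
      if (w[r, i] + g[i + 1L, bitwXor(S, bit) + 1L] == g[i, S + 1L]) {
        pick[i] <- r
        S <- bitwXor(S, bit)
        break
      }
    }
  }
  list(pick = pick, total = g[1L, full + 1L])
}

#' Assign pseudochromosome names by maximum homology
#'
#' Names each target chromosome after a reference chromosome via a
#' maximum-weight one-to-one matching on the homology matrix (bp), so that
#' the naming is injective; the unmatched reference names are reported as
#' excluded. The per-target greedy maximum is reported alongside, and any
#' target whose matched name differs from its greedy maximum is logged as
#' a forced exception. References listed in `exclude` are removed before
#' matching (the published procedure excluded the surplus reference
#' chromosomes a priori).
#'
#' @param mat A `homology_matrix`.
#' @param n_target Number of target chromosomes to name (defaults to all
#'   columns; must not exceed the number of references).
#' @param exclude Optional reference chromosome names removed before
#'   matching.
#' @return An object of class `nomenclature_assignment`: a list with
#'   `assignment` (data frame: `target`, `new_name`, `bp`, `pct`,
#'   `greedy_name`, `forced_exception`), `excluded` (character) and
#'   `total_bp` (matching weight).
#' @export
assign_names <- function(mat, n_target = ncol(mat$bp), exclude = NULL) {
  stopifnot(inherits(mat, "homology_matrix"))
  bp <- mat$bp
  pct <- mat$pct
  if (!is.null(exclude)) {
    keep <- !(rownames(bp) %in% exclude)
    bp <- bp[keep, , drop = FALSE]
    pct <- pct[keep, , drop = FALSE]
  }
  if (n_target > ncol(bp)) stop_invalid("n_target exceeds the matrix columns")
  bp <- bp[, seq_len(n_target), drop = FALSE]
  pct <- pct[, seq_len(n_target), drop = FALSE]
  if (n_target > nrow(bp)) {
    stop_invalid("more target chromosomes than available reference names")
  }
  if (all(bp == 0)) {
    stop(errorCondition("degenerate all-zero homology matrix",
                        class = c("triadsynt_no_assignment", "error")))
  }
  m <- max_weight_matching(bp)
  refs <- rownames(bp)
  greedy <- refs[apply(bp, 2, which.max)]
  assignment <- data.frame(
    target = colnames(bp),
    new_name = refs[m$pick],
    bp = bp[cbind(m$pick, seq_len(n_target))],
    pct = pct[cbind(m$pick, seq_len(n_target))],
    greedy_name = greedy,
    forced_exception = refs[m$pick] != greedy,
    stringsAsFactors = FALSE
  )
  excluded <- c(exclude, setdiff(refs, assignment$new_name))
  structure(list(assignment = assignment,
                 excluded = unique(excluded),
                 total_bp = m$total),
            class = "nomenclature_assignment")
}

#' @export
print.nomenclature_assignment <- function(x, ...) {
  cat("Pseudochromosome naming (maximum-homology matching):\n")
  for (i in seq_len(nrow(x$assignment))) {
    a <- x$assignment[i, ]
    cat(sprintf("  %s -> %s (%.0f bp, %.1f%%)%s\n", a$target, a$new_name,
                a$bp, a$pct,
                if (a$forced_exception) paste0(" [exception; greedy maximum ",
                                               a$greedy_name, "]") else ""))
  }
  if (length(x$excluded)) {
    cat("  excluded references:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Render a nomenclature report table
#'
#' Emits the homology grid with naming rows on top: optional legacy name
#' rows (e.g. earlier genetic-map nomenclatures) and the new names
#' produced by [assign_names()], followed by the bp / percentage cells per
#' reference chromosome.
#'
#' @param assignment A `nomenclature_assignment`.
#' @param mat The `homology_matrix` it was computed from.
#' @param legacy Optional named list of character vectors (one per legacy
#'   version, aligned with the matrix's target columns).
#' @return A character data frame ready for `write.table`.
#' @export
render_nomenclature_report <- function(assignment, mat, legacy = NULL) {
  stopifnot(inherits(assignment, "nomenclature_assignment"),
            inherits(mat, "homology_matrix"))
  tgts <- colnames(mat$bp)
  header_rows <- list()
  if (!is.null(legacy)) {
    for (nm in names(legacy)) {
      header_rows[[nm]] <- c(nm, as.character(legacy[[nm]])[seq_along(tgts)])
    }
  }
  new_names <- assignment$assignment$new_name[match(tgts, assignment$assignment$target)]
  header_rows[["V3"]] <- c("V3", ifelse(is.na(new_names), "", new_names))
  body <- lapply(rownames(mat$bp), function(r) {
    cells <- vapply(tgts, function(t) {
      if (mat$bp[r, t] == 0) "" else
        sprintf("%.0f (%s%%)", mat$bp[r, t],
                format(mat$pct[r, t], digits = 3, trim = TRUE))
    }, character(1))
    c(r, cells)
  })
  rows <- c(header_rows, body)
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("row", tgts)
  rownames(out) <- NULL
  out
}
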