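#' K-mer histogram of a sequence set
#'
#' Counts canonical k-mers (the lexicographic minimum of each k-mer and its
#' reverse complement, the standard convention for unoriented reads) over a
#' set of DNA sequences and tabulates the multiplicity spectrum. K-mers
#' containing characters outside `ACGT` are skipped.
#'
#' @param sequences Character vector (or `DNAStringSet`) of sequences.
#' @param k K-mer length (`>= 1`).
#' @return An object of class `kmer_histogram`: a list with `k` and
#'   `counts`, a data frame of `multiplicity` and `count` (number of
#'   distinct k-mers seen that many times).
#' @examples
#' build_kmer_histogram("AAAA", k = 2) # the k-mer AA occurs 3 times
#' @export
build_kmer_histogram <- function(sequences, k) {
  if (k < 1) stop_invalid("k must be >= 1")
  sequences <- as.character(sequences)
  kmers <- character(0)
  for (s in sequences) {
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    km <- km[!grepl("[^ACGT]", km)]
    kmers <- c(kmers, km)
  }
  if (length(kmers) == 0L) {
    stop(errorCondition(
      paste0("no valid k-mers: k = ", k, " exceeds every sequence length"),
      class = c("triadsynt_empty_histogram", "error")
    ))
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  canonical <- pmin(kmers, rc)
  mult <- table(canonical)
  spectrum <- table(as.integer(mult))
  counts <- data.frame(multiplicity = as.integer(names(spectrum)),
                       count = as.integer(spectrum))
  structure(list(k = as.integer(k), counts = counts), class = "kmer_histogram")
}

#' Simulate a k-mer frequency histogram
#'
#' Draws the multiplicity spectrum of a sequencing run directly from the
#' standard mixture model: distinct genomic k-mers (one per genome
#' position, assumed unique) receive Poisson counts at the effective
#' coverage \eqn{\lambda (1-e)^k}, and sequencing errors contribute a
#' low-multiplicity spike of novel k-mers.
#'
#' @param genome_size Genome size in bp.
#' @param coverage Mean sequencing depth (\eqn{\lambda > 0}).
#' @param error_rate Per-base error probability (`0 <= e < 1`).
#' @param k K-mer length.
#' @param seed Integer seed; identical seeds give identical histograms.
#' @return A `kmer_histogram`.
#' @export
simulate_kmer_histogram <- function(genome_size, coverage, error_rate = 0,
                                    k = 21, seed = 1) {
  if (k <= 0) stop_invalid("k must be positive")
  if (coverage <= 0) stop_invalid("coverage must be positive")
  if (error_rate < 0 || error_rate >= 1) stop_invalid("error_rate must be in [0, 1)")
  with_op_seed(seed, "kmer_histogram", {
    lambda_eff <- coverage * (1 - error_rate)^k
    mult <- rpois(genome_size, lambda_eff)
    mult <- mult[mult > 0L]
    spectrum <- table(mult)
    counts <- data.frame(multiplicity = as.integer(names(spectrum)),
                         count = as.integer(spectrum))
    # error k-mers: one novel k-mer per erroneous k-mer position, seen once
    n_err <- rpois(1L, genome_size * coverage * (1 - (1 - error_rate)^k))
    if (n_err > 0L) {
      if (1L %in% counts$multiplicity) {
        counts$count[counts$multiplicity == 1L] <-
          counts$count[counts$multiplicity == 1L] + n_err
      } else {
        counts <- rbind(data.frame(multiplicity = 1L, count = n_err), counts)
      }
    }
    counts <- counts[order(counts$multiplicity), ]
    rownames(counts) <- NULL
    structure(list(k = as.integer(k), counts = counts), class = "kmer_histogram")
  })
}

#' Estimate genome size from a k-mer histogram
#'
#' Valley/peak estimator: the error spike at low multiplicity is separated
#' from the coverage peak at the first local minimum (valley) of the
#' spectrum; the genome size is the total k-mer mass above the valley
#' divided by the peak depth,
#' \deqn{\hat G = \sum_{m \ge valley} m \cdot c_m / m_{peak}.}
#' The peak is searched strictly above the valley, ties broken toward lower
#' multiplicity.
#'
#' @param hist A `kmer_histogram`.
#' @return An object of class `genome_size_estimate`: a list with
#'   `genome_size` (bp), `valley` and `peak_depth` diagnostics.
#' @export
estimate_genome_size <- function(hist) {
  stopifnot(inherits(hist, "kmer_histogram"))
  max_m <- max(hist$counts$multiplicity)
  dense <- numeric(max_m)
  dense[hist$counts$multiplicity] <- hist$counts$count
  upturn <- which(diff(dense) > 0)
  if (length(upturn) == 0L) {
    stop(errorCondition(
      paste0("no coverage peak: histogram is monotone non-increasing over ",
             max_m, " multiplicities"),
      class = c("triadsynt_no_peak", "error")
    ))
  }
  valley <- upturn[1]
  above <- (valley + 1L):max_m
  peak_depth <- above[which.max(dense[above])]
  mass <- sum(seq(valley, max_m) * dense[valley:max_m])
  structure(list(genome_size = mass / peak_depth, valley = valley,
                 peak_depth = peak_depth), class = "genome_size_estimate")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  total <- sum(as.numeric(x$counts$multiplicity) * x$counts$count)
  cat(sprintf("k-mer histogram (k = %d): %d multiplicity classes, %d distinct k-mers, %.0f counted positions\n",
              x$k, nrow(x$counts), sum(x$counts$count), total))
  invisible(x)
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf("Estimated genome size: %.0f bp (valley at %d, peak depth %d)\n",
              x$genome_size, x$valley, x$peak_depth))
  invisible(x)
}

#' Read / write a k-mer histogram as TSV
#'
#' The two-column (multiplicity, count) text format shared by common k-mer
#' counter dumps.
#'
#' @param path File path.
#' @param hist A `kmer_histogram`.
#' @param k K-mer length to record on reading (the format does not carry it).
#' @return `read_kmer_histogram` returns a `kmer_histogram`;
#'   `write_kmer_histogram` returns `path` invisibly.
#' @export
read_kmer_histogram <- function(path, k = 21L) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("multiplicity", "count"))
  structure(list(k = as.integer(k),
                 counts = df[order(df$multiplicity), , drop = FALSE]),
            class = "kmer_histogram")
}

#' @rdname read_kmer_histogram
#' @export
write_kmer_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "kmer_histogram"))
  write.table(hist$counts, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assembly summary statistics
#'
#' Sequence count, total length, longest sequence and N50 (the length at
#' which the cumulative sorted-descending lengths first reach half the
#' total).
#'
#' @param lengths Vector of sequence lengths in bp (all `>= 1`).
#' @return An object of class `assembly_stats`: `n_sequences`, `total_bp`,
#'   `longest_bp`, `n50_bp`.
#' @examples
#' assembly_stats(c(5, 4, 3, 2, 1)) # N50 = 4
#' @export
assembly_stats <- function(lengths) {
  if (length(lengths) == 0L) stop_invalid("empty length list")
  if (any(lengths < 1)) stop_invalid("lengths must be >= 1")
  lens <- sort(as.numeric(lengths), decreasing = TRUE)
  total <- sum(lens)
  n50 <- lens[which(cumsum(lens) >= total / 2)[1]]
  structure(list(n_sequences = length(lens), total_bp = total,
                 longest_bp = lens[1], n50_bp = n50),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("%d sequences, %.0f bp total, longest %.0f bp, N50 %.0f bp\n",
              x$n_sequences, x$total_bp, x$longest_bp, x$n50_bp))
  invisible(x)
}

#' Fraction of the genome assigned to pseudochromosomes
#'
#' Assigned length divided by the (k-mer based) genome-size estimate,
#' expressed as a percentage truncated to one decimal, the convention used
#' when quoting how much of an estimated genome an anchored assembly
#' covers.
#'
#' @param assigned_bp Total bp assigned to linkage groups.
#' @param genome_size_bp Estimated genome size in bp.
#' @return Percentage truncated (not rounded) to one decimal.
#' @examples
#' assigned_fraction(505183631, 522.13e6)
#' @export
assigned_fraction <- function(assigned_bp, genome_size_bp) {
  if (genome_size_bp <= 0) stop_invalid("genome size must be positive")
  floor(assigned_bp / genome_size_bp * 1000) / 10
}
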