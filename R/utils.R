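#' @importFrom stats rpois rgeom runif median cor var setNames
#' @importFrom utils head tail read.table write.table
NULL

# Derive a deterministic sub-seed for one named operation from the master
# seed. Keeps every value strictly below 2^31 - 1.
derive_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  chars <- utf8ToInt(op)
  h <- sum(chars * seq_along(chars))
  as.integer((abs(seed) * 7919 + h * 131) %% 2147483629)
}

# Evaluate `expr` under a deterministic per-operation RNG stream without
# disturbing the caller's RNG state.
with_op_seed <- function(seed, op, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, op))
  expr
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("triadsynt_invalid", "error")))
}

# Random DNA helpers ---------------------------------------------------------

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
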