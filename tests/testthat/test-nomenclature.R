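fake_chains <- function(df) {
  # df: ref_chrom, tgt_chrom, ref_start0, ref_end0
  df$chain_id <- seq_len(nrow(df))
  df$orientation <- "+"
  df$score <- 100
  df$n_anchors <- 5L
  structure(list(chains = df,
                 anchors = data.frame(chain_id = integer(0)),
                 params = chain_params()),
            class = "collinear_chains")
}

test_that("homology cells sum disjoint spans and merge overlapping ones", {
  lens <- c(R1 = 1e6)
  one <- fake_chains(data.frame(ref_chrom = "R1", tgt_chrom = "T1",
                                ref_start0 = 0, ref_end0 = 1e6))
  m1 <- build_homology_matrix(one, lens)
  expect_equal(m1$bp["R1", "T1"], 1e6)
  expect_equal(m1$pct["R1", "T1"], 100)

  two <- fake_chains(data.frame(ref_chrom = "R1", tgt_chrom = c("T1", "T1"),
                                ref_start0 = c(0, 5e5), ref_end0 = c(2e5, 7e5)))
  expect_equal(build_homology_matrix(two, lens)$bp["R1", "T1"], 4e5)

  overlap <- fake_chains(data.frame(ref_chrom = "R1", tgt_chrom = c("T1", "T1"),
                                    ref_start0 = c(0, 0), ref_end0 = c(2e5, 2e5)))
  expect_equal(build_homology_matrix(overlap, lens)$bp["R1", "T1"], 2e5)

  bad <- fake_chains(data.frame(ref_chrom = "R9", tgt_chrom = "T1",
                                ref_start0 = 0, ref_end0 = 10))
  expect_error(build_homology_matrix(bad, lens), class = "triadsynt_invalid")
})

test_that("the transcribed homology table parses to a 10 x 8 grid", {
  m <- parse_homology_table(table2_path())
  expect_equal(dim(m$bp), c(10, 8))
  expect_equal(rownames(m$bp), sprintf("A%02d", 1:10))
  expect_equal(colnames(m$bp), sprintf("B%02d", 1:8))
  expect_equal(sum(m$bp == 0), 80 - 33) # 33 populated cells
  # empty cells are zeros and all percentages are within a chromosome
  expect_true(all(m$pct >= 0 & m$pct <= 100))
  expect_true(all(rowSums(m$pct) <= 100 + 1e-9))
})

test_that("a full scan of the transcribed table finds the A10 maximum of 72.1%", {
  m <- parse_homology_table(table2_path())
  expect_equal(max(m$pct), 72.1)
  idx <- which(m$pct == max(m$pct), arr.ind = TRUE)
  expect_equal(rownames(m$pct)[idx[1]], "A10")
  expect_equal(m$bp[idx], 14954862)
})

test_that("diagonal-dominant matrices are named identically with no exception", {
  w <- diag(8) * 100 + 1
  rownames(w) <- sprintf("R%d", 1:8)
  colnames(w) <- sprintf("T%d", 1:8)
  mat <- structure(list(bp = w, pct = w / 10,
                        ref_lengths = setNames(rep(1000, 8), rownames(w))),
                   class = "homology_matrix")
  a <- assign_names(mat)
  expect_equal(a$assignment$new_name, rownames(w))
  expect_false(any(a$assignment$forced_exception))
  expect_equal(length(a$excluded), 0)
})

test_that("two targets against three references exclude exactly one reference", {
  # brute force over all 6 injective assignments: optimum is T1->R2, T2->R3
  w <- matrix(c(5, 1,
                9, 2,
                4, 8), nrow = 3, byrow = TRUE,
              dimnames = list(c("R1", "R2", "R3"), c("T1", "T2")))
  mat <- structure(list(bp = w, pct = w, ref_lengths = c(R1 = 1, R2 = 1, R3 = 1)),
                   class = "homology_matrix")
  a <- assign_names(mat)
  expect_equal(a$assignment$new_name, c("R2", "R3"))
  expect_equal(a$excluded, "R1")
  expect_equal(a$total_bp, 17)
  expect_equal(length(a$excluded), nrow(w) - ncol(w))
})

test_that("matching equals exhaustive search on random matrices up to 8 x 10", {
  set.seed(51)
  sizes <- list(c(3, 2), c(4, 3), c(6, 5), c(8, 6), c(10, 8))
  for (sz in sizes) {
    for (rep in 1:3) {
      w <- matrix(runif(sz[1] * sz[2], 0, 1e6), sz[1], sz[2],
                  dimnames = list(sprintf("R%02d", seq_len(sz[1])),
                                  sprintf("T%02d", seq_len(sz[2]))))
      mat <- structure(list(bp = w, pct = w,
                            ref_lengths = setNames(rep(1, sz[1]),
                                                   rownames(w))),
                       class = "homology_matrix")
      a <- assign_names(mat)
      expect_equal(a$total_bp, oracle_matching(w), tolerance = 1e-9)
      expect_equal(length(a$excluded), sz[1] - sz[2])
    }
  }
})

test_that("naming is equivariant under target permutations", {
  set.seed(52)
  w <- matrix(runif(80, 0, 1e6), 10, 8,
              dimnames = list(sprintf("R%02d", 1:10), sprintf("T%02d", 1:8)))
  mat <- structure(list(bp = w, pct = w,
                        ref_lengths = setNames(rep(1, 10), rownames(w))),
                   class = "homology_matrix")
  a <- assign_names(mat)
  perm <- sample(8)
  mat2 <- mat
  mat2$bp <- w[, perm]
  mat2$pct <- mat2$bp
  a2 <- assign_names(mat2)
  expect_equal(a2$assignment$new_name,
               a$assignment$new_name[perm])
})

test_that("forced exceptions are logged when matching overrides the greedy maximum", {
  # both targets prefer R1; matching must push one of them elsewhere
  w <- matrix(c(10, 9,
                2, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("R1", "R2"), c("T1", "T2")))
  mat <- structure(list(bp = w, pct = w, ref_lengths = c(R1 = 1, R2 = 1)),
                   class = "homology_matrix")
  a <- assign_names(mat)
  expect_equal(a$assignment$new_name, c("R1", "R2"))
  expect_equal(a$assignment$greedy_name, c("R1", "R1"))
  expect_equal(a$assignment$forced_exception, c(FALSE, TRUE))
})

test_that("a-priori exclusions reproduce the published naming convention", {
  m <- parse_homology_table(table2_path())
  a <- assign_names(m, n_target = 8, exclude = c("A09", "A10"))
  expect_equal(a$assignment$new_name, sprintf("A%02d", 1:8))
  expect_equal(sort(a$excluded), c("A09", "A10"))
  expect_error(assign_names(structure(list(bp = matrix(0, 2, 2,
                                                       dimnames = list(c("a","b"), c("c","d"))),
                                           pct = matrix(0, 2, 2),
                                           ref_lengths = c(a = 1, b = 1)),
                                      class = "homology_matrix")),
               class = "triadsynt_no_assignment")
})

test_that("homology matrices round-trip through the table dialect", {
  set.seed(53)
  w <- matrix(round(runif(12, 0, 1e6)), 4, 3,
              dimnames = list(sprintf("R%d", 1:4), sprintf("T%d", 1:3)))
  lens <- setNames(round(runif(4, 1e6, 2e6)), rownames(w))
  mat <- structure(list(bp = w, pct = sweep(w, 1, lens, "/") * 100,
                        ref_lengths = lens), class = "homology_matrix")
  path <- tempfile(fileext = ".tsv")
  write_homology_table(mat, path)
  back <- parse_homology_table(path, ref_lengths = lens)
  expect_equal(back$bp, mat$bp)
  expect_equal(back$pct, mat$pct)
})

test_that("nomenclature report renders legacy and new name rows", {
  m <- parse_homology_table(table2_path())
  a <- assign_names(m, n_target = 8, exclude = c("A09", "A10"))
  rep1 <- render_nomenclature_report(a, m)
  expect_equal(rep1[[1]][1], "V3")
  expect_equal(nrow(rep1), 1 + 10)
  legacy <- list(V1 = c("B01", "B06", "B02", "B07", "B04", "B05", "B08", "B03"),
                 V2 = c("B02", "B06", "B03", "B05", "B04", "B08", "B07", "B01"))
  rep2 <- render_nomenclature_report(a, m, legacy)
  expect_equal(rep2[[1]][1:3], c("V1", "V2", "V3"))
  expect_equal(unlist(rep2[3, -1], use.names = FALSE), a$assignment$new_name)
})
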