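test_that("a single clean chain projects to one block copy", {
  ref_blocks <- data.frame(gene_id = sprintf("a%02d", 1:10), block = "F")
  chains <- structure(list(
    chains = data.frame(chain_id = 1L, ref_chrom = "R1", tgt_chrom = "T1",
                        orientation = "+", score = 500, n_anchors = 10),
    anchors = data.frame(chain_id = 1L, gene_ref = sprintf("a%02d", 1:10),
                         gene_tgt = sprintf("b%02d", 1:10),
                         ref_rank = 1:10, tgt_rank = 1:10),
    params = chain_params()
  ), class = "collinear_chains")
  bc <- project_blocks(chains, ref_blocks)
  expect_equal(nrow(bc), 1)
  expect_equal(bc$block, "F")
  expect_equal(bc$retained, 10)
  expect_equal(bc$reference, 10)
})

test_that("chains spanning a block boundary are split at the boundary", {
  ref_blocks <- data.frame(gene_id = sprintf("a%02d", 1:10),
                           block = rep(c("A", "B"), each = 5))
  chains <- structure(list(
    chains = data.frame(chain_id = 1L, ref_chrom = "R1", tgt_chrom = "T1",
                        orientation = "+", score = 500, n_anchors = 10),
    anchors = data.frame(chain_id = 1L, gene_ref = sprintf("a%02d", 1:10),
                         gene_tgt = sprintf("b%02d", 1:10),
                         ref_rank = 1:10, tgt_rank = 1:10),
    params = chain_params()
  ), class = "collinear_chains")
  bc <- project_blocks(chains, ref_blocks)
  expect_equal(sort(bc$block), c("A", "B"))
  expect_equal(attr(bc, "splits"), 1L)
})

test_that("clean triplication yields three copies of every block label", {
  copies <- shared_copies()
  tab <- table(copies$block)
  expect_equal(length(tab), 24)
  # modal copy number is the triplication signature
  expect_equal(as.integer(names(sort(-table(as.integer(tab))))[1]), 3)
})

test_that("zero retention in one paleogenome leaves two copies per block", {
  anc <- build_ancestral_genome(6, 30, cds_codons = 120, seed = 61)
  fr <- triplicate_and_fractionate(anc, c(1, 1, 0), seed = 61)
  lay <- shuffle_blocks_into_chromosomes(fr, 4, seed = 61)
  evo <- evolve_sequences(lay, anc, seed = 61)
  anch <- score_gene_pairs(evo$ref_cds, evo$tgt_cds)
  ref_genes <- anc$genes
  ref_genes$chrom <- "R1"
  ref_genes$rank <- seq_len(nrow(ref_genes))
  tgt_genes <- data.frame(gene_id = lay$genes$gene_id, chrom = lay$genes$chrom,
                          rank = lay$genes$index)
  ch <- chain_anchors(anch, ref_genes, tgt_genes)
  bc <- project_blocks(ch, data.frame(gene_id = ref_genes$gene_id,
                                      block = ref_genes$block))
  expect_true(all(table(bc$block) == 2))
})

test_that("subgenome labels and ranking recover the planted truth", {
  sim <- shared_sim()
  lab <- label_subgenomes(shared_copies())
  gm <- attr(lab, "gene_map")
  pred <- setNames(lab$subgenome[gm$copy_id], gm$gene_tgt)
  tr <- sim$truth$genes
  tr <- tr[tr$subgenome %in% c("LF", "MF1", "MF2"), ]
  tr <- tr[tr$gene_id %in% names(pred), ]
  expect_gte(mean(pred[tr$gene_id] == tr$subgenome), 0.95)
  s <- attr(lab, "summary")
  expect_true(s$retained[["LF"]] >= s$retained[["MF1"]])
  expect_true(s$retained[["MF1"]] >= s$retained[["MF2"]])
})

test_that("a single block with retention 5/3/1 is forcibly ranked LF/MF1/MF2", {
  copies <- structure(data.frame(
    copy_id = 1:3, block = "A", tgt_chrom = c("T1", "T2", "T3"),
    rank_min = 1, rank_max = 5, retained = c(5, 3, 1), reference = 5,
    subgenome = "unassigned", stringsAsFactors = FALSE
  ), class = c("block_copies", "data.frame"),
  gene_map = data.frame(gene_tgt = character(0), copy_id = integer(0)))
  lab <- label_subgenomes(copies)
  expect_equal(lab$subgenome, c("LF", "MF1", "MF2"))
})

test_that("subgenome ordering is recovered across seeded replicates", {
  anc <- build_ancestral_genome(24, 50, cds_codons = 10, seed = 71)
  ok <- vapply(1:20, function(s) {
    fr <- triplicate_and_fractionate(anc, c(0.55, 0.45, 0.40), seed = 7000 + s)
    lay <- shuffle_blocks_into_chromosomes(fr, 8, seed = 7000 + s)
    # copies as a perfect projection would see them
    g <- lay$genes
    g$key <- paste(g$block, g$subgenome, g$chrom)
    agg <- do.call(rbind, lapply(split(g, g$key), function(x) {
      data.frame(block = x$block[1], tgt_chrom = x$chrom[1],
                 rank_min = min(x$index), rank_max = max(x$index),
                 retained = nrow(x), subgenome_true = x$subgenome[1],
                 stringsAsFactors = FALSE)
    }))
    agg <- agg[order(agg$tgt_chrom, agg$rank_min), ]
    agg$copy_id <- seq_len(nrow(agg))
    agg$reference <- 50L
    agg$subgenome <- "unassigned"
    copies <- structure(agg[, c("copy_id", "block", "tgt_chrom", "rank_min",
                                "rank_max", "retained", "reference",
                                "subgenome")],
                        class = c("block_copies", "data.frame"),
                        gene_map = data.frame(gene_tgt = character(0),
                                              copy_id = integer(0)))
    lab <- label_subgenomes(copies)
    # ordering recovered: each labelled group majority-matches its true
    # paleogenome, so the LF/MF1/MF2 ranking maps onto the planted rates
    all(vapply(c("LF", "MF1", "MF2"), function(sg) {
      mean(lab$subgenome[agg$subgenome_true == sg] == sg) > 0.5
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("retention profiles hit the trivial limits and binomial rates", {
  sim <- shared_sim()
  lab <- label_subgenomes(shared_copies())
  # at desk scale the 500-gene window exceeds a reference chromosome, so
  # the profile falls back to full-chromosome windows (with a warning)
  expect_warning(
    prof <- retention_profile(lab, shared_calls(), sim$reference$genes,
                              window = 500),
    "full-chromosome"
  )
  expect_true(all(prof$LF >= 0 & prof$LF <= 1))
  # window-averaged rates approximate the planted retention probabilities
  for (sg in c("LF", "MF1", "MF2")) {
    rate <- sim$params$retention[match(sg, c("LF", "MF1", "MF2"))]
    expect_lt(abs(mean(prof[[sg]]) - rate), 3 * sqrt(rate * (1 - rate) / 500))
  }
  # genome-wide profile mean matches total retained / reference total
  gm <- attr(lab, "gene_map")
  for (sg in c("LF", "MF1", "MF2")) {
    tgt_in <- gm$gene_tgt[lab$subgenome[gm$copy_id] == sg]
    calls <- shared_calls()
    retained_refs <- unique(calls$gene_ref[calls$gene_tgt %in% tgt_in])
    expect_lt(abs(mean(prof[[sg]]) -
                    length(retained_refs) / nrow(sim$reference$genes)), 0.02)
  }
  expect_error(retention_profile(lab, shared_calls(), sim$reference$genes,
                                 window = 1), class = "triadsynt_invalid")
})

test_that("constant-retention limits give flat profiles", {
  ref_genes <- data.frame(gene_id = sprintf("a%02d", 1:20), chrom = "R1")
  copies <- structure(data.frame(
    copy_id = 1L, block = "A", tgt_chrom = "T1", rank_min = 1, rank_max = 20,
    retained = 20, reference = 20, subgenome = "LF", stringsAsFactors = FALSE
  ), class = c("block_copies", "data.frame"),
  gene_map = data.frame(gene_tgt = sprintf("b%02d", 1:20), copy_id = 1L))
  calls <- data.frame(gene_ref = sprintf("a%02d", 1:20),
                      gene_tgt = sprintf("b%02d", 1:20))
  prof <- retention_profile(copies, calls, ref_genes, window = 10)
  expect_true(all(prof$LF == 1))
})

test_that("lineage-specific genes are exactly the unanchored complement", {
  sim <- shared_sim()
  ch <- shared_chains()
  ls <- find_lineage_specific_genes(sim$target$genes$gene_id, ch)
  expect_true(all(sim$truth$specific_genes %in% ls$genes))
  expect_equal(ls$count + length(unique(ch$anchors$gene_tgt)),
               nrow(sim$target$genes))

  # full coverage leaves nothing specific
  fake <- structure(list(
    chains = data.frame(chain_id = 1L),
    anchors = data.frame(chain_id = 1L, gene_ref = "a", gene_tgt = c("x", "y"),
                         ref_rank = 1:2, tgt_rank = 1:2),
    params = chain_params()
  ), class = "collinear_chains")
  expect_equal(find_lineage_specific_genes(c("x", "y"), fake)$count, 0)
})
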