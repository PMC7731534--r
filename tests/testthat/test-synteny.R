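test_that("identical CDS score maximally and unrelated CDS are excluded", {
  set.seed(21)
  cds <- setNames(vapply(1:6, function(i) triadsynt:::random_cds(100),
                         character(1)), paste0("g", 1:6))
  other <- setNames(vapply(1:6, function(i) triadsynt:::random_cds(100),
                           character(1)), paste0("h", 1:6))
  anch <- score_gene_pairs(cds, c(cds, other))
  self <- anch[anch$gene_a == anch$gene_b, ]
  expect_equal(nrow(self), 6)
  expect_true(all(self$similarity == 1))
  cross <- anch[substr(anch$gene_b, 1, 1) == "h", ]
  expect_equal(nrow(cross), 0)
})

test_that("diverged ortholog pairs are retained at the default threshold", {
  set.seed(22)
  cds <- setNames(vapply(1:100, function(i) triadsynt:::random_cds(300),
                         character(1)), sprintf("g%03d", 1:100))
  evolved <- setNames(vapply(cds, triadsynt:::mutate_synonymous, character(1),
                             ks = 0.1), names(cds))
  anch <- score_gene_pairs(cds, evolved)
  matched <- anch[anch$gene_a == anch$gene_b, ]
  expect_gte(nrow(matched) / 100, 0.99)
})

test_that("untranslatable CDS are skipped with a warning", {
  cds_a <- c(ok = triadsynt:::random_cds(50), bad = "ATGAA")
  cds_b <- c(ok = triadsynt:::random_cds(50))
  expect_warning(score_gene_pairs(cds_a, cds_b), "untranslatable")
})

test_that("least-Ks calling picks the minimum and respects tie rules", {
  # three partners for one target gene with Ks around 0.1 / 0.39 / 0.41
  set.seed(23)
  base <- triadsynt:::random_cds(300)
  tgt <- triadsynt:::mutate_synonymous(base, 0.05)
  refs <- c(r1 = triadsynt:::mutate_synonymous(base, 0.0001),
            r2 = triadsynt:::mutate_synonymous(base, 0.35),
            r3 = triadsynt:::mutate_synonymous(base, 0.45))
  chains <- structure(list(
    chains = data.frame(chain_id = 1L, ref_chrom = "A", tgt_chrom = "B",
                        orientation = "+", score = 150, n_anchors = 3),
    anchors = data.frame(chain_id = 1L, gene_ref = names(refs),
                         gene_tgt = "t1", ref_rank = 1:3, tgt_rank = c(1, 1, 1)),
    params = chain_params(match_size = 1)
  ), class = "collinear_chains")
  calls <- call_orthologs(chains, refs, c(t1 = tgt))
  expect_equal(calls$gene_ref[calls$least_ks], "r1")
  expect_equal(sum(calls$least_ks), 1)

  # exact tie: identical Ks for two refs -> lowest gene id wins, tie logged
  chains$anchors <- data.frame(chain_id = 1L, gene_ref = c("rB", "rA"),
                               gene_tgt = "t1", ref_rank = 1:2,
                               tgt_rank = c(1, 1))
  same <- c(rB = base, rA = base)
  calls2 <- call_orthologs(chains, same, c(t1 = base))
  expect_equal(calls2$gene_ref[calls2$least_ks], "rA")
  expect_equal(attr(calls2, "ties"), "t1")
})

test_that("saturated partners leave a gene uncalled and logged", {
  chains <- structure(list(
    chains = data.frame(chain_id = 1L, ref_chrom = "A", tgt_chrom = "B",
                        orientation = "+", score = 50, n_anchors = 1),
    anchors = data.frame(chain_id = 1L, gene_ref = "r1", gene_tgt = "t1",
                         ref_rank = 1, tgt_rank = 1),
    params = chain_params(match_size = 1)
  ), class = "collinear_chains")
  calls <- call_orthologs(chains, c(r1 = "GGT"), c(t1 = "GGC"))
  expect_equal(sum(calls$least_ks), 0)
  expect_equal(attr(calls, "uncalled"), "t1")
})

test_that("ortholog calls recover the planted pairing on the study scenario", {
  sim <- shared_sim()
  calls <- shared_calls()
  truth <- paste(sim$truth$orthologs$ref_gene, sim$truth$orthologs$tgt_gene)
  called <- paste(calls$gene_ref, calls$gene_tgt)[calls$mutual]
  expect_gte(mean(called %in% truth), 0.95) # precision
  expect_gte(mean(truth %in% called), 0.95) # recall
})

test_that("no inversions are reported when all chains are forward", {
  inst_anchors <- data.frame(gene_a = sprintf("a%02d", 1:8),
                             gene_b = sprintf("b%02d", 1:8))
  ga <- data.frame(gene_id = sprintf("a%02d", 1:8), chrom = "A", rank = 1:8)
  gb <- data.frame(gene_id = sprintf("b%02d", 1:8), chrom = "B", rank = 1:8)
  ch <- chain_anchors(inst_anchors, ga, gb)
  expect_equal(nrow(detect_inversions(ch)), 0)
})

test_that("a planted inversion flanked by forward synteny is called", {
  # forward run, inverted middle, forward run on one chromosome pair
  r <- 1:30
  t <- c(1:10, 20:11, 21:30)
  anch <- data.frame(gene_a = sprintf("a%02d", r), gene_b = sprintf("b%02d", t))
  ga <- data.frame(gene_id = sprintf("a%02d", 1:30), chrom = "A", rank = 1:30)
  gb <- data.frame(gene_id = sprintf("b%02d", 1:30), chrom = "B", rank = 1:30)
  ch <- chain_anchors(anch, ga, gb)
  inv <- detect_inversions(ch)
  expect_equal(nrow(inv), 1)
  expect_equal(inv$tgt_rank_min, 11)
  expect_equal(inv$tgt_rank_max, 20)
})

test_that("dot-plot export classifies pairs and is empty-safe", {
  empty <- structure(list(
    chains = data.frame(chain_id = integer(0), ref_chrom = character(0),
                        tgt_chrom = character(0), orientation = character(0),
                        score = numeric(0), n_anchors = integer(0)),
    anchors = data.frame(chain_id = integer(0), gene_ref = character(0),
                         gene_tgt = character(0), ref_rank = integer(0),
                         tgt_rank = integer(0)),
    params = chain_params()
  ), class = "collinear_chains")
  d0 <- export_dotplot(empty)
  expect_equal(nrow(d0), 0)
  expect_true(all(c("ref_chrom", "tgt_chrom", "class") %in% names(d0)))

  sim <- shared_sim()
  d <- export_dotplot(shared_chains(), shared_calls(),
                      sim$reference$genes, sim$target$genes)
  expect_true(all(d$class %in% c("ortholog", "other-syntenic")))
  expect_gt(sum(d$class == "ortholog"), 0)
  # centromeres are gene deserts: no dots inside the truth centromere spans
  cen <- sim$target$centromeres
  for (i in seq_len(nrow(cen))) {
    inside <- d$tgt_chrom == cen$chrom[i] & d$tgt_bp > cen$start0[i] &
      d$tgt_bp < cen$end0[i]
    expect_equal(sum(inside), 0)
  }
})
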