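mk_markers <- function(tags, lg = "LG1", cM = seq_along(tags)) {
  data.frame(marker_id = sprintf("m%02d", seq_along(tags)), lg = lg, cM = cM,
             tag_seq = tags, stringsAsFactors = FALSE)
}

test_that("marker tags are located on either strand or dropped when ambiguous", {
  set.seed(41)
  tag1 <- triadsynt:::random_dna(25)
  tag2 <- triadsynt:::random_dna(25)
  tag3 <- triadsynt:::random_dna(25)
  sc1 <- paste0(triadsynt:::random_dna(40), tag1, triadsynt:::random_dna(40),
                triadsynt:::revcomp(tag2), triadsynt:::random_dna(20), tag3)
  sc2 <- paste0(triadsynt:::random_dna(30), tag3, triadsynt:::random_dna(30))
  hits <- locate_markers(c(s1 = sc1, s2 = sc2), mk_markers(c(tag1, tag2, tag3)))
  expect_equal(hits$marker_id, c("m01", "m02"))
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$scaffold_id, c("s1", "s1"))
  expect_equal(hits$pos0[1], 40)
  expect_equal(attr(hits, "ambiguous"), "m03") # on two scaffolds

  none <- locate_markers(c(s1 = sc1), mk_markers(triadsynt:::random_dna(25)))
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "unmatched"), "m01")

  dup <- mk_markers(c(tag1, tag2))
  dup$marker_id <- c("x", "x")
  expect_error(locate_markers(c(s1 = sc1), dup), class = "triadsynt_invalid")
  short <- mk_markers("ACGTACGT")
  expect_error(locate_markers(c(s1 = sc1), short), class = "triadsynt_invalid")
})

test_that("every marker is exactly one of placed, ambiguous or unmatched", {
  sim <- shared_sim()
  hits <- locate_markers(sim$scaffolds, sim$markers)
  placed <- hits$marker_id
  amb <- attr(hits, "ambiguous")
  un <- attr(hits, "unmatched")
  expect_equal(sort(c(placed, amb, un)), sort(sim$markers$marker_id))
  expect_equal(length(intersect(placed, c(amb, un))), 0)
})

test_that("scaffolds are assigned to the majority linkage group", {
  hits <- data.frame(
    marker_id = sprintf("m%02d", 1:13),
    lg = c(rep("LG3", 10), "LG1", rep("LG2", 2)),
    cM = 1:13,
    scaffold_id = c(rep("s1", 10), "s2", "s3", "s3"),
    pos0 = 1:13, strand = "+", stringsAsFactors = FALSE
  )
  pl <- assign_scaffolds(hits, scaffold_ids = c("s1", "s2", "s3", "s4"))
  expect_equal(pl$lg[pl$scaffold_id == "s1"], "LG3")
  expect_false(pl$assigned[pl$scaffold_id == "s2"]) # one hit < min_markers
  expect_true(pl$assigned[pl$scaffold_id == "s3"])
  expect_false(pl$assigned[pl$scaffold_id == "s4"]) # zero hits
})

test_that("ordering and orientation follow median cM and cM~bp correlation", {
  hits <- data.frame(
    marker_id = sprintf("m%02d", 1:6),
    lg = "LG1", cM = c(1, 2, 3, 10, 11, 12),
    scaffold_id = c(rep("sA", 3), rep("sB", 3)),
    pos0 = c(100, 200, 300, 900, 500, 100), # sB runs against the map
    strand = "+", stringsAsFactors = FALSE
  )
  pl <- assign_scaffolds(hits)
  oo <- order_and_orient(pl, hits, c(sA = 1000, sB = 1000))
  expect_equal(oo$placements$order_index[oo$placements$scaffold_id == "sA"], 1)
  expect_equal(oo$placements$orientation[oo$placements$scaffold_id == "sA"], "+")
  expect_equal(oo$placements$orientation[oo$placements$scaffold_id == "sB"], "-")
  expect_equal(unname(oo$lg_correlation["LG1"]), 1)
  # AGP: 2 scaffolds + 1 gap
  expect_equal(nrow(oo$agp), 3)
  expect_equal(oo$agp$component_type, c("W", "U", "W"))
})

test_that("anchoring recovers the planted scaffold layout exactly", {
  sim <- shared_sim()
  hits <- locate_markers(sim$scaffolds, sim$markers)
  pl <- assign_scaffolds(hits, scaffold_ids = names(sim$scaffolds))
  expect_equal(sum(pl$assigned), 14) # one organelle scaffold stays out
  expect_false(pl$assigned[pl$scaffold_id == sim$truth$scaffolds$scaffold_id[
    is.na(sim$truth$scaffolds$lg)]])
  oo <- order_and_orient(pl, hits, setNames(nchar(sim$scaffolds),
                                            names(sim$scaffolds)))
  m <- merge(oo$placements, sim$truth$scaffolds, by = "scaffold_id")
  expect_equal(m$order_index, m$order)
  expect_equal(m$orientation.x, m$orientation.y)
  expect_true(all(oo$lg_correlation >= 0.99))
  expect_equal(sum(table(oo$placements$lg) == 1), 5)
})

test_that("AGP output round-trips through write and read", {
  sim <- shared_sim()
  hits <- locate_markers(sim$scaffolds, sim$markers)
  pl <- assign_scaffolds(hits, scaffold_ids = names(sim$scaffolds))
  oo <- order_and_orient(pl, hits, setNames(nchar(sim$scaffolds),
                                            names(sim$scaffolds)))
  path <- tempfile(fileext = ".agp")
  write_agp(oo$agp, path)
  back <- read_agp(path)
  expect_equal(back$object, oo$agp$object)
  expect_equal(back$component_id, oo$agp$component_id)
  expect_equal(back$orientation, oo$agp$orientation)
  expect_equal(back$object_beg, oo$agp$object_beg)
  expect_equal(back$object_end, oo$agp$object_end)
})

test_that("misassemblies are flagged for chimeras and non-monotone maps", {
  clean <- data.frame(marker_id = sprintf("m%d", 1:5), lg = "LG1",
                      cM = 1:5, scaffold_id = "s1", pos0 = (1:5) * 100,
                      strand = "+", stringsAsFactors = FALSE)
  expect_false(any(detect_misassembly(clean)$flagged))

  chimera <- clean
  chimera$lg[4:5] <- "LG2"
  flags <- detect_misassembly(chimera)
  expect_true(flags$flagged)
  expect_equal(flags$reason, "chimera")

  # planted chimera from two chromosome arms of the synthetic genome
  sim <- shared_sim()
  hits <- locate_markers(sim$scaffolds, sim$markers)
  two <- sim$truth$scaffolds$scaffold_id[!is.na(sim$truth$scaffolds$lg)][1:2]
  joined <- hits[hits$scaffold_id %in% two, ]
  joined$scaffold_id <- "chimera1"
  expect_true(detect_misassembly(joined)$flagged[1])

  zig <- data.frame(marker_id = sprintf("z%d", 1:7), lg = "LG1",
                    cM = c(1, 5, 2, 6, 3, 7, 4), # three reversals of the trend
                    scaffold_id = "s1", pos0 = (1:7) * 100,
                    strand = "+", stringsAsFactors = FALSE)
  expect_true(detect_misassembly(zig, tolerance = 2)$flagged)
  expect_false(detect_misassembly(zig, tolerance = 4)$flagged)
})
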