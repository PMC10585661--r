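test_that("chain graph sizes follow the linkage conventions", {
  expect_equal(chain_graph_size(fa_chain("FA 18:2"), "free_acid"), 39L)
  expect_equal(chain_graph_size(fa_chain("FA 18:0"), "free_acid"), 39L)
  expect_equal(chain_graph_size(fa_chain("FA 16:0"), "free_acid"), 35L)
  # esterified acyl with one hydroxyl: 2*16 + 2
  ch <- parse_lipid("PC 16:0;OH_18:1")$chains[[1]]
  expect_equal(chain_graph_size(ch, "esterified"), 34L)
  expect_equal(chain_graph_size(fa_chain("FA 16:0"), "esterified"), 32L)
  expect_equal(chain_graph_size(fa_chain("FA 16:0"), "ether"), 31L)
  expect_equal(chain_graph_size(fa_chain("FA 16:0"), "lcb"), 31L)
})

test_that("chain alignment reproduces the double-bond mismatch counts", {
  al <- align_chains(fa_chain("FA 18:2"), fa_chain("FA 18:1"))
  expect_equal(al$intersection, 36L)
  expect_equal(al$union, 39L)

  al <- align_chains(fa_chain("FA 18:2(9,12)"), fa_chain("FA 18:1(9)"))
  expect_equal(al$intersection, 38L)
  expect_equal(al$union, 39L)

  al <- align_chains(fa_chain("FA 18:1"), fa_chain("FA 18:1"))
  expect_equal(al$intersection, 39L)          # identity guard
  expect_equal(al$union, 39L)

  al <- align_chains(fa_chain("FA 16:0"), fa_chain("FA 18:0"))
  expect_equal(al$intersection, 35L)          # shorter skeleton embeds
  expect_equal(al$union, 39L)

  al <- align_chains(fa_chain("FA 18:2(9,12)"), fa_chain("FA 18:2(9,13)"))
  expect_equal(al$intersection, 37L)          # symmetric difference {12, 13}
})

test_that("headgroup MCS is symmetric, cached and matches subgraph structure", {
  pc <- headgroup_mcs("PC", "PC")
  expect_equal(pc$intersection, pc$union)
  pe_size <- lipidstruct:::graph_size(class_descriptor("PE")$graph)
  pcpe <- headgroup_mcs("PC", "PE")
  expect_equal(pcpe$intersection, pe_size)    # PE head embeds in PC's
  expect_equal(pcpe$union, pc$union + pe_size - pcpe$intersection)
  expect_identical(headgroup_mcs("PE", "PC"), pcpe)

  fa <- headgroup_mcs("FA", "FA")
  expect_equal(fa$intersection, 0L)           # whole molecule is the chain
  expect_equal(fa$union, 0L)
  expect_error(headgroup_mcs("PC", "nope"), "UnknownClass")
})

test_that("connected MCS equals brute-force enumeration on toy graphs", {
  path <- function(els) {
    n <- length(els)
    toy_graph(els, if (n > 1) cbind(seq_len(n - 1L), seq.int(2L, n), 1L))
  }
  ring6 <- toy_graph(rep("C", 6), rbind(cbind(1:5, 2:6, 1L), c(6L, 1L, 1L)))
  dbl <- toy_graph(c("C", "C", "O"), rbind(c(1L, 2L, 2L), c(2L, 3L, 1L)))
  sgl <- toy_graph(c("C", "C", "O"), rbind(c(1L, 2L, 1L), c(2L, 3L, 1L)))
  star <- toy_graph(c("C", "O", "O", "N"),
                    rbind(c(1L, 2L, 1L), c(1L, 3L, 2L), c(1L, 4L, 1L)))
  pairs <- list(
    list(path(rep("C", 5)), path(rep("C", 3))),
    list(ring6, path(rep("C", 6))),
    list(dbl, sgl),                 # order mismatch restricts the match
    list(star, path(c("O", "C", "O"))),
    list(star, dbl),
    list(path(c("C", "O", "C", "N")), path(c("N", "C", "O", "C"))),
    list(ring6, ring6)
  )
  for (p in pairs) {
    got <- lipidstruct:::mcs_connected(p[[1]], p[[2]])$size
    expect_equal(got, mcs_oracle(p[[1]], p[[2]]))
    expect_equal(got, lipidstruct:::mcs_connected(p[[2]], p[[1]])$size)
  }
})

test_that("worked fatty-acid comparisons give the published component counts", {
  s <- lipid_similarity("FA 18:2", "FA 18:1")
  expect_equal(s$components$intersection, 36L)
  expect_equal(s$components$union, 39L)
  expect_equal(s$distance, 1 - 36 / 39)

  s <- lipid_similarity("FA 18:2(9,12)", "FA 18:1(9)")
  expect_equal(s$components$intersection, 38L)
  expect_equal(s$components$union, 39L)
})

test_that("distance is a bounded symmetric measure with zero self-distance", {
  lip <- random_lipids(40, seed = 7)
  for (nm in lip) expect_equal(lipid_similarity(nm, nm)$distance, 0)
  set.seed(7)
  idx <- cbind(sample.int(40, 150, replace = TRUE),
               sample.int(40, 150, replace = TRUE))
  for (r in seq_len(nrow(idx))) {
    d1 <- lipid_similarity(lip[idx[r, 1]], lip[idx[r, 2]])$distance
    d2 <- lipid_similarity(lip[idx[r, 2]], lip[idx[r, 1]])$distance
    expect_identical(d1, d2)
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
})

test_that("information levels align downwards before comparison", {
  # species vs sn-resolved: both reduced to summed species chains
  d1 <- lipid_similarity("PC 34:1", "PC 18:1/16:0")$distance
  expect_equal(d1, 0)
  d2 <- lipid_similarity("FA 18:2(9,12)", "FA 18:2")$distance
  expect_equal(d2, 0)
})

test_that("distance grows with chain length difference", {
  base <- "PC 12:0/12:0"
  d <- vapply(c(12:24, 26), function(n) {
    lipid_similarity(base, sprintf("PC 12:0/%d:0", n))$distance
  }, numeric(1))
  expect_true(all(diff(d) > 0))
  # single chains, no positions, equal DB count
  d <- vapply(seq(12, 22, 2), function(n) {
    lipid_similarity("FA 12:0", sprintf("FA %d:0", n))$distance
  }, numeric(1))
  expect_true(all(diff(d) >= 0))
})

test_that("best-permutation pairing never undercuts sn-strict", {
  pairs <- list(c("PC 16:0/18:1", "PC 18:1/16:0"),
                c("PC 16:0/18:1", "PC 16:0/18:1"),
                c("TG 12:0/16:0/18:1", "TG 18:1/12:0/16:0"),
                c("Cer 18:1;O2/24:0", "Cer 18:1;O2/16:0"))
  for (p in pairs) {
    b <- lipid_similarity(p[1], p[2], mode = "best_permutation")
    s <- lipid_similarity(p[1], p[2], mode = "sn_strict")
    expect_gte(b$components$intersection, s$components$intersection)
  }
  # permuted sn chains are identical under best match, distinct under strict
  expect_equal(lipid_similarity("PC 16:0/18:1", "PC 18:1/16:0")$distance, 0)
  expect_gt(lipid_similarity("PC 16:0/18:1", "PC 18:1/16:0",
                             mode = "sn_strict")$distance, 0)
})

test_that("unpaired chains of unequal chain counts enlarge the union only", {
  s <- lipid_similarity("DG 16:0_18:1", "TG 16:0_18:1_18:2")
  # glycerol head identical (11) + matched chains 32 + 36; unpaired 18:2 = 36
  expect_equal(s$components$intersection, 11L + 32L + 36L)
  expect_equal(s$components$union, 11L + 32L + 36L + 36L)
})
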