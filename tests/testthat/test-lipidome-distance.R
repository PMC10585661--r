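test_that("Hausdorff distance handles the elementary cases", {
  A <- matrix(runif(20), 10, 2)
  expect_equal(hausdorff(A, A), 0)
  expect_equal(hausdorff(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 5)
  expect_error(hausdorff(matrix(1, 1, 2), matrix(1, 1, 3)),
               "DimensionMismatch")
})

test_that("early-break Hausdorff equals the naive double loop exactly", {
  set.seed(21)
  for (r in 1:40) {
    A <- matrix(rnorm(20 * 7), 20, 7)
    B <- matrix(rnorm(20 * 7), 20, 7)
    expect_identical(hausdorff(A, B), hausdorff_naive(A, B))
  }
})

test_that("Hausdorff behaves metrically on random point sets", {
  set.seed(5)
  sets <- replicate(12, matrix(rnorm(15 * 3), 15, 3), simplify = FALSE)
  for (r in 1:30) {
    ijk <- sample.int(12, 3)
    dab <- hausdorff(sets[[ijk[1]]], sets[[ijk[2]]])
    dba <- hausdorff(sets[[ijk[2]]], sets[[ijk[1]]])
    dbc <- hausdorff(sets[[ijk[2]]], sets[[ijk[3]]])
    dac <- hausdorff(sets[[ijk[1]]], sets[[ijk[3]]])
    expect_identical(dab, dba)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("lipidome distance matrices are symmetric with meaningful zeros", {
  tab <- generate_lipidomes(simulation_config(seed = 8, n_samples = 6,
                                              n_groups = 2))
  # duplicate one sample
  ab <- rbind(tab$abundances, dup = tab$abundances[1, ])
  sv <- rbind(tab$study_variables, dup = tab$study_variables[1, , drop = FALSE])
  rownames(ab)[7] <- rownames(sv)[7] <- "dup"
  tab2 <- lipidome_table(ab, sv)
  D <- lipidome_distance_matrix(tab2)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 7))
  expect_equal(D["S01", "dup"], 0)
  expect_true(all(D[upper.tri(D)][D[upper.tri(D)] != 0] > 0))
})

test_that("disjoint lipidomes still have a finite distance", {
  ab <- matrix(NA_real_, 2, 4,
               dimnames = list(c("a", "b"),
                               c("PC 34:1", "PC 36:2", "TG 52:2", "TG 54:3")))
  ab[1, 1:2] <- c(1e3, 1e4)   # sample a: only PCs
  ab[2, 3:4] <- c(1e5, 1e6)   # sample b: only TGs
  tab <- lipidome_table(ab)
  D <- lipidome_distance_matrix(tab)
  expect_true(is.finite(D["a", "b"]))
  expect_gt(D["a", "b"], 0)
})

test_that("forced topologies and linkage rules are respected", {
  D <- matrix(c(0, 1, 5,
                1, 0, 5,
                5, 5, 0), 3, 3, dimnames = list(c("x", "y", "z"),
                                                c("x", "y", "z")))
  for (lk in c("average", "complete", "single")) {
    tr <- cluster_lipidomes(D, linkage = lk)
    expect_equal(sort(dendrogram_leaves(if (isTRUE(tr$left$leaf)) tr$right
                                        else tr$left)), c("x", "y"))
    first <- if (isTRUE(tr$left$leaf)) tr$right else tr$left
    expect_equal(first$height, 1)
    expect_equal(tr$height, if (lk == "single") 5 else 5)
  }
  # identical lipidomes collapse at height zero
  D0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tr <- cluster_lipidomes(D0)
  expect_equal(tr$height, 0)
  expect_setequal(dendrogram_leaves(tr), letters[1:4])
})

test_that("single linkage merge heights equal the MST edge weights", {
  set.seed(33)
  for (r in 1:10) {
    P <- matrix(rnorm(8 * 3), 8, 3)
    D <- as.matrix(dist(P))
    dimnames(D) <- list(paste0("s", 1:8), paste0("s", 1:8))
    tr <- cluster_lipidomes(D, linkage = "single")
    heights <- c()
    walk <- function(n) {
      if (!isTRUE(n$leaf)) {
        heights <<- c(heights, n$height)
        walk(n$left); walk(n$right)
      }
    }
    walk(tr)
    expect_equal(sort(heights), mst_edge_weights(D), tolerance = 1e-12)
  }
})

test_that("average linkage is the unweighted mean over cross pairs", {
  # clusters {a,b} and {c,d,e}: UPGMA distance must be the mean of all 6
  # cross distances regardless of merge history
  set.seed(4)
  P <- c(a = 0, b = 0.1, c = 10, d = 10.2, e = 10.4)
  D <- abs(outer(P, P, "-"))
  tr <- cluster_lipidomes(D, linkage = "average")
  cross <- mean(abs(outer(P[1:2], P[3:5], "-")))
  expect_equal(tr$height, cross, tolerance = 1e-12)
})

test_that("dendrograms round-trip through Newick", {
  tab <- generate_lipidomes(simulation_config(seed = 14, n_samples = 8,
                                              n_groups = 2))
  D <- lipidome_distance_matrix(tab)
  tr <- cluster_lipidomes(D)
  back <- newick_to_dendrogram(to_newick(tr))
  expect_equal(tree_signature(back), tree_signature(tr))
  collect_heights <- function(n) {
    if (isTRUE(n$leaf)) return(numeric(0))
    c(n$height, collect_heights(n$left), collect_heights(n$right))
  }
  expect_equal(sort(collect_heights(back)), sort(collect_heights(tr)),
               tolerance = 1e-9)
})

test_that("subtree reanalysis restricts the universe and recomputes", {
  tab <- generate_lipidomes(planted_cluster_config(31))
  an <- lipidome_analysis(tab)
  # reanalysing the full tree reproduces the topology
  again <- subtree_reanalysis(an$dendrogram, tab)
  expect_equal(tree_signature(again$dendrogram),
               tree_signature(an$dendrogram))
  # a pure-group subtree analysis covers exactly its samples, and its lipid
  # universe shrinks to the union of their lipidomes
  g <- tab$study_variables$group
  names(g) <- sample_ids(tab)
  side <- if (length(unique(g[dendrogram_leaves(an$dendrogram$left)])) == 1L) {
    an$dendrogram$left
  } else {
    an$dendrogram$right
  }
  sub <- subtree_reanalysis(side, tab)
  expect_setequal(rownames(sub$distance_matrix), dendrogram_leaves(side))
  expect_true(length(sub$space$lipid_ids) < length(an$space$lipid_ids))
  leaf <- an$dendrogram
  while (!isTRUE(leaf$leaf)) leaf <- leaf$left
  expect_error(subtree_reanalysis(leaf, tab), "TooFewSamples")
})

test_that("well-separated blocks split at the root", {
  set.seed(77)
  for (r in 1:10) {
    m1 <- matrix(rnorm(5 * 3, 0), 5, 3)
    m2 <- matrix(rnorm(4 * 3, 20), 4, 3)
    P <- rbind(m1, m2)
    D <- as.matrix(dist(P))
    ids <- c(paste0("a", 1:5), paste0("b", 1:4))
    dimnames(D) <- list(ids, ids)
    tr <- cluster_lipidomes(D)
    expect_setequal(dendrogram_leaves(tr$left),
                    if (startsWith(dendrogram_leaves(tr$left)[1], "a")) {
                      paste0("a", 1:5)
                    } else {
                      paste0("b", 1:4)
                    })
  }
})
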