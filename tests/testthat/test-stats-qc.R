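test_that("Benford expectations, conformance and scale invariance", {
  set.seed(3)
  rep1 <- benford_check(10^runif(10000, 0, 6))
  expect_equal(rep1$expected[1], log10(2))
  expect_equal(sum(rep1$expected), 1, tolerance = 1e-9)
  expect_equal(sum(rep1$digit_freqs), 1, tolerance = 1e-9)
  expect_true(rep1$conforms)                     # log-uniform obeys the law

  bad <- benford_check(runif(10000, 1, 2))
  expect_false(bad$conforms)                     # all leading digits are 1
  expect_equal(bad$digit_freqs[1], 1)

  v <- 10^runif(500, 0, 4)
  expect_identical(benford_check(v)$digit_freqs,
                   benford_check(v * 1e3)$digit_freqs)   # exact for 10^k
  expect_identical(benford_check(v)$digit_freqs,
                   benford_check(v / 1e6)$digit_freqs)
  tripled <- benford_check(v * 3)$digit_freqs
  expect_lt(max(abs(tripled - benford_check(v)$digit_freqs)), 0.15)

  expect_true(is.na(benford_check(10^runif(20, 0, 4))$conforms))
})

test_that("group tests dispatch on group count and detect separation", {
  x <- c(1.2, 3.4, 2.2, 4.1)
  same <- group_test(c(x, x), rep(c("a", "b"), each = 4))
  expect_equal(same$test, "welch_t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(11)
  far <- group_test(c(rnorm(20), rnorm(20, 5)), rep(c("a", "b"), each = 20))
  expect_lt(far$p_value, 1e-10)

  three <- group_test(rnorm(15), rep(c("a", "b", "c"), each = 5))
  expect_equal(three$test, "anova")
  expect_true(three$p_value >= 0 && three$p_value <= 1)

  expect_error(group_test(rnorm(3), c("a", "a", "b")),
               "InsufficientGroupSize")
})

test_that("AUC equals the Mann-Whitney identity, ties included", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       rep(c("a", "b"), each = 3))$auc, 1)
  set.seed(13)
  for (r in 1:50) {
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    scores <- sample.int(8, n1 + n0, replace = TRUE)  # forced ties
    labels <- c(rep("neg", n0), rep("pos", n1))
    auc <- roc_auc(scores, labels)$auc
    U <- unname(suppressWarnings(
      stats::wilcox.test(scores[labels == "pos"],
                         scores[labels == "neg"])$statistic))
    expect_equal(auc, U / (n1 * n0), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep("a", 4)), "SingleClass")
})

test_that("random scores give chance-level AUC", {
  set.seed(29)
  auc <- roc_auc(rnorm(1000), rep(c("a", "b"), 500))$auc
  expect_gt(auc, 0.45); expect_lt(auc, 0.55)
})

test_that("CV distributions compute sd/mean per lipid and group", {
  ab <- cbind("PC 34:1" = c(1, 2, 3, 1, 2, 3),
              "PC 36:2" = rep(5, 6))
  rownames(ab) <- paste0("s", 1:6)
  tab <- lipidome_table(ab, data.frame(group = rep(c("x", "y"), each = 3),
                                       row.names = paste0("s", 1:6)))
  cv <- cv_distribution(tab, "group")
  expect_equal(cv$cv[cv$lipid == "PC 34:1"], rep(1 / 2, 2))
  expect_equal(cv$cv[cv$lipid == "PC 36:2"], rep(0, 2))

  set.seed(31)
  med <- median(vapply(1:300, function(i) {
    x <- stats::rlnorm(50, sdlog = 0.25)
    stats::sd(x) / mean(x)
  }, numeric(1)))
  expect_gt(med, 0.2); expect_lt(med, 0.31)      # sqrt(exp(s^2) - 1) ~ 0.254
})

test_that("p-value histograms flag planted regulation", {
  # 10% of lipids with a strong planted effect spike the left bin
  cfg <- simulation_config(seed = 43, n_samples = 20, n_groups = 2,
                           classes = c(PC = 18L, PE = 18L, TG = 14L),
                           planted_effects = list(
                             list(class = "TG", group = "G2",
                                  fold_change = 16)))
  ph <- pvalue_histogram(generate_lipidomes(cfg), "group")
  expect_true(all(ph$p_values >= 0 & ph$p_values <= 1))
  bins <- table(cut(ph$p_values, seq(0, 1, 0.1)))
  expect_gt(bins[1], 2 * mean(bins))
  expect_lt(ph$uniformity_p, 0.01)

  one <- lipidome_table(
    matrix(10^runif(8, 2, 4), 8, 1,
           dimnames = list(paste0("s", 1:8), "PC 34:1")),
    data.frame(group = rep(c("a", "b"), 4), row.names = paste0("s", 1:8)))
  ph1 <- pvalue_histogram(one, "group")
  expect_length(ph1$p_values, 1L)
  expect_true(is.na(ph1$uniformity_p))
})

test_that("volcano calls planted fold changes and respects both thresholds", {
  # identical groups: nothing significant
  ab <- matrix(10^runif(60, 2, 5), 6, 10)
  ab <- rbind(ab[1:3, ], ab[1:3, ])
  dimnames(ab) <- list(paste0("s", 1:6),
                       vapply(random_lipids(10, seed = 3), identity,
                              character(1)))
  tab0 <- lipidome_table(ab, data.frame(group = rep(c("a", "b"), each = 3),
                                        row.names = paste0("s", 1:6)))
  expect_false(any(volcano(tab0, "group")$significant))

  cfg <- simulation_config(seed = 47, n_samples = 40, n_groups = 2,
                           sigma = 0.2,
                           classes = c(PC = 10L, TG = 10L, SM = 5L))
  target <- lipid_ids(generate_lipidomes(cfg))[1]
  cfg <- simulation_config(seed = 47, n_samples = 40, n_groups = 2,
                           sigma = 0.2,
                           classes = c(PC = 10L, TG = 10L, SM = 5L),
                           planted_effects = list(
                             list(lipid = target, group = "G2",
                                  fold_change = 4)))
  v <- volcano(generate_lipidomes(cfg), "group")
  row <- v[v$lipid == target, ]
  expect_true(row$significant)
  expect_equal(row$log2_fold_change, 2, tolerance = 0.3 / 2)
  expect_true(all(v$adjusted_p >= v$p_value - 1e-15))

  # BH keeps the p-value order
  ord <- order(v$p_value)
  expect_true(all(diff(v$adjusted_p[ord]) >= -1e-15))
})

test_that("null group tests are calibrated (quick check)", {
  set.seed(53)
  p <- vapply(1:300, function(i) {
    group_test(rnorm(20), rep(c("a", "b"), each = 10))$p_value
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.10)
  expect_gt(mean(p), 0.4); expect_lt(mean(p), 0.6)
})
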