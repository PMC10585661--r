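classes25 <- c(PC = 5L, PE = 4L, TG = 4L, SM = 3L, Cer = 3L, LPC = 3L,
               FA = 3L)

test_that("KS best separation matches direct CDF evaluation", {
  r <- ks_best_separation(c(1, 2), c(3, 4))
  expect_equal(r$ks_stat, 1)
  expect_equal(r$best_value, 2)
  expect_equal(ks_best_separation(c(1, 5, 9), c(1, 5, 9))$ks_stat, 0)

  L <- c(1, 3, 5); R <- c(2, 3, 6)
  r <- ks_best_separation(L, R)
  vals <- sort(unique(c(L, R)))
  diffs <- vapply(vals, function(v) abs(mean(L <= v) - mean(R <= v)),
                  numeric(1))
  expect_equal(r$ks_stat, max(diffs))
  expect_equal(r$best_value, vals[which.max(diffs)])
  expect_error(ks_best_separation(numeric(0), 1), "EmptyBranch")
})

test_that("KS statistic equals the textbook two-sample statistic", {
  set.seed(17)
  for (r in 1:200) {
    L <- rnorm(sample(3:20, 1))
    R <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    ours <- ks_best_separation(L, R)$ks_stat
    ref <- suppressWarnings(stats::ks.test(L, R)$statistic)
    expect_equal(ours, unname(ref), tolerance = 1e-12)
  }
})

test_that("dendrogram annotation reports splits per variable kind", {
  # two clearly separated lipidome groups, numeric variable sorted with them
  cfg <- simulation_config(seed = 19, n_samples = 10, n_groups = 2,
                           planted_effects = list(
                             list(class = "PC", group = "G1",
                                  exclusive = TRUE),
                             list(class = "TG", group = "G2",
                                  exclusive = TRUE)))
  tab <- generate_lipidomes(cfg)
  tab$study_variables$age <-
    ifelse(tab$study_variables$group == "G1", 30, 60) + seq_len(10) / 10
  tab$study_variables$constant <- rep(1, 10)
  an <- lipidome_analysis(tab)
  root <- an$dendrogram
  expect_equal(root$ks_annotations$age$ks_stat, 1)
  # best separation value sits at the boundary between the planted groups
  expect_lte(root$ks_annotations$age$best_value, 60)
  expect_equal(root$ks_annotations$constant$ks_stat, 0)
  # categorical variable: per-branch frequency tables
  expect_named(root$ks_annotations$group, c("left", "right"))
  expect_equal(sum(root$ks_annotations$group$left) +
                 sum(root$ks_annotations$group$right), 10)
})

test_that("linear-model AIC matches its closed form", {
  set.seed(23)
  y <- c(2.3, 4.1, 5.0, 7.2, 8.9)
  # intercept-only model, by hand
  rss0 <- sum((y - mean(y))^2)
  expect_equal(aic_linear(matrix(numeric(0), 5, 0), y),
               5 * log(rss0 / 5) + 2 * 2)
  # adding one column changes AIC by 2 - N*log(RSS ratio)
  x <- rnorm(5)
  f <- stats::lm.fit(cbind(1, x), y)
  rss1 <- sum(f$residuals^2)
  expect_equal(aic_linear(cbind(x), y) - aic_linear(matrix(numeric(0), 5, 0), y),
               5 * log(rss1 / rss0) + 2)
  # perfect fit stays finite through the RSS floor
  expect_true(is.finite(aic_linear(cbind(1:6), 2 * (1:6))))
  expect_error(aic_linear(cbind(1:6, 1:6), rnorm(6)), "SingularDesign")
  expect_error(aic_linear(matrix(rnorm(12), 3, 4), rnorm(3)))
})

test_that("SFS evaluates the capped quadratic model count", {
  tab <- generate_lipidomes(simulation_config(seed = 29, n_samples = 12,
                                              n_groups = 2,
                                              classes = classes25))
  expect_equal(ncol(tab$abundances), 25L)
  res <- sfs_select(tab, "group")
  expect_equal(length(res$aic_trace), 5L)          # ceiling(sqrt(25))
  expect_equal(res$models_evaluated, sum(25 - seq_len(5) + 1))  # 115
  expect_equal(res$best_step, which.min(res$aic_trace))
  expect_equal(res$best_lipids,
               res$selected_lipids[seq_len(res$best_step)])
  expect_lte(length(res$selected_lipids), ceiling(sqrt(25)))
})

test_that("a planted fold-change lipid is the round-1 selection", {
  hits <- vapply(1:10, function(s) {
    base <- simulation_config(seed = 4000 + s, n_samples = 20, n_groups = 2,
                              classes = classes25)
    target <- lipid_ids(generate_lipidomes(base))[1]
    cfg <- simulation_config(seed = 4000 + s, n_samples = 20, n_groups = 2,
                             classes = classes25,
                             planted_effects = list(
                               list(lipid = target, group = "G2",
                                    fold_change = 4)))
    sfs_select(generate_lipidomes(cfg), "group")$selected_lipids[1] == target
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate SFS inputs behave as specified", {
  ab <- matrix(10^runif(8, 2, 5), 8, 1,
               dimnames = list(paste0("s", 1:8), "PC 34:1"))
  tab <- lipidome_table(ab, data.frame(group = rep(c("a", "b"), 4),
                                       row.names = paste0("s", 1:8)))
  res <- sfs_select(tab, "group")
  expect_equal(length(res$aic_trace), 1L)
  expect_equal(res$selected_lipids, "PC 34:1")
  # missing variable values are dropped, never imputed
  tab$study_variables$group[1:6] <- NA
  expect_error(sfs_select(tab, "group"), "non-missing")
})

test_that("multi-category variables use the best one-vs-rest encoding", {
  cfg <- simulation_config(seed = 37, n_samples = 18, n_groups = 3,
                           classes = classes25,
                           planted_effects = list(
                             list(lipid = NULL, class = "SM", group = "G3",
                                  fold_change = 6)))
  res <- sfs_select(generate_lipidomes(cfg), "group")
  expect_match(res$encoding, "^group=")
  expect_equal(res$models_evaluated, 3L * 115L)    # one run per category
})

test_that("selection is invariant to lipid column order", {
  tab <- generate_lipidomes(simulation_config(seed = 41, n_samples = 16,
                                              n_groups = 2,
                                              classes = classes25))
  res1 <- sfs_select(tab, "group")
  perm <- rev(seq_len(ncol(tab$abundances)))
  tab2 <- lipidome_table(tab$abundances[, perm], tab$study_variables)
  res2 <- sfs_select(tab2, "group")
  expect_setequal(res1$selected_lipids, res2$selected_lipids)
  expect_equal(res1$aic_trace, res2$aic_trace, tolerance = 1e-9)
})
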