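#' @title Group statistics and quality control
#' @description Per-lipid group tests (Welch t-test / one-way ANOVA),
#'   ROC/AUC, coefficient-of-variation distributions, p-value histograms
#'   with a uniformity diagnostic, volcano analysis with
#'   Benjamini-Hochberg adjustment, and a Benford's-law conformance check
#'   for abundance tables.
#' @name stats_qc
NULL

#' Benford's-law conformance of positive values
#'
#' Extracts the leading decimal digit of every strictly positive finite
#' value scale-invariantly and tests the digit frequencies against
#' `log10(1 + 1/d)` with a chi-square goodness-of-fit test (8 degrees of
#' freedom). Data spanning several orders of magnitude (as lipid abundances
#' should) conform; a narrow value range or poor imputation shows up as
#' non-conformance.
#'
#' @param values numeric vector; non-finite and non-positive entries are
#'   dropped.
#' @param alpha conformance threshold on the chi-square p-value
#'   (default 0.01).
#' @return list of class `benford_report`: `digit_freqs` (9 observed
#'   proportions), `expected`, `chi2`, `p_value`, `conforms` (`NA` when
#'   fewer than 50 usable values), `n`.
#' @examples
#' benford_check(10^runif(1000, 0, 5))$conforms
#' @export
benford_check <- function(values, alpha = 0.01) {
  v <- values[is.finite(values) & values > 0]
  expected <- log10(1 + 1 / (1:9))
  if (length(v) == 0L) {
    return(structure(list(digit_freqs = rep(NA_real_, 9), expected = expected,
                          chi2 = NA_real_, p_value = NA_real_, conforms = NA,
                          n = 0L), class = "benford_report"))
  }
  d <- v * 10^(-floor(log10(v)))
  d[d < 1] <- d[d < 1] * 10          # guard against floating-point log10
  d[d >= 10] <- d[d >= 10] / 10
  digit <- pmin(pmax(floor(d), 1L), 9L)
  counts <- tabulate(digit, nbins = 9L)
  freqs <- counts / sum(counts)
  chi2 <- sum((counts - sum(counts) * expected)^2 / (sum(counts) * expected))
  p <- stats::pchisq(chi2, df = 8L, lower.tail = FALSE)
  conforms <- if (length(v) < 50L) NA else p >= alpha
  structure(list(digit_freqs = freqs, expected = expected, chi2 = chi2,
                 p_value = p, conforms = conforms, n = length(v)),
            class = "benford_report")
}

#' @export
print.benford_report <- function(x, ...) {
  cat(sprintf("<benford_report> n = %d, chi2 = %.2f, p = %.4g, conforms: %s\n",
              x$n, x$chi2, x$p_value, x$conforms))
  invisible(x)
}

#' Group comparison test for one lipid
#'
#' Two groups: Welch's unequal-variance t-test. More than two groups:
#' one-way ANOVA.
#'
#' @param abundances numeric vector.
#' @param labels group labels aligned with `abundances`.
#' @return list with `statistic`, `p_value` and `test` (`"welch_t"` or
#'   `"anova"`).
#' @export
group_test <- function(abundances, labels) {
  keep <- !is.na(abundances) & !is.na(labels)
  abundances <- abundances[keep]
  labels <- factor(as.character(labels[keep]))
  sizes <- table(labels)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("InsufficientGroupSize: need >= 2 groups with >= 2 samples each",
         call. = FALSE)
  }
  if (length(sizes) == 2L) {
    gl <- levels(labels)
    ht <- stats::t.test(abundances[labels == gl[1L]],
                        abundances[labels == gl[2L]], var.equal = FALSE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "welch_t")
  } else {
    ht <- stats::oneway.test(abundances ~ labels, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "anova")
  }
}

#' ROC curve and AUC for a binary study variable
#'
#' The AUC is computed by the trapezoid rule over all score thresholds and
#' equals the Mann-Whitney U statistic divided by n1 * n2 (ties counted
#' half).
#'
#' @param scores numeric scores (e.g. abundances of a selected lipid).
#' @param labels binary labels; the lexicographically larger level (or
#'   `TRUE`) is the positive class.
#' @return list with `curve` (data.frame `fpr`, `tpr`, one row per
#'   threshold) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.character(labels[keep])
  lev <- sort(unique(labels))
  if (length(lev) != 2L) {
    stop("SingleClass: need exactly two label values", call. = FALSE)
  }
  pos <- labels == lev[2L]
  n1 <- sum(pos); n0 <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  cut <- c(which(diff(s) != 0), length(s))   # one point per distinct score
  tpr <- c(0, cumsum(p)[cut] / n1)
  fpr <- c(0, cumsum(!p)[cut] / n0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Coefficients of variation per lipid and group
#'
#' @param table a `lipidome_table`.
#' @param grouping study variable name used to group samples, or `NULL` for
#'   a single group.
#' @return data.frame with `lipid`, `group`, `n`, `cv` (sd/mean on raw
#'   abundances; `NA` with `zero_mean = TRUE` when the group mean is 0).
#' @export
cv_distribution <- function(table, grouping = NULL) {
  ab <- table$abundances
  groups <- if (is.null(grouping)) {
    rep("all", nrow(ab))
  } else {
    as.character(table$study_variables[[grouping]])
  }
  out <- list()
  for (g in sort(unique(groups[!is.na(groups)]))) {
    sub <- ab[groups == g & !is.na(groups), , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      x <- sub[, j][!is.na(sub[, j])]
      if (length(x) < 2L) next
      m <- mean(x)
      out[[length(out) + 1L]] <- data.frame(
        lipid = colnames(sub)[j], group = g, n = length(x),
        cv = if (m == 0) NA_real_ else stats::sd(x) / m,
        zero_mean = m == 0)
    }
  }
  do.call(rbind, out)
}

#' Per-lipid p-values with a uniformity diagnostic
#'
#' Runs [group_test()] per lipid against a study variable and reports a
#' Kolmogorov test of the p-values against U(0,1). A flat histogram points
#' to no regulation between the groups (or a failed perturbation); an
#' excess of small p-values indicates real group differences. Tests are run
#' on log10-transformed abundances.
#'
#' @param table a `lipidome_table`.
#' @param variable study variable name.
#' @return list with `p_values` (named per lipid), `uniformity_p` (`NA`
#'   with a single lipid) and `diagnostic` text.
#' @export
pvalue_histogram <- function(table, variable) {
  labels <- table$study_variables[[variable]]
  X <- .log_abundance_matrix(table$abundances)
  p <- vapply(seq_len(ncol(X)), function(j) {
    group_test(X[, j], labels)$p_value
  }, numeric(1))
  names(p) <- colnames(X)
  if (length(p) < 2L) {
    return(list(p_values = p, uniformity_p = NA_real_,
                diagnostic = "single lipid: no distribution diagnostic"))
  }
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  diag <- if (ks$p.value >= 0.01) {
    "p-values compatible with uniformity: no evidence of group regulation"
  } else {
    "p-value distribution deviates from uniformity"
  }
  list(p_values = p, uniformity_p = ks$p.value, diagnostic = diag)
}

#' Volcano analysis for a two-category study variable
#'
#' log2 fold changes are computed on raw group mean abundances; p-values
#' come from Welch tests on log10-transformed abundances and are adjusted
#' with Benjamini-Hochberg. A lipid is significant when both |log2 FC| >=
#' log2(`fc_threshold`) and adjusted p <= `alpha`.
#'
#' @param table a `lipidome_table`.
#' @param variable name of a study variable with exactly two categories;
#'   fold change is second level over first (levels sorted).
#' @param fc_threshold fold-change threshold (default 2).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data.frame of class `volcano_result`: `lipid`,
#'   `log2_fold_change`, `p_value`, `adjusted_p`, `significant`.
#' @export
volcano <- function(table, variable, fc_threshold = 2, alpha = 0.05) {
  labels <- as.character(table$study_variables[[variable]])
  lev <- sort(unique(labels[!is.na(labels)]))
  if (length(lev) != 2L) {
    stop("volcano requires a study variable with exactly two categories",
         call. = FALSE)
  }
  ab <- table$abundances
  X <- .log_abundance_matrix(ab)
  res <- lapply(seq_len(ncol(ab)), function(j) {
    m1 <- mean(ab[labels == lev[1L], j], na.rm = TRUE)
    m2 <- mean(ab[labels == lev[2L], j], na.rm = TRUE)
    data.frame(lipid = colnames(ab)[j],
               log2_fold_change = log2(m2 / m1),
               p_value = group_test(X[, j], labels)$p_value)
  })
  res <- do.call(rbind, res)
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- abs(res$log2_fold_change) >= log2(fc_threshold) &
    res$adjusted_p <= alpha
  class(res) <- c("volcano_result", "data.frame")
  res
}
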