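#' @title Figures
#' @description ggplot2 figures for the main results: the structural space
#'   scatter, the lipidome dendrogram, volcano, p-value histogram, CV
#'   distribution and ROC curve. All functions return ggplot objects (or a
#'   phylo object for the dendrogram) so the caller controls the device;
#'   the numbers behind every figure are available from the corresponding
#'   computation functions.
#' @name figures
NULL

#' Scatter plot of a lipid space
#'
#' @param space a `lipid_space`.
#' @param pcx,pcy principal components on the x and y axes (defaults 1, 2).
#' @return a ggplot object.
#' @export
plot_space <- function(space, pcx = 1L, pcy = 2L) {
  co <- space$coordinates
  stopifnot(max(pcx, pcy) <= ncol(co))
  df <- data.frame(x = co[, pcx], y = co[, pcy], lipid = space$lipid_ids,
                   class = vapply(space$lipid_ids, function(nm) {
                     parse_lipid(nm)$class_name
                   }, character(1)))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                   colour = class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste0("PC", pcx), y = paste0("PC", pcy),
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Dendrogram as an ape phylo object
#'
#' Converts the merge tree to \pkg{ape}'s `phylo` via its Newick
#' serialization, for plotting with `plot()` from \pkg{ape}.
#'
#' @param node root `dendrogram_node`.
#' @export
as_phylo_dendrogram <- function(node) ape::read.tree(text = to_newick(node))

#' Volcano plot
#'
#' @param result a [volcano()] result.
#' @param fc_threshold,alpha thresholds drawn as guide lines (match the
#'   values used in [volcano()]).
#' @return a ggplot object.
#' @export
plot_volcano <- function(result, fc_threshold = 2, alpha = 0.05) {
  ggplot2::ggplot(result,
                  ggplot2::aes(x = log2_fold_change,
                               y = -log10(adjusted_p),
                               colour = significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_threshold),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' p-value histogram
#'
#' @param ph a [pvalue_histogram()] result.
#' @param bins histogram bins (default 20).
#' @return a ggplot object.
#' @export
plot_pvalue_histogram <- function(ph, bins = 20L) {
  df <- data.frame(p = ph$p_values)
  ggplot2::ggplot(df, ggplot2::aes(x = p)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, length.out = bins + 1L),
                            fill = "grey40") +
    ggplot2::labs(x = "p-value", y = "lipids", subtitle = ph$diagnostic) +
    ggplot2::theme_minimal()
}

#' CV distribution plot
#'
#' @param cv a [cv_distribution()] result.
#' @return a ggplot object.
#' @export
plot_cv_distribution <- function(cv) {
  ggplot2::ggplot(cv, ggplot2::aes(x = group, y = cv)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "group", y = "coefficient of variation") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param roc a [roc_auc()] result.
#' @return a ggplot object.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc$curve, ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", roc$auc)) +
    ggplot2::theme_minimal()
}
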