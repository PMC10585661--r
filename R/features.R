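#' @title Feature analysis: KS branch separation and sequential forward
#'   selection
#' @description Internal dendrogram branches are annotated with the
#'   two-sample Kolmogorov-Smirnov statistic of each numerical study
#'   variable (the "best separation value" is the data value where the two
#'   branch CDFs differ most); categorical variables get per-branch category
#'   frequency tables. Lipid subsets describing a study variable are found
#'   by greedy sequential forward selection over multiple linear regression
#'   models scored with AIC, capped at ceiling(sqrt(n)) rounds.
#' @name feature_selection
NULL

#' Two-sample KS statistic and best separation value
#'
#' @param values_left,values_right non-empty numeric vectors (the study
#'   variable values of the two branches).
#' @return list with `ks_stat` (max |CDF_left - CDF_right| over the
#'   observed values) and `best_value` (the smallest value attaining it).
#' @examples
#' ks_best_separation(c(1, 2), c(3, 4))  # ks_stat 1, best_value 2
#' @export
ks_best_separation <- function(values_left, values_right) {
  values_left <- values_left[!is.na(values_left)]
  values_right <- values_right[!is.na(values_right)]
  if (length(values_left) == 0L || length(values_right) == 0L) {
    stop("EmptyBranch: both branches need at least one value", call. = FALSE)
  }
  vals <- sort(unique(c(values_left, values_right)))
  diffs <- vapply(vals, function(v) {
    abs(mean(values_left <= v) - mean(values_right <= v))
  }, numeric(1))
  i <- which.max(diffs)        # first maximum = smallest attaining value
  list(ks_stat = diffs[i], best_value = vals[i])
}

#' Annotate dendrogram branches with study-variable separation
#'
#' Each internal node is annotated per study variable: numerical variables
#' with the KS best-separation split between the left and right leaf
#' values; categorical variables with per-branch category frequency tables.
#' Samples with a missing value are excluded per node; nodes where either
#' branch has no remaining value carry no annotation for that variable.
#'
#' @param tree root `dendrogram_node`.
#' @param table the `lipidome_table` the tree was built from (its
#'   `study_variables` are used).
#' @param variables names of the variables to annotate (default: all).
#' @return the tree with `ks_annotations` filled on internal nodes: a named
#'   list mapping variable to either `list(ks_stat, best_value)` or
#'   `list(left = <freq table>, right = <freq table>)`.
#' @export
annotate_dendrogram <- function(tree, table, variables = NULL) {
  sv <- table$study_variables
  if (is.null(variables)) variables <- colnames(sv)
  rec <- function(node) {
    if (isTRUE(node$leaf)) return(node)
    node$left <- rec(node$left)
    node$right <- rec(node$right)
    lv <- dendrogram_leaves(node$left)
    rv <- dendrogram_leaves(node$right)
    ann <- list()
    for (v in variables) {
      x <- sv[[v]]
      names(x) <- rownames(sv)
      if (is.numeric(x)) {
        xl <- x[lv][!is.na(x[lv])]
        xr <- x[rv][!is.na(x[rv])]
        if (length(xl) && length(xr)) {
          ann[[v]] <- ks_best_separation(xl, xr)
        }
      } else {
        ann[[v]] <- list(
          left = table(x[lv], useNA = "no"),
          right = table(x[rv], useNA = "no"))
      }
    }
    node$ks_annotations <- ann
    node
  }
  rec(tree)
}

#' AIC of an ordinary least-squares fit
#'
#' Fits `target ~ 1 + design` and scores it as
#' `N * ln(RSS / N) + 2 * (k + 1)` with `k` = number of features + 1 for the
#' intercept. Constant terms of the Gaussian likelihood are omitted: only
#' AIC differences between models on the same response matter. The residual
#' sum of squares is floored at 1e-12 to keep perfect fits finite.
#'
#' @param design numeric matrix of feature columns (no intercept column).
#' @param target numeric response.
#' @return scalar AIC.
#' @export
aic_linear <- function(design, target) {
  design <- as.matrix(design)
  N <- length(target)
  if (N < ncol(design) + 2L) {
    stop("aic_linear: need at least ", ncol(design) + 2L, " observations",
         call. = FALSE)
  }
  X <- cbind(1, design)
  fit <- stats::lm.fit(X, target)
  if (fit$rank < ncol(X)) {
    stop("SingularDesign: collinear feature columns", call. = FALSE)
  }
  rss <- max(sum(fit$residuals^2), 1e-12)
  k <- ncol(design) + 1L
  N * log(rss / N) + 2 * (k + 1L)
}

# log10 transform with a half-minimum pseudo-count per lipid column;
# unobserved (NA) abundances are treated as zero before the pseudo-count.
.log_abundance_matrix <- function(ab) {
  ab[is.na(ab)] <- 0
  apply(ab, 2L, function(x) {
    pos <- x[x > 0]
    pseudo <- if (length(pos)) min(pos) / 2 else 1
    log10(x + pseudo)
  })
}

.encode_target <- function(variable, values) {
  if (variable$kind == "numerical") {
    return(list(list(label = variable$name, y = as.numeric(values))))
  }
  lev <- sort(unique(as.character(values)))
  if (length(lev) < 2L) {
    stop("sfs_select: variable '", variable$name,
         "' has fewer than 2 distinct values", call. = FALSE)
  }
  if (length(lev) == 2L) {
    return(list(list(label = paste0(variable$name, "=", lev[2L]),
                     y = as.numeric(values == lev[2L]))))
  }
  lapply(lev, function(l) {             # one-vs-rest encodings
    list(label = paste0(variable$name, "=", l), y = as.numeric(values == l))
  })
}

#' Sequential forward selection of lipids for a study variable
#'
#' Greedy forward selection over multiple linear regressions on
#' log10-transformed abundances: round r evaluates every superset of the
#' previous selection by one lipid (n - r + 1 models) and keeps the
#' AIC-minimal one; the search stops after ceiling(sqrt(n)) rounds to limit
#' computation and overfitting, and the best step is the global AIC minimum
#' across rounds. Binary categorical targets are coded 0/1; variables with
#' more than two categories are encoded one-vs-rest per category and the
#' best-scoring encoding is retained. AIC ties go to the lower lipid index.
#'
#' @param table a `lipidome_table`.
#' @param variable a study variable name (looked up in the table) or a list
#'   with `name`, `kind` (`"categorical"`/`"numerical"`) and `values`.
#' @param max_steps optional cap overriding ceiling(sqrt(n)).
#' @return list of class `sfs_result`: `selected_lipids` (ordered selection
#'   path), `aic_trace`, `best_step`, `best_lipids`
#'   (`selected_lipids[1:best_step]`), `models_evaluated`, `encoding`.
#' @export
sfs_select <- function(table, variable, max_steps = NULL) {
  ab <- table$abundances
  if (is.character(variable)) {
    stopifnot(variable %in% colnames(table$study_variables))
    vals <- table$study_variables[[variable]]
    variable <- list(name = variable,
                     kind = if (is.numeric(vals)) "numerical" else "categorical",
                     values = vals)
  }
  keep <- !is.na(variable$values)
  if (sum(keep) < 4L) {
    stop("sfs_select: need at least 4 samples with a non-missing variable",
         call. = FALSE)
  }
  X <- .log_abundance_matrix(ab[keep, , drop = FALSE])
  n <- ncol(X)
  stopifnot(n >= 1L)
  steps <- min(if (is.null(max_steps)) ceiling(sqrt(n)) else max_steps, n)

  run_one <- function(y) {
    selected <- integer(0)
    trace <- numeric(0)
    evaluated <- 0L
    for (r in seq_len(steps)) {
      cand <- setdiff(seq_len(n), selected)
      best_aic <- Inf; best_j <- NA_integer_
      for (j in cand) {
        a <- tryCatch(aic_linear(X[, c(selected, j), drop = FALSE], y),
                      error = function(e) Inf)
        evaluated <- evaluated + 1L
        if (a < best_aic) { best_aic <- a; best_j <- j }
      }
      selected <- c(selected, best_j)
      trace <- c(trace, best_aic)
    }
    list(selected = selected, trace = trace, evaluated = evaluated)
  }

  encodings <- .encode_target(variable, variable$values[keep])
  runs <- lapply(encodings, function(enc) c(run_one(enc$y), label = enc$label))
  best_run <- runs[[which.min(vapply(runs, function(r) min(r$trace),
                                     numeric(1)))]]
  best_step <- which.min(best_run$trace)
  structure(list(
    selected_lipids = colnames(X)[best_run$selected],
    aic_trace = best_run$trace,
    best_step = best_step,
    best_lipids = colnames(X)[best_run$selected[seq_len(best_step)]],
    models_evaluated = sum(vapply(runs, `[[`, integer(1), "evaluated")),
    encoding = best_run$label), class = "sfs_result")
}

#' @export
print.sfs_result <- function(x, ...) {
  cat(sprintf("<sfs_result> %d round(s), best step %d (AIC %.3f): %s\n",
              length(x$aic_trace), x$best_step, x$aic_trace[x$best_step],
              paste(x$best_lipids, collapse = ", ")))
  invisible(x)
}
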