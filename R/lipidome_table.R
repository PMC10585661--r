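#' Lipidome table container
#'
#' A `lipidome_table` holds a samples x lipids abundance matrix together
#' with per-sample study variables. A missing (`NA`) abundance means the
#' lipid was not observed in that sample: it is absent from that lipidome's
#' structural subspace, which is distinct from an abundance of zero.
#'
#' @param abundances numeric matrix, samples in rows, lipids in columns;
#'   dimnames required (sample ids, canonical lipid names).
#' @param study_variables optional data.frame of per-sample variables, rows
#'   aligned with the abundance rows.
#' @param skipped_lipids names that failed to parse during import (kept for
#'   QC reporting).
#' @return object of class `lipidome_table`.
#' @export
lipidome_table <- function(abundances, study_variables = NULL,
                           skipped_lipids = character()) {
  stopifnot(is.matrix(abundances), !is.null(rownames(abundances)),
            !is.null(colnames(abundances)))
  storage.mode(abundances) <- "double"
  if (is.null(study_variables)) {
    study_variables <- data.frame(row.names = rownames(abundances))
  }
  stopifnot(nrow(study_variables) == nrow(abundances))
  rownames(study_variables) <- rownames(abundances)
  structure(list(abundances = abundances,
                 study_variables = study_variables,
                 skipped_lipids = as.character(skipped_lipids)),
            class = "lipidome_table")
}

#' @export
print.lipidome_table <- function(x, ...) {
  cat(sprintf("<lipidome_table> %d samples x %d lipids, %d study variable(s)\n",
              nrow(x$abundances), ncol(x$abundances),
              ncol(x$study_variables)))
  if (length(x$skipped_lipids)) {
    cat(sprintf("  %d lipid name(s) skipped on import\n",
                length(x$skipped_lipids)))
  }
  invisible(x)
}

#' @export
dim.lipidome_table <- function(x) dim(x$abundances)

#' Sample identifiers of a lipidome table
#' @param table a `lipidome_table`.
#' @export
sample_ids <- function(table) rownames(table$abundances)

#' Lipid names of a lipidome table
#' @param table a `lipidome_table`.
#' @export
lipid_ids <- function(table) colnames(table$abundances)

#' Extract one sample as a lipidome
#'
#' @param table a `lipidome_table`.
#' @param sample sample id or index.
#' @return list with `sample_id`, `lipid_ids` (lipids observed in the
#'   sample), `abundances` and `study_variables`.
#' @export
lipidome <- function(table, sample) {
  ab <- table$abundances[sample, ]
  keep <- !is.na(ab)
  sid <- if (is.character(sample)) sample else rownames(table$abundances)[sample]
  structure(list(sample_id = sid,
                 lipid_ids = colnames(table$abundances)[keep],
                 abundances = unname(ab[keep]),
                 study_variables = as.list(table$study_variables[sid, ,
                                                                 drop = FALSE])),
            class = "lipidome")
}

#' Restrict a lipidome table to a subset of samples
#'
#' Drops lipids observed in none of the retained samples.
#'
#' @param table a `lipidome_table`.
#' @param samples sample ids or indices to keep.
#' @export
subset_samples <- function(table, samples) {
  ab <- table$abundances[samples, , drop = FALSE]
  keep <- colSums(!is.na(ab)) > 0L
  lipidome_table(ab[, keep, drop = FALSE],
                 table$study_variables[samples, , drop = FALSE],
                 table$skipped_lipids)
}
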