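#' @title Reading and writing lipidomics tables
#' @description Supported input dialects: pivot tables with lipids in rows
#'   and samples in columns or vice versa (orientation auto-detected from
#'   which axis' labels parse as lipid names), flat sample/lipid/abundance
#'   triples, and a minimal mzTab-M dialect (small-molecule summary rows).
#'   Study variables travel in rows/columns labelled `variable:<name>`.
#' @name table_io
NULL

.detect_delimiter <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  counts <- c("\t" = lengths(regmatches(line, gregexpr("\t", line))),
              "," = lengths(regmatches(line, gregexpr(",", line))),
              ";" = lengths(regmatches(line, gregexpr(";", line))))
  if (max(counts) == 0L) {
    stop("EmptyTable: no recognised delimiter in '", path, "'", call. = FALSE)
  }
  names(counts)[which.max(counts)]
}

.parse_rate <- function(labels) {
  if (length(labels) == 0L) return(0)
  ok <- vapply(labels, function(l) {
    !inherits(tryCatch(parse_lipid(l), error = identity), "error")
  }, logical(1))
  mean(ok)
}

.is_variable_label <- function(labels, variable_names) {
  startsWith(labels, "variable:") | labels %in% variable_names
}

.strip_variable_prefix <- function(labels) sub("^variable:", "", labels)

# Coerce a character vector to numeric when every non-missing entry parses.
.maybe_numeric <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (all(is.na(num) == (is.na(x) | x == ""))) num else x
}

#' Read a lipidomics abundance table
#'
#' @param path delimited text file (TAB, comma or semicolon; auto-detected).
#' @param orientation `"auto"` (default), `"lipid_rows"`, `"lipid_columns"`
#'   or `"flat_triples"`. Auto-detection picks the axis whose labels parse
#'   as lipid names at a rate of at least 50%; a three-column file with
#'   `sample`/`lipid` headers is read as flat triples.
#' @param delimiter field delimiter override.
#' @param variable_names labels to treat as study variables even without
#'   the `variable:` prefix.
#' @return a [lipidome_table()]. Unparseable lipid names are skipped with a
#'   warning and recorded in `skipped_lipids`; empty cells become missing
#'   values, not zeros.
#' @export
read_lipid_table <- function(path, orientation = c("auto", "lipid_rows",
                                                   "lipid_columns",
                                                   "flat_triples"),
                             delimiter = NULL, variable_names = character()) {
  orientation <- match.arg(orientation)
  if (is.null(delimiter)) delimiter <- .detect_delimiter(path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "",
                          colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("EmptyTable: no data rows in '", path, "'", call. = FALSE)
  }
  lowered <- tolower(colnames(df))
  if (orientation == "flat_triples" ||
      (orientation == "auto" && ncol(df) == 3L &&
       all(c("sample", "lipid") %in% lowered))) {
    return(.from_flat(df, lowered))
  }
  row_labels <- df[[1L]]
  col_labels <- colnames(df)[-1L]
  row_var <- .is_variable_label(row_labels, variable_names)
  col_var <- .is_variable_label(col_labels, variable_names)
  if (orientation == "auto") {
    rr <- .parse_rate(row_labels[!row_var])
    cr <- .parse_rate(col_labels[!col_var])
    if (rr < 0.5 && cr < 0.5) {
      stop("NoLipidAxis: neither axis' labels parse as lipid names",
           call. = FALSE)
    }
    orientation <- if (rr >= cr) "lipid_rows" else "lipid_columns"
  }
  if (orientation == "lipid_columns") {
    # transpose to the lipid_rows layout and re-dispatch
    mat <- t(as.matrix(df[, -1L, drop = FALSE]))
    colnames(mat) <- row_labels
    df <- data.frame(lipid = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    row_labels <- df[[1L]]
    col_labels <- colnames(df)[-1L]
    row_var <- .is_variable_label(row_labels, variable_names)
    col_var <- .is_variable_label(col_labels, variable_names)
  }
  samples <- col_labels[!col_var]
  lipid_rows <- which(!row_var)
  canon <- character(0); keep_rows <- integer(0); skipped <- character(0)
  for (i in lipid_rows) {
    parsed <- tryCatch(parse_lipid(row_labels[i]), error = identity)
    if (inherits(parsed, "error")) {
      skipped <- c(skipped, row_labels[i])
    } else {
      keep_rows <- c(keep_rows, i)
      canon <- c(canon, format(parsed))
    }
  }
  if (length(skipped)) {
    warning(length(skipped), " lipid name(s) could not be parsed and were ",
            "skipped: ", paste(utils::head(skipped, 5L), collapse = ", "),
            call. = FALSE)
  }
  if (length(keep_rows) == 0L) {
    stop("NoLipidAxis: no parseable lipid names", call. = FALSE)
  }
  num <- as.matrix(df[keep_rows, c(FALSE, !col_var), drop = FALSE])
  ab <- t(apply(num, 1L, function(x) suppressWarnings(as.numeric(x))))
  if (length(keep_rows) == 1L) ab <- matrix(ab, nrow = 1L)
  rownames(ab) <- canon
  colnames(ab) <- samples
  sv <- data.frame(row.names = samples)
  for (i in which(row_var)) {
    sv[[.strip_variable_prefix(row_labels[i])]] <-
      .maybe_numeric(unlist(df[i, c(FALSE, !col_var)], use.names = FALSE))
  }
  lipidome_table(t(ab), sv, skipped)
}

.from_flat <- function(df, lowered) {
  si <- match("sample", lowered); li <- match("lipid", lowered)
  ai <- setdiff(seq_len(3L), c(si, li))
  samples <- unique(df[[si]])
  skipped <- character(0)
  canon <- vapply(df[[li]], function(nm) {
    p <- tryCatch(parse_lipid(nm), error = identity)
    if (inherits(p, "error")) NA_character_ else format(p)
  }, character(1))
  if (anyNA(canon)) {
    skipped <- unique(df[[li]][is.na(canon)])
    warning(length(skipped), " lipid name(s) could not be parsed and were ",
            "skipped: ", paste(utils::head(skipped, 5L), collapse = ", "),
            call. = FALSE)
  }
  keep <- !is.na(canon)
  lipids <- unique(canon[keep])
  if (length(lipids) == 0L) {
    stop("NoLipidAxis: no parseable lipid names", call. = FALSE)
  }
  ab <- matrix(NA_real_, length(samples), length(lipids),
               dimnames = list(samples, lipids))
  vals <- suppressWarnings(as.numeric(df[[ai]]))
  ab[cbind(match(df[[si]][keep], samples), match(canon[keep], lipids))] <-
    vals[keep]
  lipidome_table(ab, NULL, skipped)
}

#' Write a lipidome table as a pivot text file
#'
#' Lipids in rows, samples in columns; study variables are appended as
#' `variable:<name>` rows. Values are written at full precision with `.` as
#' the decimal separator, so `read_lipid_table()` round-trips them.
#'
#' @param table a `lipidome_table`.
#' @param path output file; `.csv` writes comma-separated, anything else
#'   TAB-separated.
#' @export
write_lipid_table <- function(table, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ab <- t(table$abundances)               # lipids x samples
  body <- apply(ab, 2L, function(x) {
    ifelse(is.na(x), "", sprintf("%.17g", x))   # lossless double round trip
  })
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(ab))
  out <- cbind(lipid = rownames(ab), body)
  colnames(out) <- c("lipid", colnames(ab))
  for (v in colnames(table$study_variables)) {
    out <- rbind(out, c(paste0("variable:", v),
                        as.character(table$study_variables[[v]])))
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a minimal mzTab-M file
#'
#' Supports the small-molecule summary dialect: an `SMH` header line naming
#' a `chemical_name` column and `abundance_assay[n]` columns, followed by
#' `SML` rows. One lipidome per assay; missing abundance cells stay
#' missing. Assay display names are taken from `MTD assay[n]` lines when
#' present.
#'
#' @param path mzTab-M file.
#' @return a [lipidome_table()].
#' @export
read_mztab_m <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  types <- vapply(fields, function(f) if (length(f)) f[[1L]] else "",
                  character(1))
  smh <- fields[types == "SMH"]
  sml <- fields[types == "SML"]
  if (length(smh) != 1L || length(sml) == 0L) {
    stop("MalformedMzTab: need one SMH header line and at least one SML row",
         call. = FALSE)
  }
  header <- smh[[1L]]
  name_col <- which(header == "chemical_name")
  ab_cols <- grep("^abundance_assay\\[[0-9]+\\]$", header)
  if (length(name_col) != 1L || length(ab_cols) == 0L) {
    stop("MalformedMzTab: SMH must name chemical_name and abundance_assay[n] columns",
         call. = FALSE)
  }
  assays <- sub("^abundance_", "", header[ab_cols])
  mtd <- fields[types == "MTD"]
  for (m in mtd) {
    if (length(m) >= 3L && m[[2L]] %in% assays) {
      assays[assays == m[[2L]]] <- m[[3L]]
    }
  }
  canon <- character(0); rows <- list(); skipped <- character(0)
  for (r in sml) {
    nm <- if (length(r) >= name_col) r[[name_col]] else ""
    p <- tryCatch(parse_lipid(nm), error = identity)
    if (inherits(p, "error")) {
      skipped <- c(skipped, nm)
      next
    }
    vals <- vapply(ab_cols, function(ci) {
      v <- if (length(r) >= ci) r[[ci]] else ""
      if (v %in% c("", "null", "NA")) NA_real_
      else suppressWarnings(as.numeric(v))
    }, numeric(1))
    canon <- c(canon, format(p))
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(skipped)) {
    warning(length(skipped), " SML row(s) with unparseable names skipped",
            call. = FALSE)
  }
  if (length(rows) == 0L) {
    stop("MalformedMzTab: no parseable SML rows", call. = FALSE)
  }
  ab <- do.call(rbind, rows)
  dimnames(ab) <- list(canon, assays)
  lipidome_table(t(ab), NULL, skipped)
}

#' Import-time quality control of a lipidome table
#'
#' Runs the Benford's-law check on the pooled positive abundances and scans
#' for duplicate lipids, negative abundance cells and the missing-value
#' rate. Findings are informative, never fatal.
#'
#' @param table a `lipidome_table`.
#' @return list of class `import_qc`: `benford` (a [benford_check()]
#'   report), `missing_rate`, and `findings`, a list of problem records
#'   (empty for a clean conforming table).
#' @export
import_qc <- function(table) {
  ab <- table$abundances
  benford <- benford_check(ab[!is.na(ab) & ab > 0])
  findings <- list()
  if (isFALSE(benford$conforms)) {
    findings[[length(findings) + 1L]] <- list(
      type = "benford",
      message = sprintf("leading-digit distribution deviates from Benford's law (chi2 = %.1f, p = %.3g)",
                        benford$chi2, benford$p_value))
  }
  dup <- unique(colnames(ab)[duplicated(colnames(ab))])
  for (d in dup) {
    findings[[length(findings) + 1L]] <- list(
      type = "duplicate_lipid", lipid = d,
      message = paste0("duplicate lipid '", d, "'"))
  }
  neg <- which(!is.na(ab) & ab < 0, arr.ind = TRUE)
  for (i in seq_len(nrow(neg))) {
    findings[[length(findings) + 1L]] <- list(
      type = "negative_abundance",
      sample = rownames(ab)[neg[i, 1L]], lipid = colnames(ab)[neg[i, 2L]],
      message = sprintf("negative abundance at sample '%s', lipid '%s'",
                        rownames(ab)[neg[i, 1L]], colnames(ab)[neg[i, 2L]]))
  }
  if (length(table$skipped_lipids)) {
    findings[[length(findings) + 1L]] <- list(
      type = "skipped_lipids", names = table$skipped_lipids,
      message = paste0(length(table$skipped_lipids),
                       " lipid name(s) skipped on import"))
  }
  structure(list(benford = benford, missing_rate = mean(is.na(ab)),
                 findings = findings), class = "import_qc")
}

#' @export
print.import_qc <- function(x, ...) {
  cat(sprintf("<import_qc> Benford p = %.3g (conforms: %s), missing rate %.1f%%, %d finding(s)\n",
              x$benford$p_value, x$benford$conforms, 100 * x$missing_rate,
              length(x$findings)))
  for (f in x$findings) cat("  -", f$message, "\n")
  invisible(x)
}

#' Write a distance matrix as TSV
#'
#' @param D matrix with dimnames.
#' @param path output path.
#' @param digits decimals (default 6).
#' @export
write_distance_matrix <- function(D, path, digits = 6L) {
  out <- format(round(D, digits), nsmall = digits, trim = TRUE)
  utils::write.table(cbind(id = rownames(D), out), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
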