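#' @title Structural lipid space models
#' @description The global structural space embeds every distinct lipid of
#'   an analysis by principal component analysis of the pairwise structural
#'   distance matrix: each lipid's distance profile (its matrix row) is one
#'   observation, the matrix is column-centred, and the leading principal
#'   components (default 7) become the lipid coordinates. Per-lipidome
#'   subspaces are row subsets of the global coordinates, optionally
#'   augmented with one quantity dimension derived from the lipid
#'   abundances.
#' @name lipid_space
NULL

#' Build the global structural space from a set of lipids
#'
#' @param lipids list of `lipid` objects or character vector of names.
#' @param mode chain matching mode, see [lipid_similarity()].
#' @param n_components number of principal components to retain (default 7;
#'   capped at the number of lipids).
#' @param distance_matrix optionally, a precomputed distance matrix (skips
#'   the pairwise structural comparison).
#' @return object of class `lipid_space`: `lipid_ids`, `coordinates`
#'   (n x n' matrix), `explained_variance` (component variances,
#'   non-increasing), `is_global`. The sign of each component is fixed so
#'   that its largest-magnitude loading is positive, making runs
#'   bit-reproducible.
#' @examples
#' sp <- build_global_space(c("PC 34:1", "PC 36:2", "PE 34:1", "TG 52:2"),
#'                          n_components = 3)
#' sp$coordinates
#' @export
build_global_space <- function(lipids, mode = c("best_permutation", "sn_strict"),
                               n_components = 7L, distance_matrix = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_components >= 2L)
  D <- if (is.null(distance_matrix)) {
    lipid_distance_matrix(lipids, mode = mode)
  } else {
    distance_matrix
  }
  n <- nrow(D)
  if (n < 2L) stop("DegenerateInput: need at least 2 distinct lipids",
                   call. = FALSE)
  if (all(D == 0)) {
    stop("DegenerateInput: all lipids are structurally identical",
         call. = FALSE)
  }
  k <- min(n_components, n)
  pc <- stats::prcomp(D, center = TRUE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                 # deterministic sign convention
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(D)
  structure(list(lipid_ids = rownames(D), coordinates = scores,
                 explained_variance = pc$sdev[seq_len(k)]^2,
                 rotation = rot, center = pc$center, is_global = TRUE),
            class = "lipid_space")
}

#' @export
print.lipid_space <- function(x, ...) {
  cat(sprintf("<lipid_space> %s, %d lipids x %d components\n",
              if (isTRUE(x$is_global)) "global" else "lipidome subspace",
              length(x$lipid_ids), ncol(x$coordinates)))
  invisible(x)
}

#' Subspace of the global model for one lipidome
#'
#' Selects the rows of the global coordinates belonging to the lipids
#' observed in the lipidome. With `use_quantities = TRUE` one extra
#' coordinate per lipid is appended: the log10 abundances are standardised
#' and rescaled to the standard deviation of the subspace's first principal
#' component scores, so that the quantity dimension is commensurate with the
#' structural dimensions. Constant or single-lipid abundance vectors map to
#' a zero quantity coordinate.
#'
#' @param global a global `lipid_space`.
#' @param lipidome a `lipidome` (see [lipidome()]), or any list with
#'   `lipid_ids` and `abundances`.
#' @param use_quantities append the quantity dimension? (default `TRUE`).
#' @return a `lipid_space` with `is_global = FALSE`.
#' @export
lipidome_subspace <- function(global, lipidome, use_quantities = TRUE) {
  ids <- lipidome$lipid_ids
  missing <- setdiff(ids, global$lipid_ids)
  if (length(missing)) {
    stop("UnknownLipid: not in the global space: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  coords <- global$coordinates[ids, , drop = FALSE]
  if (use_quantities) {
    q <- log10(lipidome$abundances)
    s <- stats::sd(q)
    z <- if (length(q) > 1L && is.finite(s) && s > 0) (q - mean(q)) / s
         else rep(0, length(q))
    pc1_sd <- if (nrow(coords) > 1L) stats::sd(coords[, 1L]) else 0
    coords <- cbind(coords, quantity = z * pc1_sd)
  }
  structure(list(lipid_ids = ids, coordinates = coords,
                 explained_variance = global$explained_variance,
                 is_global = FALSE), class = "lipid_space")
}
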