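#' @title Comparing lipidomes: Hausdorff distance and clustering
#' @description Lipidomes are compared as point sets in the structural
#'   space: the distance between two lipidomes is the Hausdorff distance
#'   between their (optionally quantity-augmented) subspace coordinates, so
#'   no shared lipid species are required. The resulting m x m matrix is
#'   clustered agglomeratively into a dendrogram.
#' @name lipidome_distance
NULL

#' Hausdorff distance between two point sets
#'
#' max of the two directed distances max_a min_b ||a - b||. Uses the
#' early-break scan: a point whose nearest neighbour is already closer than
#' the current maximum cannot raise it and is abandoned early. The result is
#' exactly equal to the naive double-loop evaluation.
#'
#' @param A,B numeric matrices with points in rows and equal column count.
#' @return non-negative scalar.
#' @examples
#' hausdorff(matrix(c(0, 0), 1), matrix(c(3, 4), 1))  # 5
#' @export
hausdorff <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) {
    stop("DimensionMismatch: point sets have different dimensionality",
         call. = FALSE)
  }
  stopifnot(nrow(A) >= 1L, nrow(B) >= 1L)
  directed2 <- function(X, Y) {
    cmax2 <- 0
    tY <- t(Y)
    for (i in seq_len(nrow(X))) {
      cmin2 <- Inf
      xi <- X[i, ]
      for (j in seq_len(ncol(tY))) {
        d2 <- sum((xi - tY[, j])^2)
        if (d2 < cmax2) { cmin2 <- -1; break }   # cannot raise the maximum
        if (d2 < cmin2) cmin2 <- d2
      }
      if (cmin2 > cmax2) cmax2 <- cmin2
    }
    cmax2
  }
  sqrt(max(directed2(A, B), directed2(B, A)))
}

#' Pairwise Hausdorff distance matrix over all lipidomes of a table
#'
#' @param table a `lipidome_table`.
#' @param space optional precomputed global `lipid_space` over the table's
#'   lipids; built on the fly when `NULL`.
#' @param use_quantities augment subspaces with the quantity dimension
#'   (default `TRUE`); both members of every pair live in the same
#'   augmented space.
#' @param mode,n_components passed to [build_global_space()] when `space`
#'   is `NULL`.
#' @return symmetric m x m matrix with zero diagonal and sample ids as
#'   dimnames.
#' @export
lipidome_distance_matrix <- function(table, space = NULL,
                                     use_quantities = TRUE,
                                     mode = "best_permutation",
                                     n_components = 7L) {
  stopifnot(inherits(table, "lipidome_table"))
  m <- nrow(table$abundances)
  if (m < 2L) stop("TooFewSamples: need at least 2 lipidomes", call. = FALSE)
  if (is.null(space)) {
    space <- build_global_space(lipid_ids(table), mode = mode,
                                n_components = n_components)
  }
  sets <- lapply(seq_len(m), function(i) {
    lipidome_subspace(space, lipidome(table, i),
                      use_quantities = use_quantities)$coordinates
  })
  D <- matrix(0, m, m, dimnames = list(sample_ids(table), sample_ids(table)))
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      D[i, j] <- D[j, i] <- hausdorff(sets[[i]], sets[[j]])
    }
  }
  D
}

# -- agglomerative clustering ------------------------------------------------

.leaf_node <- function(id) {
  structure(list(leaf = TRUE, sample_id = id), class = "dendrogram_node")
}

.internal_node <- function(left, right, height) {
  structure(list(leaf = FALSE, left = left, right = right,
                 height = height, ks_annotations = NULL),
            class = "dendrogram_node")
}

#' Agglomerative clustering of a lipidome distance matrix
#'
#' Hand-stepped agglomeration with deterministic tie-breaking: at each step
#' the minimal off-diagonal entry is merged, ties resolved by the smallest
#' (i, j) index pair in the current cluster ordering (merged clusters keep
#' the position of their first member). `"average"` linkage is unweighted
#' (UPGMA): the distance between clusters is the arithmetic mean over all
#' cross pairs. Merge heights are the merge distances, untransformed.
#'
#' @param D symmetric distance matrix with zero diagonal and sample ids as
#'   dimnames.
#' @param linkage `"single"`, `"average"` (default) or `"complete"`.
#' @return root `dendrogram_node`: leaves carry `sample_id`; internal nodes
#'   carry `left`, `right`, `height` and (after
#'   [annotate_dendrogram()]) `ks_annotations`.
#' @export
cluster_lipidomes <- function(D, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(D), nrow(D) == ncol(D), all(abs(diag(D)) < 1e-12),
            isTRUE(all.equal(D, t(D))))
  m <- nrow(D)
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  if (m == 1L) return(.leaf_node(ids[1L]))
  nodes <- lapply(ids, .leaf_node)
  sizes <- rep(1L, m)
  act <- D
  while (length(nodes) > 1L) {
    k <- length(nodes)
    best <- c(NA_integer_, NA_integer_); bd <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        if (act[i, j] < bd) { bd <- act[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    merged <- .internal_node(nodes[[i]], nodes[[j]], bd)
    newd <- vapply(seq_len(k), function(l) {
      if (l == i || l == j) return(NA_real_)
      switch(linkage,
        single = min(act[i, l], act[j, l]),
        complete = max(act[i, l], act[j, l]),
        average = (sizes[i] * act[i, l] + sizes[j] * act[j, l]) /
                  (sizes[i] + sizes[j]))
    }, numeric(1))
    nodes[[i]] <- merged
    sizes[i] <- sizes[i] + sizes[j]
    act[i, ] <- newd
    act[, i] <- newd
    act[i, i] <- 0
    nodes <- nodes[-j]
    sizes <- sizes[-j]
    act <- act[-j, -j, drop = FALSE]
  }
  nodes[[1L]]
}

#' Leaves of a dendrogram node
#' @param node a `dendrogram_node`.
#' @return character vector of sample ids, left-to-right.
#' @export
dendrogram_leaves <- function(node) {
  if (isTRUE(node$leaf)) return(node$sample_id)
  c(dendrogram_leaves(node$left), dendrogram_leaves(node$right))
}

#' @export
print.dendrogram_node <- function(x, ...) {
  lv <- dendrogram_leaves(x)
  if (isTRUE(x$leaf)) {
    cat(sprintf("<dendrogram leaf> %s\n", x$sample_id))
  } else {
    cat(sprintf("<dendrogram> %d leaves, root height %.4g\n",
                length(lv), x$height))
  }
  invisible(x)
}

# -- Newick serialization ----------------------------------------------------

.newick_label <- function(id) gsub("[,;:()\\s]", "_", id, perl = TRUE)

#' Serialize a dendrogram to Newick
#'
#' Branch lengths are height differences between parent and child (leaf
#' height 0), so cophenetic heights are preserved.
#'
#' @param node root `dendrogram_node`.
#' @return Newick string (with trailing `";"`).
#' @export
to_newick <- function(node) {
  rec <- function(n, parent_height) {
    bl <- parent_height - (if (isTRUE(n$leaf)) 0 else n$height)
    body <- if (isTRUE(n$leaf)) {
      .newick_label(n$sample_id)
    } else {
      paste0("(", rec(n$left, n$height), ",", rec(n$right, n$height), ")")
    }
    paste0(body, ":", format(bl, digits = 15, scientific = FALSE))
  }
  if (isTRUE(node$leaf)) {
    return(paste0(.newick_label(node$sample_id), ";"))
  }
  paste0("(", rec(node$left, node$height), ",",
         rec(node$right, node$height), ");")
}

#' Parse a Newick string back into a dendrogram
#'
#' Reads the tree with \pkg{ape} and reconstructs node heights from the
#' root-to-node path lengths (valid for the monotone trees produced by
#' [cluster_lipidomes()], where every leaf sits at height 0).
#'
#' @param text Newick string.
#' @return root `dendrogram_node`.
#' @export
newick_to_dendrogram <- function(text) {
  tr <- ape::read.tree(text = text)
  depths <- ape::node.depth.edgelength(tr)
  total <- max(depths[seq_len(ape::Ntip(tr))])
  build <- function(node_id) {
    kids <- tr$edge[tr$edge[, 1L] == node_id, 2L]
    if (length(kids) == 0L) {
      return(.leaf_node(tr$tip.label[node_id]))
    }
    stopifnot(length(kids) == 2L)
    .internal_node(build(kids[1L]), build(kids[2L]),
                   total - depths[node_id])
  }
  build(ape::Ntip(tr) + 1L)
}

#' Re-run the analysis on the lipidomes below a dendrogram node
#'
#' Restricts the table to the node's leaves, shrinks the lipid universe to
#' the union of the remaining lipidomes, and recomputes the global space,
#' the lipidome distance matrix and the dendrogram.
#'
#' @param node a `dendrogram_node` with at least 2 leaves.
#' @param table the full `lipidome_table`.
#' @param use_quantities,mode,n_components,linkage analysis parameters, see
#'   [lipidome_analysis()].
#' @return a `lipidome_analysis` result for the subset.
#' @export
subtree_reanalysis <- function(node, table, use_quantities = TRUE,
                               mode = "best_permutation", n_components = 7L,
                               linkage = "average") {
  leaves <- dendrogram_leaves(node)
  if (length(leaves) < 2L) {
    stop("TooFewSamples: subtree has fewer than 2 lipidomes", call. = FALSE)
  }
  lipidome_analysis(subset_samples(table, leaves),
                    use_quantities = use_quantities, mode = mode,
                    n_components = n_components, linkage = linkage)
}

#' Full lipidome analysis pipeline
#'
#' Builds the global structural space over all lipids of the table, the
#' per-lipidome Hausdorff distance matrix, and the dendrogram, annotated
#' with the table's study variables.
#'
#' @param table a `lipidome_table`.
#' @param use_quantities include abundances as an extra subspace dimension.
#' @param mode chain matching mode, see [lipid_similarity()].
#' @param n_components principal components of the global space.
#' @param linkage clustering linkage, see [cluster_lipidomes()].
#' @return list of class `lipidome_analysis`: `space`, `distance_matrix`,
#'   `dendrogram`, `table`.
#' @export
lipidome_analysis <- function(table, use_quantities = TRUE,
                              mode = "best_permutation", n_components = 7L,
                              linkage = "average") {
  space <- build_global_space(lipid_ids(table), mode = mode,
                              n_components = n_components)
  D <- lipidome_distance_matrix(table, space,
                                use_quantities = use_quantities)
  tree <- cluster_lipidomes(D, linkage = linkage)
  if (ncol(table$study_variables) > 0L && !isTRUE(tree$leaf)) {
    tree <- annotate_dendrogram(tree, table)
  }
  structure(list(space = space, distance_matrix = D, dendrogram = tree,
                 table = table), class = "lipidome_analysis")
}

#' @export
print.lipidome_analysis <- function(x, ...) {
  cat(sprintf("<lipidome_analysis> %d lipidomes, %d lipids, %d components\n",
              nrow(x$distance_matrix), length(x$space$lipid_ids),
              ncol(x$space$coordinates)))
  invisible(x)
}
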