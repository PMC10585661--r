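#' Molecular graphs for headgroup/backbone structures
#'
#' A `mol_graph` is a hydrogen-suppressed labelled graph: heavy atoms carry
#' an element symbol, bonds carry an order (1 = single, 2 = double). Graphs
#' are used for the fixed backbone + headgroup part of each lipid class; the
#' variable carbon chains are handled arithmetically (see
#' [chain_graph_size()]).
#'
#' @param atoms character vector of element symbols ("C", "O", "N", "P", ...).
#' @param bonds integer matrix with columns `a`, `b`, `order`; atom ids are
#'   indices into `atoms`.
#' @return An object of class `mol_graph`.
#' @keywords internal
mol_graph <- function(atoms = character(), bonds = NULL) {
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- matrix(integer(), ncol = 3L, dimnames = list(NULL, c("a", "b", "order")))
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 3L, dimnames = list(NULL, c("a", "b", "order")))
  }
  n <- length(atoms)
  if (NROW(bonds) > 0L) {
    stopifnot(all(bonds[, 1:2] >= 1L), all(bonds[, 1:2] <= n),
              all(bonds[, 1L] != bonds[, 2L]), all(bonds[, 3L] %in% 1:2))
  }
  structure(list(atoms = as.character(atoms), bonds = bonds), class = "mol_graph")
}

#' Number of components (atoms + bonds) of a molecular graph
#' @param g a `mol_graph`.
#' @keywords internal
graph_size <- function(g) length(g$atoms) + nrow(g$bonds)

# Small mutable builder used to write the class registry compactly.
graph_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$atoms <- character()
  env$bonds <- list()
  env
}

gb_atom <- function(gb, element) {
  gb$atoms <- c(gb$atoms, element)
  length(gb$atoms)
}

gb_bond <- function(gb, a, b, order = 1L) {
  gb$bonds[[length(gb$bonds) + 1L]] <- c(a, b, order)
  invisible(NULL)
}

# Append a simple carbon path of length n; returns atom ids.
gb_carbon_path <- function(gb, n) {
  ids <- vapply(seq_len(n), function(i) gb_atom(gb, "C"), integer(1))
  if (n > 1L) for (i in seq_len(n - 1L)) gb_bond(gb, ids[i], ids[i + 1L])
  ids
}

# Attach a single new atom to an existing atom.
gb_attach <- function(gb, to, element, order = 1L) {
  id <- gb_atom(gb, element)
  gb_bond(gb, to, id, order)
  id
}

gb_build <- function(gb) {
  bonds <- if (length(gb$bonds)) do.call(rbind, gb$bonds) else NULL
  mol_graph(gb$atoms, bonds)
}

# Adjacency matrix with bond orders as entries (0 = no bond).
graph_adjacency <- function(g) {
  n <- length(g$atoms)
  A <- matrix(0L, n, n)
  b <- g$bonds
  if (nrow(b)) {
    A[cbind(b[, 1L], b[, 2L])] <- b[, 3L]
    A[cbind(b[, 2L], b[, 1L])] <- b[, 3L]
  }
  A
}
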