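#' Exact maximum common connected subgraph between two molecular graphs
#'
#' Branch-and-bound search for the largest connected common subgraph of two
#' labelled molecular graphs, scored in components (matched atoms + matched
#' bonds). Atom element labels and bond orders must agree for a match; a
#' double bond is a single component whose order attribute must match.
#' Connectivity is required through matched bonds. The search is
#' deterministic (fixed seed-pair and candidate ordering), so the result is
#' reproducible and symmetric in its arguments.
#'
#' @param ga,gb `mol_graph` objects.
#' @return list with `size` (atoms + bonds of the best common subgraph),
#'   `n_atoms` and `n_bonds`.
#' @keywords internal
mcs_connected <- function(ga, gb) {
  na <- length(ga$atoms); nb <- length(gb$atoms)
  if (na == 0L || nb == 0L) {
    return(list(size = 0L, n_atoms = 0L, n_bonds = 0L))
  }
  if (na > nb) {                       # canonical orientation for symmetry
    res <- mcs_connected(gb, ga)
    return(res)
  }
  A <- graph_adjacency(ga); B <- graph_adjacency(gb)
  labA <- ga$atoms; labB <- gb$atoms
  degA <- rowSums(A > 0); degB <- rowSums(B > 0)
  dmax <- min(max(degA), max(degB))
  labels <- unique(c(labA, labB))

  best <- new.env(parent = emptyenv())
  best$size <- 0L; best$atoms <- 0L; best$bonds <- 0L

  # Upper bound on additional components from the unmapped atoms.
  bound_extra <- function(availA, availB) {
    s <- 0L
    for (l in labels) {
      s <- s + min(sum(labA[availA] == l), sum(labB[availB] == l))
    }
    s * (1L + dmax)
  }

  search <- function(mapA, usedB, score, n_at, n_bd, excluded) {
    if (score > best$size) {
      best$size <- score; best$atoms <- n_at; best$bonds <- n_bd
    }
    mapped <- which(mapA > 0L)
    frontier <- integer(0)
    for (u in seq_len(na)) {
      if (mapA[u] == 0L && !excluded[u] && any(A[u, mapped] > 0L)) {
        frontier <- c(frontier, u)
      }
    }
    if (length(frontier) == 0L) return(invisible(NULL))
    availA <- mapA == 0L & !excluded
    if (score + bound_extra(which(availA), which(!usedB)) <= best$size) {
      return(invisible(NULL))
    }
    u <- frontier[1L]
    # branch 1: map u onto each compatible neighbour image
    for (v in seq_len(nb)) {
      if (usedB[v] || labB[v] != labA[u]) next
      gain_bonds <- 0L
      connected <- FALSE
      for (a in mapped) {
        o <- A[a, u]
        if (o > 0L && B[mapA[a], v] == o) {
          gain_bonds <- gain_bonds + 1L
          connected <- TRUE
        }
      }
      if (!connected) next
      mapA[u] <- v; usedB[v] <- TRUE
      search(mapA, usedB, score + 1L + gain_bonds, n_at + 1L,
             n_bd + gain_bonds, excluded)
      mapA[u] <- 0L; usedB[v] <- FALSE
    }
    # branch 2: leave u unmatched
    excluded[u] <- TRUE
    search(mapA, usedB, score, n_at, n_bd, excluded)
    invisible(NULL)
  }

  for (u0 in seq_len(na)) {
    for (v0 in seq_len(nb)) {
      if (labB[v0] != labA[u0]) next
      mapA <- integer(na); usedB <- logical(nb)
      excluded <- seq_len(na) < u0   # u0 is the smallest mapped atom of ga
      mapA[u0] <- v0; usedB[v0] <- TRUE
      if (1L + bound_extra(which(mapA == 0L & !excluded), which(!usedB)) >
          best$size) {
        search(mapA, usedB, 1L, 1L, 0L, excluded)
      }
    }
  }
  list(size = best$size, n_atoms = best$atoms, n_bonds = best$bonds)
}

.hg_cache <- new.env(parent = emptyenv())

#' Headgroup maximum common subgraph for a pair of lipid classes
#'
#' Computes (and caches, per unordered class pair) the component counts of
#' the maximum common connected subgraph between the backbone + headgroup
#' graphs of two registered lipid classes. For identical classes the
#' intersection equals the full graph size; classes with an empty headgroup
#' graph (e.g. `FA`) contribute nothing.
#'
#' @param class_a,class_b registered class names.
#' @return list with `intersection` and `union` component counts
#'   (union = size(A) + size(B) - intersection).
#' @examples
#' headgroup_mcs("PC", "PE")
#' @export
headgroup_mcs <- function(class_a, class_b) {
  da <- class_descriptor(class_a); db <- class_descriptor(class_b)
  sa <- graph_size(da$graph); sb <- graph_size(db$graph)
  if (identical(class_a, class_b)) {
    return(list(intersection = sa, union = sa))
  }
  key <- paste(sort(c(class_a, class_b)), collapse = "\r")
  hit <- .hg_cache[[key]]
  if (!is.null(hit)) return(hit)
  inter <- mcs_connected(da$graph, db$graph)$size
  res <- list(intersection = inter, union = sa + sb - inter)
  assign(key, res, envir = .hg_cache)
  res
}
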