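# Shared fixtures and independent oracles for the test suite.

fa_chain <- function(name) parse_lipid(name)$chains[[1]]

toy_graph <- function(atoms, bonds = NULL) {
  lipidstruct:::mol_graph(atoms, bonds)
}

# Brute-force maximum common connected subgraph oracle: enumerate every
# atom subset of the first graph, every label-preserving injection into the
# second, count order-matched bonds, require connectivity through matched
# bonds, and maximise atoms + bonds. Exponential; for toy graphs only.
mcs_oracle <- function(ga, gb) {
  A <- lipidstruct:::graph_adjacency(ga)
  B <- lipidstruct:::graph_adjacency(gb)
  la <- ga$atoms; lb <- gb$atoms
  na <- length(la); nb <- length(lb)
  if (na == 0L || nb == 0L) return(0L)
  best <- 0L
  score_map <- function(S, phi) {
    matched <- matrix(0L, length(S), length(S))
    for (i in seq_along(S)) {
      for (j in seq_along(S)) {
        if (i < j && A[S[i], S[j]] > 0L &&
            B[phi[i], phi[j]] == A[S[i], S[j]]) {
          matched[i, j] <- matched[j, i] <- 1L
        }
      }
    }
    # connectivity over matched bonds
    seen <- c(1L, integer(0))
    frontier <- 1L
    while (length(frontier)) {
      nxt <- setdiff(which(rowSums(matched[, seen, drop = FALSE]) > 0), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (length(seen) < length(S)) return(-1L)
    length(S) + sum(matched) %/% 2L
  }
  enum_inj <- function(S, used, phi) {
    if (length(phi) == length(S)) {
      s <- score_map(S, phi)
      if (s > best) best <<- s
      return(invisible(NULL))
    }
    i <- length(phi) + 1L
    for (v in seq_len(nb)) {
      if (!used[v] && lb[v] == la[S[i]]) {
        used[v] <- TRUE
        enum_inj(S, used, c(phi, v))
        used[v] <- FALSE
      }
    }
  }
  for (mask in seq_len(2^na - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(na) - 1L)) > 0L)
    if (length(S) > nb) next
    enum_inj(S, logical(nb), integer(0))
  }
  best
}

# Naive double-loop Hausdorff oracle.
hausdorff_naive <- function(A, B) {
  dist_one <- function(X, Y) {
    max(vapply(seq_len(nrow(X)), function(i) {
      min(vapply(seq_len(nrow(Y)), function(j) {
        sum((X[i, ] - Y[j, ])^2)
      }, numeric(1)))
    }, numeric(1)))
  }
  sqrt(max(dist_one(A, B), dist_one(B, A)))
}

# Prim MST edge weights (for the single-linkage oracle).
mst_edge_weights <- function(D) {
  m <- nrow(D)
  in_tree <- c(TRUE, rep(FALSE, m - 1L))
  edges <- numeric(0)
  while (sum(in_tree) < m) {
    sub <- D[in_tree, !in_tree, drop = FALSE]
    k <- which.min(sub)
    edges <- c(edges, min(sub))
    j <- which(!in_tree)[(k - 1L) %/% sum(in_tree) + 1L]
    in_tree[j] <- TRUE
  }
  sort(edges)
}

# Configuration with one compositional marker class per group: three
# structurally planted lipidome clusters.
planted_cluster_config <- function(seed) {
  simulation_config(seed = seed, n_samples = 15L, n_groups = 3L,
                    planted_effects = list(
                      list(class = "PC", group = "G1", exclusive = TRUE),
                      list(class = "TG", group = "G2", exclusive = TRUE),
                      list(class = "SM", group = "G3", exclusive = TRUE)))
}

# Does the dendrogram's root split plus the next split of the larger side
# recover a 3-group partition exactly?
recovers_three_groups <- function(tree, groups) {
  pure <- function(lv) length(unique(groups[lv])) == 1L
  sides <- list(dendrogram_leaves(tree$left), dendrogram_leaves(tree$right))
  one <- vapply(sides, pure, logical(1))
  if (!any(one)) return(FALSE)
  big <- if (one[1L] && !pure(sides[[2L]])) tree$right
         else if (one[2L] && !pure(sides[[1L]])) tree$left
         else return(FALSE)
  if (isTRUE(big$leaf)) return(FALSE)
  bl <- dendrogram_leaves(big$left); br <- dendrogram_leaves(big$right)
  pure(bl) && pure(br) &&
    length(unique(c(groups[bl], groups[br]))) == 2L &&
    length(unique(groups[unlist(sides)])) == 3L
}

# deterministic sorted newick signature of a dendrogram topology
tree_signature <- function(node) {
  if (isTRUE(node$leaf)) return(node$sample_id)
  kids <- sort(c(tree_signature(node$left), tree_signature(node$right)))
  paste0("(", kids[1L], ",", kids[2L], ")")
}
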