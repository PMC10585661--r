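#' @title Structural similarity between lipids
#' @description The distance between two lipids is 1 - Jaccard over aligned
#'   atom-and-bond components: a precomputed headgroup maximum common
#'   subgraph plus a positional alignment of the carbon chains. Components
#'   are heavy atoms and bonds; a double bond is one component whose order
#'   must match.
#' @name structure_similarity
NULL

# components contributed by one functional group unit (atoms + bonds)
.FG_COMPONENTS <- c(OH = 2L, oxo = 2L, COOH = 6L, OOH = 4L, NH2 = 2L)

.fg_component_total <- function(fg) {
  if (nrow(fg) == 0L) return(0L)
  sum(.FG_COMPONENTS[fg$name] * fg$count)
}

# matched functional-group components between two chains: per group name,
# min(count) units are matched (positions are compared only through the
# chain identity guard; unpositioned groups match by type).
.fg_matched <- function(fa, fb) {
  if (nrow(fa) == 0L || nrow(fb) == 0L) return(0L)
  ca <- tapply(fa$count, fa$name, sum)
  cb <- tapply(fb$count, fb$name, sum)
  shared <- intersect(names(ca), names(cb))
  if (!length(shared)) return(0L)
  sum(vapply(shared, function(nm) {
    .FG_COMPONENTS[[nm]] * min(ca[[nm]], cb[[nm]])
  }, numeric(1)))
}

#' Component count of a carbon-chain graph
#'
#' Counts atoms + bonds of a carbon chain under the linkage convention of
#' its context: a free fatty acid of C carbons has C carbons, two carboxyl
#' oxygens, C-1 carbon-carbon bonds and two C-O bonds (2C + 3 components; 39
#' for C18); an esterified acyl chain keeps its carbonyl oxygen and C=O bond
#' (2C components; the ester oxygen belongs to the headgroup); ether/alkenyl
#' chains and long-chain bases are plain carbon skeletons (2C - 1).
#' Functional groups add their atoms and attachment bonds. Double bonds do
#' not change the count (order is an attribute of an existing bond).
#'
#' @param chain a `carbon_chain`.
#' @param context one of `"free_acid"`, `"esterified"`, `"ether"`, `"lcb"`.
#' @return integer component count.
#' @examples
#' chain_graph_size(parse_lipid("FA 18:2")$chains[[1]], "free_acid")  # 39
#' @export
chain_graph_size <- function(chain, context = c("free_acid", "esterified",
                                                "ether", "lcb")) {
  context <- match.arg(context)
  n <- chain$num_carbon
  skel <- switch(context,
    free_acid = 2L * n + 3L,
    esterified = 2L * n,
    ether = 2L * n - 1L,
    lcb = 2L * n - 1L)
  skel + .fg_component_total(chain$fgroups)
}

.chain_skeleton <- function(chain, context) {
  chain_graph_size(.new_chain(chain$kind, chain$num_carbon, chain$num_db),
                   context)
}

# Linkage context of a chain within its class.
.chain_context <- function(class_name, kind) {
  switch(kind,
    acyl = if (class_name == "FA") "free_acid" else "esterified",
    alkyl_ether = "ether",
    alkenyl_ether = "ether",
    lcb = "lcb",
    pseudo_species = {
      desc <- class_descriptor(class_name)
      .chain_context(class_name, desc$chain_kinds[1L])
    })
}

#' Align two carbon chains and count shared components
#'
#' Chains are aligned positionally from the carbonyl/linkage carbon (forward
#' direction). The union is the skeleton of the longer chain plus all
#' functional-group components not matched between the chains; the
#' intersection is the skeleton of the shorter chain plus matched
#' functional-group components, minus double-bond mismatches. When both
#' chains carry full double-bond position sets, a mismatch is a position
#' present in exactly one chain within the aligned region; when either chain
#' lacks positions, every double bond of both chains counts as a mismatch -
#' except for two chains identical at their information level, which match
#' completely (identity guard, required for zero self-distance).
#'
#' @param a,b `carbon_chain` objects.
#' @param context_a,context_b linkage contexts (see [chain_graph_size()]).
#' @return list with integer `intersection` and `union`.
#' @examples
#' fa <- function(s) parse_lipid(s)$chains[[1]]
#' align_chains(fa("FA 18:2"), fa("FA 18:1"))           # 36 / 39
#' align_chains(fa("FA 18:2(9,12)"), fa("FA 18:1(9)"))  # 38 / 39
#' @export
align_chains <- function(a, b, context_a = "free_acid",
                         context_b = context_a) {
  skel_a <- .chain_skeleton(a, context_a)
  skel_b <- .chain_skeleton(b, context_b)
  fg_a <- .fg_component_total(a$fgroups)
  fg_b <- .fg_component_total(b$fgroups)
  matched_fg <- .fg_matched(a$fgroups, b$fgroups)

  if (.chains_identical(a, b) && context_a == context_b) {
    mismatch <- 0L
  } else if (!is.null(a$db_positions) && !is.null(b$db_positions)) {
    aligned_max <- min(a$num_carbon, b$num_carbon) - 1L
    pa <- a$db_positions[a$db_positions <= aligned_max]
    pb <- b$db_positions[b$db_positions <= aligned_max]
    mismatch <- length(setdiff(pa, pb)) + length(setdiff(pb, pa))
  } else if (a$num_db == 0L && b$num_db == 0L) {
    mismatch <- 0L
  } else {
    mismatch <- a$num_db + b$num_db
  }

  intersection <- max(0L, min(skel_a, skel_b) + matched_fg - mismatch)
  union <- max(skel_a, skel_b) + fg_a + fg_b - matched_fg
  list(intersection = as.integer(intersection), union = as.integer(union))
}

# all injective assignments of seq_len(k) into positions of seq_len(n), k<=n
.injections <- function(n, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in remaining) rec(c(prefix, v), setdiff(remaining, v))
  }
  rec(integer(0), seq_len(n))
  out
}

#' Structural similarity and distance between two lipids
#'
#' Aligns the two lipids at the lower of their information levels, sums the
#' headgroup maximum-common-subgraph component counts and the per-chain
#' alignment counts, and returns the Jaccard index (shared / united
#' components) and distance = 1 - Jaccard. Chains are paired either in sn
#' order (`"sn_strict"`) or by the pairing that maximises the total
#' intersection over all permutations (`"best_permutation"`, the default).
#' Chains left unpaired when chain counts differ contribute their full
#' component count to the union only.
#'
#' @param a,b `lipid` objects or shorthand names (parsed on the fly).
#' @param mode chain matching mode, `"best_permutation"` or `"sn_strict"`.
#' @return list with `components` (integer `intersection`, `union`),
#'   `jaccard` and `distance`, both in `[0, 1]`.
#' @examples
#' lipid_similarity("FA 18:2", "FA 18:1")$components         # 36 / 39
#' lipid_similarity("FA 18:2(9,12)", "FA 18:1(9)")$distance  # 1 - 38/39
#' @export
lipid_similarity <- function(a, b, mode = c("best_permutation", "sn_strict")) {
  mode <- match.arg(mode)
  if (is.character(a)) a <- parse_lipid(a)
  if (is.character(b)) b <- parse_lipid(b)
  lvl <- min(.LEVELS[a$level], .LEVELS[b$level])
  .similarity_core(.prepare_lipid(a, lvl), .prepare_lipid(b, lvl), mode)
}

# Project to a level rank and precompute per-chain contexts.
.prepare_lipid <- function(lipid, level_rank) {
  p <- project_to_level(lipid, names(.LEVELS)[level_rank])
  list(class_name = p$class_name, chains = p$chains,
       contexts = vapply(p$chains, function(ch) {
         .chain_context(p$class_name, ch$kind)
       }, character(1)))
}

.injection_cache <- new.env(parent = emptyenv())

.injections_cached <- function(n, k) {
  key <- paste0(n, ".", k)
  hit <- .injection_cache[[key]]
  if (is.null(hit)) {
    hit <- .injections(n, k)
    assign(key, hit, envir = .injection_cache)
  }
  hit
}

.similarity_core <- function(a, b, mode) {
  hg <- headgroup_mcs(a$class_name, b$class_name)
  swap <- length(a$chains) > length(b$chains)
  ca <- if (swap) b$chains else a$chains
  cb <- if (swap) a$chains else b$chains
  cxa <- if (swap) b$contexts else a$contexts
  cxb <- if (swap) a$contexts else b$contexts
  ka <- length(ca); kb <- length(cb)

  pairings <- if (mode == "sn_strict") list(seq_len(ka))
              else .injections_cached(kb, ka)
  best <- NULL
  for (p in pairings) {
    tot_i <- 0L; tot_u <- 0L
    for (i in seq_len(ka)) {
      al <- align_chains(ca[[i]], cb[[p[i]]], cxa[i], cxb[p[i]])
      tot_i <- tot_i + al$intersection
      tot_u <- tot_u + al$union
    }
    for (j in setdiff(seq_len(kb), p)) {
      tot_u <- tot_u + chain_graph_size(cb[[j]], cxb[j])
    }
    if (is.null(best) || tot_i > best$i ||
        (tot_i == best$i && tot_u < best$u)) {
      best <- list(i = tot_i, u = tot_u)   # max intersection, then min union
    }
  }

  inter <- hg$intersection + best$i
  uni <- hg$union + best$u
  jac <- if (uni > 0L) inter / uni else 1
  list(components = list(intersection = as.integer(inter),
                         union = as.integer(uni)),
       jaccard = jac, distance = 1 - jac)
}

#' Pairwise structural distance matrix over a set of lipids
#'
#' @param lipids list of `lipid` objects or character vector of names.
#' @param mode chain matching mode, see [lipid_similarity()].
#' @return symmetric n x n matrix of distances with canonical lipid names
#'   as dimnames.
#' @export
lipid_distance_matrix <- function(lipids,
                                  mode = c("best_permutation", "sn_strict")) {
  mode <- match.arg(mode)
  if (is.character(lipids)) lipids <- lapply(lipids, parse_lipid)
  lipids <- lapply(lipids, function(l) {
    if (is.character(l)) parse_lipid(l) else l
  })
  n <- length(lipids)
  nms <- vapply(lipids, format, character(1))
  D <- matrix(0, n, n, dimnames = list(nms, nms))
  if (n < 2L) return(D)
  ranks <- vapply(lipids, function(l) .LEVELS[[l$level]], integer(1))
  # pre-project every lipid at each level rank it will be compared at
  prep <- lapply(seq_len(n), function(i) {
    out <- vector("list", 4L)
    for (r in unique(pmin(ranks[i], ranks))) {
      out[[r]] <- .prepare_lipid(lipids[[i]], r)
    }
    out
  })
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      r <- min(ranks[i], ranks[j])
      d <- .similarity_core(prep[[i]][[r]], prep[[j]][[r]], mode)$distance
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}
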