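#' Lipid class registry
#'
#' The registry covers a curated subset of lipid classes spanning
#' glycerophospholipids (diacyl, lyso, ether/plasmalogen, cardiolipin),
#' glycerolipids, sphingolipids, sterol esters and free fatty acids. Each
#' class stores its expected chain count and kinds, its lipid category, a
#' hydrogen-suppressed backbone + headgroup graph, and a canonical example
#' name used in round-trip tests.
#'
#' Conventions for the headgroup graphs: the ester oxygen of each acylation
#' site belongs to the headgroup; the fatty acyl chain contributes its
#' carbons, its carbonyl oxygen and the bonds between them (see
#' [chain_graph_size()]). Bonds between a chain and the headgroup are not
#' counted as components of either part. For classes whose whole molecule is
#' the chain (FA, Cer backbone, sphingoid bases) the headgroup graph is
#' empty; hydroxyl and amino groups of long-chain bases are carried by the
#' chain as functional groups.
#'
#' @name class_registry
#' @keywords internal
NULL

# -- graph constructors ------------------------------------------------------

# Glycerol with three oxygens (sn-1, sn-2, sn-3); returns builder + ids.
.g_glycerol3O <- function() {
  gb <- graph_builder()
  C <- gb_carbon_path(gb, 3L)
  O1 <- gb_attach(gb, C[1], "O")
  O2 <- gb_attach(gb, C[2], "O")
  O3 <- gb_attach(gb, C[3], "O")
  list(gb = gb, C = C, O = c(O1, O2, O3))
}

# Phosphate attached to an existing oxygen: P with =O and O(-).
# Returns the P id for head-alcohol attachment.
.g_phosphate <- function(gb, O) {
  P <- gb_attach(gb, O, "P")
  gb_attach(gb, P, "O", 2L)
  gb_attach(gb, P, "O")
  P
}

.g_choline <- function(gb, P) {
  Obr <- gb_attach(gb, P, "O")
  Ca <- gb_attach(gb, Obr, "C")
  Cb <- gb_attach(gb, Ca, "C")
  N <- gb_attach(gb, Cb, "N")
  for (i in 1:3) gb_attach(gb, N, "C")
  invisible(NULL)
}

.g_ethanolamine <- function(gb, P, serine = FALSE) {
  Obr <- gb_attach(gb, P, "O")
  Ca <- gb_attach(gb, Obr, "C")
  Cb <- gb_attach(gb, Ca, "C")
  gb_attach(gb, Cb, "N")
  if (serine) {
    Cc <- gb_attach(gb, Cb, "C")
    gb_attach(gb, Cc, "O", 2L)
    gb_attach(gb, Cc, "O")
  }
  invisible(NULL)
}

.graph_gpl <- function(head = c("none", "choline", "ethanolamine", "serine",
                                "glycerol", "inositol")) {
  head <- match.arg(head)
  g <- .g_glycerol3O()
  P <- .g_phosphate(g$gb, g$O[3])
  gb <- g$gb
  switch(head,
    none = gb_attach(gb, P, "O"),                       # phosphate OH (PA)
    choline = .g_choline(gb, P),
    ethanolamine = .g_ethanolamine(gb, P),
    serine = .g_ethanolamine(gb, P, serine = TRUE),
    glycerol = {
      Obr <- gb_attach(gb, P, "O")
      C <- gb_attach(gb, Obr, "C")
      C2 <- gb_attach(gb, C, "C")
      C3 <- gb_attach(gb, C2, "C")
      gb_attach(gb, C2, "O")
      gb_attach(gb, C3, "O")
    },
    inositol = {
      Obr <- gb_attach(gb, P, "O")
      ring <- gb_carbon_path(gb, 6L)
      gb_bond(gb, ring[6], ring[1])
      gb_bond(gb, Obr, ring[1])
      for (i in 2:6) gb_attach(gb, ring[i], "O")
    })
  gb_build(gb)
}

.graph_glycerol <- function() {
  gb_build(.g_glycerol3O()$gb)
}

.graph_cardiolipin <- function() {
  gb <- graph_builder()
  Cc <- gb_carbon_path(gb, 3L)          # central glycerol
  gb_attach(gb, Cc[2], "O")             # central hydroxyl
  for (side in 1:2) {
    C <- gb_carbon_path(gb, 3L)
    O1 <- gb_attach(gb, C[1], "O")
    O2 <- gb_attach(gb, C[2], "O")
    O3 <- gb_attach(gb, C[3], "O")
    P <- gb_attach(gb, O3, "P")
    gb_attach(gb, P, "O", 2L)
    gb_attach(gb, P, "O")
    Obr <- gb_attach(gb, P, "O")
    gb_bond(gb, Obr, Cc[if (side == 1L) 1L else 3L])
  }
  gb_build(gb)
}

.graph_phosphocholine <- function() {
  gb <- graph_builder()
  O <- gb_atom(gb, "O")                  # bridge to the sphingoid C1
  P <- gb_attach(gb, O, "P")
  gb_attach(gb, P, "O", 2L)
  gb_attach(gb, P, "O")
  .g_choline(gb, P)
  gb_build(gb)
}

# n_hexose in {1, 2}; glycosidic oxygens included, anomeric O bridges to the
# ceramide; second hexose attached 1->6.
.graph_hexose_head <- function(n_hexose = 1L) {
  gb <- graph_builder()
  anchor <- gb_atom(gb, "O")            # glycosidic O to the ceramide
  for (h in seq_len(n_hexose)) {
    ring <- gb_carbon_path(gb, 5L)
    Oring <- gb_attach(gb, ring[5], "O")
    gb_bond(gb, Oring, ring[1])
    C6 <- gb_attach(gb, ring[5], "C")
    gb_bond(gb, anchor, ring[1])
    for (i in 2:4) gb_attach(gb, ring[i], "O")
    if (h < n_hexose) {
      anchor <- gb_attach(gb, C6, "O")  # 1->6 glycosidic bridge
    } else {
      gb_attach(gb, C6, "O")
    }
  }
  gb_build(gb)
}

.graph_sterol <- function() {
  gb <- graph_builder()
  # steroid nucleus: rings A (C1-5,C10), B (C5-10), C (C8,9,11-14), D (C13-17)
  C <- vapply(1:17, function(i) gb_atom(gb, "C"), integer(1))
  ring_bonds <- rbind(
    c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 10), c(10, 1),
    c(5, 6), c(6, 7), c(7, 8), c(8, 9), c(9, 10),
    c(8, 14), c(14, 13), c(13, 12), c(12, 11), c(11, 9),
    c(13, 17), c(17, 16), c(16, 15), c(15, 14))
  for (i in seq_len(nrow(ring_bonds))) {
    order <- if (all(ring_bonds[i, ] %in% c(5, 6))) 2L else 1L  # Delta-5,6
    gb_bond(gb, C[ring_bonds[i, 1]], C[ring_bonds[i, 2]], order)
  }
  gb_attach(gb, C[10], "C")             # C19 methyl
  gb_attach(gb, C[13], "C")             # C18 methyl
  C20 <- gb_attach(gb, C[17], "C")
  gb_attach(gb, C20, "C")               # C21 methyl
  C22 <- gb_attach(gb, C20, "C")
  C23 <- gb_attach(gb, C22, "C")
  C24 <- gb_attach(gb, C23, "C")
  C25 <- gb_attach(gb, C24, "C")
  gb_attach(gb, C25, "C")
  gb_attach(gb, C25, "C")
  gb_attach(gb, C[3], "O")              # 3-O (esterified by the chain)
  gb_build(gb)
}

.graph_empty <- function() mol_graph()

# -- registry ----------------------------------------------------------------

.make_class <- function(class_name, category, chain_kinds, graph, example) {
  list(class_name = class_name, category = category,
       expected_chain_count = length(chain_kinds),
       chain_kinds = chain_kinds, graph = graph, example = example)
}

.build_registry <- function() {
  gpl <- "glycerophospholipid"; gl <- "glycerolipid"; sp <- "sphingolipid"
  st <- "sterol_lipid"; fa <- "fatty_acyl"
  acyl2 <- c("acyl", "acyl")
  defs <- list(
    .make_class("FA", fa, "acyl", .graph_empty(), "FA 18:1"),
    .make_class("MG", gl, "acyl", .graph_glycerol(), "MG 18:1"),
    .make_class("DG", gl, acyl2, .graph_glycerol(), "DG 16:0_18:1"),
    .make_class("TG", gl, c("acyl", "acyl", "acyl"), .graph_glycerol(),
                "TG 16:0_18:1_18:2"),
    .make_class("PC", gpl, acyl2, .graph_gpl("choline"), "PC 16:0_18:1"),
    .make_class("PE", gpl, acyl2, .graph_gpl("ethanolamine"), "PE 16:0_18:1"),
    .make_class("PS", gpl, acyl2, .graph_gpl("serine"), "PS 16:0_18:1"),
    .make_class("PG", gpl, acyl2, .graph_gpl("glycerol"), "PG 16:0_18:1"),
    .make_class("PI", gpl, acyl2, .graph_gpl("inositol"), "PI 16:0_18:1"),
    .make_class("PA", gpl, acyl2, .graph_gpl("none"), "PA 16:0_18:1"),
    .make_class("LPC", gpl, "acyl", .graph_gpl("choline"), "LPC 18:0"),
    .make_class("LPE", gpl, "acyl", .graph_gpl("ethanolamine"), "LPE 18:0"),
    .make_class("LPS", gpl, "acyl", .graph_gpl("serine"), "LPS 18:0"),
    .make_class("LPG", gpl, "acyl", .graph_gpl("glycerol"), "LPG 18:0"),
    .make_class("LPI", gpl, "acyl", .graph_gpl("inositol"), "LPI 18:0"),
    .make_class("LPA", gpl, "acyl", .graph_gpl("none"), "LPA 18:0"),
    .make_class("PC O-", gpl, c("alkyl_ether", "acyl"), .graph_gpl("choline"),
                "PC O-16:0_18:1"),
    .make_class("PE O-", gpl, c("alkyl_ether", "acyl"),
                .graph_gpl("ethanolamine"), "PE O-16:0_18:1"),
    .make_class("PC P-", gpl, c("alkenyl_ether", "acyl"), .graph_gpl("choline"),
                "PC P-16:0_18:1"),
    .make_class("PE P-", gpl, c("alkenyl_ether", "acyl"),
                .graph_gpl("ethanolamine"), "PE P-16:0_18:1"),
    .make_class("CL", gpl, rep("acyl", 4L), .graph_cardiolipin(),
                "CL 16:0_18:1_18:1_18:2"),
    .make_class("SM", sp, c("lcb", "acyl"), .graph_phosphocholine(),
                "SM 18:1;O2/16:0"),
    .make_class("LSM", sp, "lcb", .graph_phosphocholine(), "LSM 18:1;O2"),
    .make_class("Cer", sp, c("lcb", "acyl"), .graph_empty(),
                "Cer 18:1;O2/24:0"),
    .make_class("HexCer", sp, c("lcb", "acyl"), .graph_hexose_head(1L),
                "HexCer 18:1;O2/24:0"),
    .make_class("Hex2Cer", sp, c("lcb", "acyl"), .graph_hexose_head(2L),
                "Hex2Cer 18:1;O2/24:0"),
    .make_class("SPB", sp, "lcb", .graph_empty(), "SPB 18:1;O2"),
    .make_class("CE", st, "acyl", .graph_sterol(), "CE 18:1")
  )
  names(defs) <- vapply(defs, `[[`, character(1), "class_name")
  defs
}

.registry_env <- new.env(parent = emptyenv())

.registry <- function() {
  if (is.null(.registry_env$classes)) .registry_env$classes <- .build_registry()
  .registry_env$classes
}

#' Supported lipid classes
#'
#' @return Character vector of registered class names.
#' @examples
#' lipid_classes()
#' @export
lipid_classes <- function() names(.registry())

#' Class descriptor lookup
#'
#' @param class_name registered class name, e.g. `"PC"`.
#' @return A list with `class_name`, `category`, `expected_chain_count`,
#'   `chain_kinds`, the backbone + headgroup `graph`, and a canonical
#'   `example` name.
#' @export
class_descriptor <- function(class_name) {
  reg <- .registry()
  if (!class_name %in% names(reg)) {
    stop("UnknownClass: lipid class '", class_name, "' is not registered",
         call. = FALSE)
  }
  reg[[class_name]]
}
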