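#' @title Lipid shorthand nomenclature
#' @description Parse a curated subset of lipid shorthand nomenclature into
#'   structured objects. Names encode the lipid class, per-chain carbon and
#'   double-bond counts, optional double-bond positions, hydroxyl and other
#'   functional-group suffixes, and the chain separator conventions that
#'   distinguish information levels: a single summed chain (species level,
#'   e.g. `"PC 34:2"`), `"_"`-separated chains of unknown sn position
#'   (molecular species level), `"/"`-separated sn-resolved chains, and
#'   fully double-bond-positioned names (structure-defined level, e.g.
#'   `"FA 18:2(9,12)"`).
#' @name nomenclature
NULL

.LEVELS <- c(species = 1L, molecular_species = 2L, sn_position = 3L,
             structure_defined = 4L)

.FG_NAMES <- c("OH", "oxo", "COOH", "OOH", "NH2")

.parse_error <- function(name, why) {
  stop("UnparseableLipid: cannot parse '", name, "' (", why, ")",
       call. = FALSE)
}

.empty_fg <- function() {
  data.frame(name = character(), position = integer(), count = integer(),
             stringsAsFactors = FALSE)
}

.new_chain <- function(kind, num_carbon, num_db, db_positions = NULL,
                       fgroups = NULL, sn_index = NULL) {
  structure(list(kind = kind, num_carbon = as.integer(num_carbon),
                 num_db = as.integer(num_db),
                 db_positions = if (is.null(db_positions)) NULL
                                else as.integer(db_positions),
                 fgroups = if (is.null(fgroups)) .empty_fg() else fgroups,
                 sn_index = if (is.null(sn_index)) NULL
                            else as.integer(sn_index)),
            class = "carbon_chain")
}

# Parse one functional-group suffix token (the part after a ';').
.parse_fg_token <- function(tok, name) {
  if (grepl("^O[0-9]*$", tok)) {
    n <- sub("^O", "", tok)
    return(list(name = "OH", position = NA_integer_,
                count = if (nzchar(n)) as.integer(n) else 1L))
  }
  if (grepl("^\\(OH\\)[0-9]+$", tok)) {
    return(list(name = "OH", position = NA_integer_,
                count = as.integer(sub("^\\(OH\\)", "", tok))))
  }
  m <- regmatches(tok, regexec("^([0-9]+)?(OH|oxo|COOH|OOH|NH2)$", tok))[[1]]
  if (length(m) == 0L) .parse_error(name, paste0("unknown suffix ';", tok, "'"))
  pos <- if (nzchar(m[2])) as.integer(m[2]) else NA_integer_
  list(name = m[3], position = pos, count = 1L)
}

.parse_chain_token <- function(tok, kind, name, allow_pseudo) {
  m <- regmatches(tok, regexec(
    "^(?:(O|P)-)?([0-9]+):([0-9]+)(\\(([^)]*)\\))?((?:;[^;]+)*)$", tok))[[1]]
  if (length(m) == 0L) .parse_error(name, paste0("malformed chain '", tok, "'"))
  if (nzchar(m[2])) {
    kind <- if (m[2] == "O") "alkyl_ether" else "alkenyl_ether"
  }
  nc <- as.integer(m[3]); nd <- as.integer(m[4])
  if (nc < 1L) .parse_error(name, "chain must have at least one carbon")
  dbp <- NULL
  if (nzchar(m[5])) {
    if (kind == "pseudo_species") {
      .parse_error(name, "double-bond positions are not valid on a summed species-level chain")
    }
    toks <- strsplit(m[6], ",", fixed = TRUE)[[1]]
    dbp <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", trimws(toks))))
    if (anyNA(dbp)) .parse_error(name, "malformed double-bond positions")
    if (length(dbp) != nd) {
      .parse_error(name, "number of double-bond positions does not equal the double-bond count")
    }
    if (is.unsorted(dbp, strictly = TRUE) || any(dbp < 2L) || any(dbp > nc - 1L)) {
      .parse_error(name, "double-bond positions must be strictly increasing within [2, C-1]")
    }
  }
  fgroups <- .empty_fg()
  if (nzchar(m[7])) {
    toks <- strsplit(sub("^;", "", m[7]), ";", fixed = TRUE)[[1]]
    fglist <- lapply(toks, .parse_fg_token, name = name)
    fgroups <- do.call(rbind, lapply(fglist, as.data.frame))
    # canonical form: pool repeated unpositioned groups of the same name
    key <- paste(fgroups$name, fgroups$position)
    if (anyDuplicated(key)) {
      fgroups <- do.call(rbind, lapply(split(fgroups, key), function(g) {
        g$count[1L] <- sum(g$count)
        g[1L, , drop = FALSE]
      }))
      rownames(fgroups) <- NULL
    }
  }
  .new_chain(kind, nc, nd, dbp, fgroups)
}

# Split "PC O-16:0/18:1" into the registered class name and the chain string.
# Longest class names match first, so "PC O-" wins over "PC" and digits inside
# class names ("Hex2Cer") are unambiguous.
.split_class <- function(name) {
  reg <- names(.registry())
  for (cl in reg[order(-nchar(reg))]) {
    if (grepl("-$", cl)) {                    # ether classes: "PC O-16:0..."
      if (startsWith(name, cl)) {
        return(list(class_name = cl,
                    chains = trimws(substring(name, nchar(cl) + 1L))))
      }
    } else {
      if (startsWith(name, paste0(cl, " "))) {
        return(list(class_name = cl,
                    chains = trimws(substring(name, nchar(cl) + 2L))))
      }
      rest <- substring(name, nchar(cl) + 2L) # hyphen dialect: "PC-34:2"
      if (startsWith(name, paste0(cl, "-")) && grepl("^[0-9]", rest)) {
        return(list(class_name = cl, chains = rest))
      }
    }
  }
  NULL
}

#' Parse a lipid shorthand name
#'
#' Parses a name such as `"PC 34:2"`, `"PE 16:0_18:1"`,
#' `"Cer 18:1;O2/24:0"` or `"FA 18:2(9,12)"` into a structured `lipid`
#' object. Whitespace is normalised and common dialect variants (hyphen
#' class separators, `O-`/`P-` ether prefixes, `;OH`/`;O2` hydroxyl
#' suffixes, E/Z stereo-descriptors on double-bond positions) are accepted;
#' stereo descriptors are discarded and only the position integer is kept.
#'
#' @param name lipid name (single character string).
#' @return A `lipid` object with fields `raw_name`, `class_name`,
#'   `category`, `level` (one of `"species"`, `"molecular_species"`,
#'   `"sn_position"`, `"structure_defined"`) and `chains`, a list of
#'   `carbon_chain` objects.
#' @examples
#' parse_lipid("PC 34:2")
#' parse_lipid("FA 18:2(9,12)")
#' parse_lipid("Cer 18:1;O2/24:0")
#' @export
parse_lipid <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  raw <- name
  name <- gsub("[ \t]", " ", trimws(name))
  name <- gsub(" +", " ", name)
  if (!nzchar(name)) .parse_error(raw, "empty name")
  sp <- .split_class(name)
  if (is.null(sp)) .parse_error(raw, "unknown lipid class")
  desc <- class_descriptor(sp$class_name)
  chains_str <- sp$chains
  has_sn <- grepl("/", chains_str, fixed = TRUE)
  has_mol <- grepl("_", chains_str, fixed = TRUE)
  if (has_sn && has_mol) .parse_error(raw, "mixed '/' and '_' chain separators")
  parts <- strsplit(chains_str, "[/_]")[[1]]
  k <- length(parts); ek <- desc$expected_chain_count
  if (k != 1L && k != ek) {
    .parse_error(raw, sprintf("expected %d chain(s) for class %s, found %d",
                              ek, desc$class_name, k))
  }
  if (k == 1L && ek > 1L) {
    # species level: one summed pseudo chain
    chain <- .parse_chain_token(parts[1], "pseudo_species", raw,
                                allow_pseudo = TRUE)
    lipid <- structure(list(raw_name = raw, class_name = desc$class_name,
                            category = desc$category, level = "species",
                            chains = list(chain)), class = "lipid")
    return(lipid)
  }
  chains <- lapply(seq_len(k), function(i) {
    .parse_chain_token(parts[i], desc$chain_kinds[i], raw, allow_pseudo = FALSE)
  })
  if (has_sn) for (i in seq_len(k)) chains[[i]]$sn_index <- i
  n_db_total <- sum(vapply(chains, `[[`, integer(1), "num_db"))
  all_positioned <- all(vapply(chains, function(ch) {
    ch$num_db == 0L || !is.null(ch$db_positions)
  }, logical(1)))
  level <-
    if (n_db_total > 0L && all_positioned && (has_sn || ek == 1L)) {
      "structure_defined"
    } else if (has_sn && ek > 1L) {
      "sn_position"
    } else {
      "molecular_species"
    }
  structure(list(raw_name = raw, class_name = desc$class_name,
                 category = desc$category, level = level, chains = chains),
            class = "lipid")
}

# -- rendering ---------------------------------------------------------------

.render_fg <- function(fg) {
  if (nrow(fg) == 0L) return("")
  ord <- order(fg$name, fg$position, na.last = TRUE)
  fg <- fg[ord, , drop = FALSE]
  toks <- character(0)
  for (i in seq_len(nrow(fg))) {
    nm <- fg$name[i]; pos <- fg$position[i]; cnt <- fg$count[i]
    if (nm == "OH" && is.na(pos)) {
      toks <- c(toks, if (cnt == 1L) "O" else paste0("O", cnt))
    } else {
      base <- if (is.na(pos)) nm else paste0(pos, nm)
      toks <- c(toks, rep(base, cnt))
    }
  }
  paste0(";", paste(toks, collapse = ";"))
}

.render_chain <- function(ch) {
  pos <- if (!is.null(ch$db_positions) && length(ch$db_positions)) {
    paste0("(", paste(ch$db_positions, collapse = ","), ")")
  } else ""
  paste0(ch$num_carbon, ":", ch$num_db, pos, .render_fg(ch$fgroups))
}

#' Canonical name of a lipid
#'
#' @param x a `lipid` object.
#' @param ... ignored.
#' @return Canonical shorthand name (character). Re-parsing a canonical name
#'   yields an equal lipid.
#' @export
format.lipid <- function(x, ...) {
  sep <- if (x$level %in% c("sn_position", "structure_defined") &&
             length(x$chains) > 1L) "/" else "_"
  chains <- paste(vapply(x$chains, .render_chain, character(1)),
                  collapse = sep)
  if (grepl("-$", x$class_name)) paste0(x$class_name, chains)
  else paste(x$class_name, chains)
}

#' @export
print.lipid <- function(x, ...) {
  cat(sprintf("<lipid> %s  [class %s, %s, %s level, %d chain(s)]\n",
              format(x), x$class_name, x$category, x$level,
              length(x$chains)))
  invisible(x)
}

#' @rdname format.lipid
#' @export
lipid_name <- function(x) format.lipid(x)

# -- information levels ------------------------------------------------------

#' Information level utilities
#'
#' `lipid_level_rank()` maps the four information levels to the ladder
#' species < molecular_species < sn_position < structure_defined.
#' `project_to_level()` reduces a lipid to a lower level: projecting to
#' `sn_position` or `molecular_species` drops double-bond and
#' functional-group positions (and the sn assignment for
#' `molecular_species`); projecting to `species` merges all chains into one
#' summed pseudo chain with pooled functional groups.
#'
#' @param level information level name.
#' @export
lipid_level_rank <- function(level) unname(.LEVELS[level])

.pool_fgroups <- function(fg_list) {
  fg <- do.call(rbind, fg_list)
  if (is.null(fg) || nrow(fg) == 0L) return(.empty_fg())
  agg <- stats::aggregate(count ~ name, data = fg, FUN = sum)
  data.frame(name = agg$name, position = NA_integer_, count = agg$count,
             stringsAsFactors = FALSE)
}

#' @rdname lipid_level_rank
#' @param lipid a `lipid` object.
#' @param target target level (at or below the lipid's current level).
#' @export
project_to_level <- function(lipid, target) {
  stopifnot(inherits(lipid, "lipid"), target %in% names(.LEVELS))
  cur <- .LEVELS[lipid$level]; tgt <- .LEVELS[target]
  if (tgt >= cur) return(lipid)
  if (target == "species") {
    ch <- lipid$chains
    pooled <- .new_chain("pseudo_species",
                         sum(vapply(ch, `[[`, integer(1), "num_carbon")),
                         sum(vapply(ch, `[[`, integer(1), "num_db")),
                         db_positions = NULL,
                         fgroups = .pool_fgroups(lapply(ch, `[[`, "fgroups")))
    lipid$chains <- list(pooled)
    lipid$level <- "species"
    return(lipid)
  }
  lipid$chains <- lapply(lipid$chains, function(ch) {
    ch$db_positions <- NULL
    if (nrow(ch$fgroups)) ch$fgroups$position <- NA_integer_
    if (target == "molecular_species") ch$sn_index <- NULL
    ch
  })
  lipid$level <- target
  lipid
}

#' Species-level projection of a lipid
#'
#' Collapses all carbon chains into one summed pseudo chain (carbons and
#' double bonds added, functional groups pooled, double-bond positions
#' dropped). Idempotent.
#'
#' @param lipid a `lipid` object.
#' @return A species-level `lipid`.
#' @examples
#' format(species_level_projection(parse_lipid("PC 18:1/16:0")))  # "PC 34:1"
#' @export
species_level_projection <- function(lipid) project_to_level(lipid, "species")

# Structural equality of two chains at their stated information level.
.chains_identical <- function(a, b) {
  if (a$kind != b$kind || a$num_carbon != b$num_carbon ||
      a$num_db != b$num_db) {
    return(FALSE)
  }
  pa <- a$db_positions; pb <- b$db_positions
  if (is.null(pa) != is.null(pb)) return(FALSE)
  if (!is.null(pa) && !identical(as.integer(pa), as.integer(pb))) return(FALSE)
  fa <- a$fgroups[order(a$fgroups$name, a$fgroups$position), , drop = FALSE]
  fb <- b$fgroups[order(b$fgroups$name, b$fgroups$position), , drop = FALSE]
  if (nrow(fa) != nrow(fb)) return(FALSE)
  all(fa$name == fb$name) && identical(fa$count, fb$count) &&
    identical(is.na(fa$position), is.na(fb$position)) &&
    all(fa$position[!is.na(fa$position)] == fb$position[!is.na(fb$position)])
}
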