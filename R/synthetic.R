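#' @title Synthetic lipidome generator
#' @description Deterministic generator of lipidome tables with controlled
#'   class composition, chain-length/double-bond distributions, planted
#'   group effects and missingness. Per-lipid baseline abundances are drawn
#'   log-uniformly over several orders of magnitude - emulating the dynamic
#'   range of real lipidomics data, which also makes the pooled abundances
#'   conform to Benford's law by construction - and per-sample noise is
#'   lognormal around the baseline.
#' @name synthetic_data
NULL

.DEFAULT_CLASS_MIX <- c(PC = 6L, PE = 5L, TG = 5L, DG = 3L, PS = 3L, PI = 3L,
                        PA = 2L, LPC = 3L, SM = 4L, Cer = 4L, FA = 4L)

#' Simulation configuration
#'
#' @param seed mandatory RNG seed.
#' @param n_samples total number of samples (split as evenly as possible
#'   over the groups).
#' @param n_groups number of sample groups; group labels `G1..Gk` are
#'   attached as the categorical study variable `"group"`.
#' @param classes named integer vector: lipids to generate per class.
#' @param carbon_range per-chain carbon range (even numbers are drawn).
#' @param db_range per-chain double-bond count range.
#' @param sigma lognormal noise, standard deviation on the natural-log
#'   scale (0.5 corresponds to a CV of about 53%).
#' @param planted_effects list of effects, each a list with `group`, either
#'   `lipid` (canonical name) or `class`, and `fold_change` (> 0) and/or
#'   `exclusive = TRUE`. A fold change scales the target lipids in the
#'   given group; an exclusive effect makes them part of that group's
#'   lipidomes only (missing everywhere else), planting a compositional
#'   difference.
#' @param missingness probability in `[0, 1)` that any abundance cell is
#'   missing.
#' @param baseline_decades log10 bounds of the per-lipid baselines
#'   (default `c(2, 8)`: six orders of magnitude).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed, n_samples = 15L, n_groups = 3L,
                              classes = .DEFAULT_CLASS_MIX,
                              carbon_range = c(12L, 22L),
                              db_range = c(0L, 4L), sigma = 0.5,
                              planted_effects = list(), missingness = 0,
                              baseline_decades = c(2, 8)) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_samples >= n_groups, n_groups >= 1L,
            all(classes >= 1L), !is.null(names(classes)),
            all(names(classes) %in% lipid_classes()),
            sigma >= 0, missingness >= 0, missingness < 1,
            diff(baseline_decades) > 0)
  for (eff in planted_effects) {
    stopifnot(!is.null(eff$fold_change) || isTRUE(eff$exclusive),
              is.null(eff$fold_change) || eff$fold_change > 0,
              !is.null(eff$group),
              !is.null(eff$lipid) || !is.null(eff$class))
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 n_groups = as.integer(n_groups), classes = classes,
                 carbon_range = carbon_range, db_range = db_range,
                 sigma = sigma, planted_effects = planted_effects,
                 missingness = missingness,
                 baseline_decades = baseline_decades),
            class = "simulation_config")
}

# run expr with a local RNG state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.random_chain_token <- function(kind, carbon_range, db_range) {
  evens <- seq.int(carbon_range[1L] + carbon_range[1L] %% 2L,
                   carbon_range[2L], by = 2L)
  nc <- evens[sample.int(length(evens), 1L)]
  nd_lo <- db_range[1L]
  nd_hi <- max(nd_lo, min(db_range[2L], (nc - 2L) %/% 3L))
  nd <- sample.int(nd_hi - nd_lo + 1L, 1L) - 1L + nd_lo
  if (kind == "lcb") {
    paste0(nc, ":", nd, ";O2")
  } else {
    paste0(nc, ":", nd)
  }
}

.random_species_name <- function(class_name, carbon_range, db_range) {
  desc <- class_descriptor(class_name)
  toks <- vapply(desc$chain_kinds, .random_chain_token, character(1),
                 carbon_range = carbon_range, db_range = db_range)
  acyl <- desc$chain_kinds %in% c("acyl")
  if (all(acyl) && length(toks) > 1L) toks <- sort(toks)  # canonical order
  sep <- if (desc$chain_kinds[1L] == "lcb" && length(toks) > 1L) "/" else "_"
  body <- paste(toks, collapse = sep)
  if (grepl("-$", class_name)) paste0(class_name, body)
  else paste(class_name, body)
}

#' Random parseable lipid names
#'
#' Draws `n` distinct lipid names across the registered classes, at either
#' molecular-species or species level. Every generated name parses.
#'
#' @param n number of lipids.
#' @param seed RNG seed.
#' @param classes candidate class names (default: a broad mixture across
#'   categories).
#' @param species_fraction fraction of names emitted at the summed species
#'   level.
#' @return character vector of `n` distinct canonical lipid names.
#' @export
random_lipids <- function(n, seed,
                          classes = c("PC", "PE", "PS", "PG", "PI", "PA",
                                      "LPC", "LPE", "PC O-", "PE P-", "TG",
                                      "DG", "MG", "SM", "Cer", "HexCer",
                                      "FA", "CE"),
                          species_fraction = 0.5) {
  .with_seed(seed, {
    out <- character(0)
    guard <- 0L
    while (length(out) < n && guard < 200L * n) {
      guard <- guard + 1L
      cl <- sample(classes, 1L)
      nm <- .random_species_name(cl, c(12L, 22L), c(0L, 4L))
      if (stats::runif(1) < species_fraction) {
        nm <- format(species_level_projection(parse_lipid(nm)))
      } else {
        nm <- format(parse_lipid(nm))
      }
      if (!nm %in% out) out <- c(out, nm)
    }
    if (length(out) < n) stop("could not draw enough distinct lipids")
    out
  })
}

#' Generate a synthetic lipidome table
#'
#' @param config a [simulation_config()].
#' @return a [lipidome_table()] with the group label attached as the
#'   categorical study variable `"group"`. Reproducible: the same
#'   configuration (including seed) yields a bit-identical table.
#' @examples
#' tab <- generate_lipidomes(simulation_config(seed = 1, n_samples = 6,
#'                                             n_groups = 2))
#' dim(tab)
#' @export
generate_lipidomes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, {
    # lipid universe
    names_all <- character(0)
    class_of <- character(0)
    for (cl in names(config$classes)) {
      k <- config$classes[[cl]]
      tries <- 0L
      while (sum(class_of == cl) < k && tries < 500L * k) {
        tries <- tries + 1L
        nm <- format(parse_lipid(.random_species_name(
          cl, config$carbon_range, config$db_range)))
        if (!nm %in% names_all) {
          names_all <- c(names_all, nm)
          class_of <- c(class_of, cl)
        }
      }
      if (sum(class_of == cl) < k) {
        stop("InvalidConfig: cannot draw ", k, " distinct lipids for class ",
             cl, call. = FALSE)
      }
    }
    nlip <- length(names_all)
    m <- config$n_samples
    groups <- paste0("G", rep_len(seq_len(config$n_groups), m))
    groups <- sort(groups)
    sample_names <- sprintf("S%02d", seq_len(m))

    baseline <- 10^stats::runif(nlip, config$baseline_decades[1L],
                                config$baseline_decades[2L])
    fc <- matrix(1, config$n_groups, nlip,
                 dimnames = list(paste0("G", seq_len(config$n_groups)),
                                 names_all))
    absent <- matrix(FALSE, config$n_groups, nlip,
                     dimnames = dimnames(fc))
    for (eff in config$planted_effects) {
      target <- if (!is.null(eff$lipid)) {
        which(names_all == format(parse_lipid(eff$lipid)))
      } else {
        which(class_of == eff$class)
      }
      if (length(target) == 0L) {
        stop("InvalidConfig: planted effect matches no lipid", call. = FALSE)
      }
      if (!is.null(eff$fold_change)) {
        fc[eff$group, target] <- fc[eff$group, target] * eff$fold_change
      }
      if (isTRUE(eff$exclusive)) {
        absent[rownames(absent) != eff$group, target] <- TRUE
      }
    }
    ab <- matrix(NA_real_, m, nlip, dimnames = list(sample_names, names_all))
    for (s in seq_len(m)) {
      ab[s, ] <- baseline * fc[groups[s], ] *
        exp(stats::rnorm(nlip, 0, config$sigma))
      ab[s, absent[groups[s], ]] <- NA_real_
    }
    if (config$missingness > 0) {
      drop <- stats::runif(length(ab)) < config$missingness
      ab[drop] <- NA_real_
    }
    lipidome_table(ab, data.frame(group = groups, row.names = sample_names,
                                  stringsAsFactors = FALSE))
  })
}
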