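# Enumeration of the constrained candidate space: sn assignments, hydroxyl
# positions and C=C positions for a species- or molecular-species query.
#
# The space is deliberately restricted to double-bond positions known in
# lipid biology: a curated per-chain-length table of monounsaturation
# positions, the omega-3/6/9 rule, methylene-interrupted n-3/n-6/n-9 PUFA
# families, and the delta-4/8/14 sphingoid set. The engine ranks candidates
# within this space; it is not designed to discover new positions.

# Curated monounsaturation delta positions per chain length (common
# mammalian MUFAs as drawn in glycerophospholipid structure databases).
# User-overridable through candidate_config(). The omega rule adds
# carbons - 3/6/9 on top of these.
.MUFA_CURATED <- list(
  "14" = 9L, "15" = 9L, "16" = 9L, "17" = 9L, "18" = c(9L, 11L),
  "19" = c(9L, 11L), "20" = c(9L, 11L), "22" = 13L, "24" = 15L, "26" = 17L
)

#' Configuration of the candidate chemical space
#'
#' @param mufa_curated named list: chain length (as character) to integer
#'   vector of curated monounsaturation delta positions.
#' @param omega_families omega offsets included as potential
#'   monounsaturation / polyunsaturation families (default 3, 6, 9).
#' @param sphingoid_set delta positions considered on sphingoid bases
#'   (default 4, 8, 14; the unusual delta-6 is excluded).
#' @param max_candidates combinatorial cap per query; enumeration past the
#'   cap is truncated with a warning.
#' @param config_file optional plain-text file overriding `mufa_curated`;
#'   two whitespace-separated columns: chain length, comma-separated
#'   positions.
#' @return a list of class `candidate_config`.
#' @export
candidate_config <- function(mufa_curated = .MUFA_CURATED,
                             omega_families = c(3L, 6L, 9L),
                             sphingoid_set = c(4L, 8L, 14L),
                             max_candidates = 10000L,
                             config_file = NULL) {
  if (!is.null(config_file)) {
    tab <- utils::read.table(config_file, header = FALSE,
                             col.names = c("carbons", "positions"),
                             colClasses = "character")
    mufa_curated <- stats::setNames(
      lapply(strsplit(tab$positions, ","), as.integer), tab$carbons)
  }
  structure(list(mufa_curated = mufa_curated,
                 omega_families = as.integer(omega_families),
                 sphingoid_set = as.integer(sphingoid_set),
                 max_candidates = as.integer(max_candidates)),
            class = "candidate_config")
}

#' Candidate delta positions for a monounsaturated chain
#'
#' Union of the curated positions for that chain length and the
#' omega-3/6/9 positions (delta = carbons - 3/6/9), deduplicated and
#' ascending. Delta-8 of an 18:1 chain, for example, is deliberately not
#' part of the space.
#'
#' @param chain_carbons chain length (>= 4).
#' @param config a [candidate_config()].
#' @return integer vector of delta positions (possibly empty).
#' @export
mufa_positions <- function(chain_carbons, config = candidate_config()) {
  chain_carbons <- as.integer(chain_carbons)
  if (chain_carbons < 4L) return(integer(0))
  curated <- config$mufa_curated[[as.character(chain_carbons)]]
  omega <- chain_carbons - config$omega_families
  pos <- sort(unique(c(curated, omega)))
  pos[pos >= 2L & pos <= chain_carbons - 1L]
}

#' Methylene-interrupted PUFA position series
#'
#' For a chain of `chain_carbons` carbons with `double_bonds` >= 2 double
#' bonds, returns one candidate position list per omega family (n-3, n-6,
#' n-9): an arithmetic sequence with step 3 whose last bond sits at
#' delta = carbons - family. Families whose first position would fall below
#' delta 2 are omitted.
#'
#' @param chain_carbons chain length.
#' @param double_bonds number of double bonds (>= 2).
#' @param config a [candidate_config()].
#' @return list of integer vectors, named by omega family (`"n-3"`, ...).
#' @examples
#' pufa_series(22, 6) # n-3 family: 4,7,10,13,16,19
#' @export
pufa_series <- function(chain_carbons, double_bonds,
                        config = candidate_config()) {
  n <- as.integer(chain_carbons)
  d <- as.integer(double_bonds)
  if (d < 2L) stop("pufa_series expects at least two double bonds")
  out <- list()
  for (fam in config$omega_families) {
    start <- n - fam - 3L * (d - 1L)
    if (start < 2L) next
    out[[paste0("n-", fam)]] <- start + 3L * (0:(d - 1L))
  }
  out
}

#' Candidate double-bond position sets for a sphingoid base
#'
#' Subsets of the delta 4/8/14 reference set of the requested size; a
#' singly unsaturated base is fixed at delta 4.
#'
#' @param double_bonds 0 to 3.
#' @param config a [candidate_config()].
#' @return list of integer vectors (one per candidate position set).
#' @export
sphingoid_positions <- function(double_bonds, config = candidate_config()) {
  d <- as.integer(double_bonds)
  if (d == 0L) return(list(integer(0)))
  if (d == 1L) return(list(4L))
  if (d > length(config$sphingoid_set)) {
    warning("no sphingoid candidates for ", d, " double bonds")
    return(list())
  }
  sets <- utils::combn(config$sphingoid_set, d, simplify = FALSE)
  Filter(function(p) all(diff(p) >= 2L), sets)
}

# Candidate (positions, provenance) pairs for one chain. provenance 1 =
# curated/LIPID-MAPS-listed, 2 = omega rule / PUFA family.
.chain_db_candidates <- function(chain, config) {
  if (chain$db == 0L) {
    return(list(list(pos = integer(0), prov = 1L)))
  }
  if (!is.null(chain$db_positions)) {
    return(list(list(pos = chain$db_positions, prov = 1L)))
  }
  if (chain$kind == "sphingoid") {
    sets <- sphingoid_positions(chain$db, config)
    return(lapply(sets, function(p) list(pos = p, prov = 1L)))
  }
  if (chain$db == 1L) {
    curated <- config$mufa_curated[[as.character(chain$carbons)]]
    pos <- mufa_positions(chain$carbons, config)
    return(lapply(pos, function(p) {
      list(pos = p, prov = if (p %in% curated) 1L else 2L)
    }))
  }
  sets <- pufa_series(chain$carbons, chain$db, config)
  lapply(sets, function(p) list(pos = p, prov = 2L))
}

# Standard hydroxyl positions on a sphingoid base: the 1-O is the head
# attachment; di-hydroxy bases carry 1,3 and tri-hydroxy 1,3,4.
.sphingoid_oh_positions <- function(oh) {
  switch(as.character(oh),
         "0" = integer(0), "1" = 1L, "2" = c(1L, 3L), "3" = c(1L, 3L, 4L),
         stop("unsupported sphingoid hydroxyl count: ", oh))
}

# distinct orderings of the chain bag over the sn slots
.sn_permutations <- function(chains) {
  n <- length(chains)
  if (n == 1L) return(list(chains))
  idx <- .permutations(n)
  keys <- vapply(idx, function(ix) {
    paste(vapply(chains[ix], .format_chain, character(1)), collapse = "|")
  }, character(1))
  lapply(idx[!duplicated(keys)], function(ix) chains[ix])
}

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in .permutations(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, (seq_len(n)[-i])[rest])
    }
  }
  out
}

# chain splits for a species-level query (diacyl assumption: two chains,
# even carbon counts, each 10..30 carbons)
.species_splits <- function(total_c, total_db, nslots) {
  if (nslots != 2L) {
    stop("species-level enumeration is supported for two-chain subclasses")
  }
  out <- list()
  for (c1 in seq(10L, min(30L, total_c - 10L), by = 2L)) {
    c2 <- total_c - c1
    if (c2 < c1 || c2 > 30L) next
    for (d1 in 0:total_db) {
      d2 <- total_db - d1
      if (c1 == c2 && d1 > d2) next
      out[[length(out) + 1L]] <- list(c(c1, d1), c(c2, d2))
    }
  }
  out
}

#' Enumerate fully resolved candidate structures for a query
#'
#' Cartesian expansion of sn-slot permutations, per-chain double-bond
#' position candidates and hydroxyl positions, restricted to the curated
#' chemical space, deduplicated, and deterministically ordered: curated
#' positions before omega-rule/PUFA-family positions, then ascending
#' positions, then sn order.
#'
#' @param query a `lipid_structure` (or shorthand string) at species or
#'   molecular species level. Fully resolved parts of the query (assigned
#'   sn slots, given double-bond positions) are kept fixed.
#' @param config a [candidate_config()].
#' @return an object of class `candidate_set`: list with `query` and
#'   `candidates` (list of resolved `lipid_structure`s with a
#'   `provenance` attribute each).
#' @export
enumerate_candidates <- function(query, config = candidate_config()) {
  if (is.character(query)) query <- parse_lipid_name(query)
  def <- .subclass_def(query$subclass)
  chain_sets <- list()
  if (!is.null(query$species_totals)) {
    t <- query$species_totals
    for (split in .species_splits(t$carbons, t$db, length(def$slots))) {
      chain_sets[[length(chain_sets) + 1L]] <-
        lapply(split, function(cd) acyl_chain(cd[1], cd[2]))
    }
  } else {
    chain_sets <- list(query$chains)
  }
  cap_hit <- FALSE
  out <- list()
  for (chains in chain_sets) {
    arrangements <- if (query$sn_assigned) list(chains) else
      .sn_permutations(chains)
    lyso_sns <- if (identical(def$sn_rule, "lyso") && !query$sn_assigned) {
      c(1L, 2L)
    } else if (identical(def$sn_rule, "lyso")) query$lyso_sn else 1L
    for (arr in arrangements) {
      percand <- lapply(arr, .chain_db_candidates, config = config)
      grid <- .cartesian(lapply(percand, seq_along))
      for (combo in grid) {
        resolved <- arr
        prov <- 1L
        for (i in seq_along(arr)) {
          pick <- percand[[i]][[combo[i]]]
          resolved[[i]]$db_positions <- pick$pos
          if (resolved[[i]]$kind == "sphingoid" && resolved[[i]]$oh > 0L) {
            resolved[[i]]$oh_positions <- .sphingoid_oh_positions(resolved[[i]]$oh)
          }
          prov <- max(prov, pick$prov)
        }
        for (lsn in lyso_sns) {
          if (length(out) >= config$max_candidates) {
            cap_hit <- TRUE
            break
          }
          cand <- lipid_structure(query$subclass, resolved, sn_assigned = TRUE,
                                  lyso_sn = lsn)
          attr(cand, "provenance") <-
            c("curated", "omega-rule")[prov]
          out[[length(out) + 1L]] <- cand
        }
      }
    }
  }
  if (cap_hit) {
    warning("candidate enumeration truncated at ", config$max_candidates)
  }
  # deduplicate on the formatted name, then deterministic ordering
  nm <- vapply(out, format_lipid_name, character(1))
  keep <- !duplicated(nm)
  out <- out[keep]
  nm <- nm[keep]
  prov <- vapply(out, function(x) attr(x, "provenance"), character(1))
  poskey <- vapply(out, function(x) {
    paste(sprintf("%02d", unlist(lapply(x$chains, `[[`, "db_positions"))),
          collapse = ",")
  }, character(1))
  ord <- order(match(prov, c("curated", "omega-rule")), poskey, nm)
  structure(list(query = query, candidates = out[ord]),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> query:", format_lipid_name(x$query), "->",
      length(x$candidates), "candidates\n")
  for (cand in utils::head(x$candidates, 20L)) {
    cat("  ", format_lipid_name(cand), "\n")
  }
  if (length(x$candidates) > 20L) cat("  ...\n")
  invisible(x)
}

.cartesian <- function(lists) {
  if (!length(lists)) return(list(integer(0)))
  grid <- do.call(expand.grid, c(lists, KEEP.OUT.ATTRS = FALSE))
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}
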