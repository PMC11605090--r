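# Lipid shorthand parsing, subclass registry, and precursor m/z.
#
# A lipid is modelled as a subclass-specific polar "head" formula (the
# backbone with free hydroxyl/amino attachment sites) plus one chain
# contribution per attached chain:
#   acyl / N-acyl : Cn H(2n-2-2d) O(1+oh)   (fatty acid minus H2O)
#   alkyl  (O-)   : Cn H(2n-2d)   O(oh)     (ether-linked)
#   alkenyl (P-)  : Cn H(2n-2-2d) O(oh)     (vinyl-ether, plasmalogen)
#   sphingoid     : Cn H(2n+3-2d) N O(oh)   (free long-chain base)
# Double-bond positions are delta positions counted from the carbonyl /
# C1 amino carbon; the bond sits between carbons p and p+1.

# ---- subclass registry -----------------------------------------------------
# head: neutral backbone formula; slots: chain slot names; kinds: chain kind
# per slot; class_*: subclass diagnostic ions (cation formulas) and neutral
# losses required / optional for the class score; sn_rule: which sn-position
# rule applies; chain_rule: how chain-level diagnostics are built.
.SUBCLASS <- local({
  gp <- function(head, class_ion = NULL, class_nl = NULL, slots = c("sn1", "sn2"),
                 kinds = c("acyl", "acyl"), sn_rule = "none",
                 chain_rule = "nl_fa", category = "GP", opt_ions = NULL) {
    list(category = category, head = head, slots = slots, kinds = kinds,
         class_ion = class_ion, class_nl = class_nl, opt_ions = opt_ions,
         sn_rule = sn_rule, chain_rule = chain_rule, class_mode = "all")
  }
  pc_ion <- "C5H15NO4P"                      # phosphocholine head, m/z 184.073
  pc_opt <- c("C8H19NO4P", "C7H17NO5P")      # head + C3H4, head + C2H2O
  sp <- function(head, class_nl = NULL, class_ion = NULL, opt_ions = NULL) {
    list(category = "SP", head = head, slots = c("sphingoid", "nacyl"),
         kinds = c("sphingoid", "nacyl"), class_ion = class_ion,
         class_nl = class_nl, opt_ions = opt_ions,
         sn_rule = "none", chain_rule = "sp", class_mode = "all")
  }
  list(
    # glycerophospholipids (15 in-depth subclasses)
    "PC"    = gp("C8H20NO6P", class_ion = pc_ion, opt_ions = pc_opt, sn_rule = "pc_sn1"),
    "PC O-" = gp("C8H20NO6P", class_ion = pc_ion, opt_ions = pc_opt,
                 kinds = c("alkyl", "acyl"), sn_rule = "pc_sn1"),
    "PC P-" = gp("C8H20NO6P", class_ion = pc_ion, opt_ions = pc_opt,
                 kinds = c("alkenyl", "acyl"), sn_rule = "pc_sn1"),
    "LPC"   = gp("C8H20NO6P", class_ion = pc_ion, opt_ions = pc_opt,
                 slots = "sn1", kinds = "acyl", sn_rule = "lyso", chain_rule = "none"),
    "PE"    = gp("C5H14NO6P", class_nl = "C2H8NO4P"),
    "PE O-" = gp("C5H14NO6P", class_nl = "C2H8NO4P", kinds = c("alkyl", "acyl")),
    "PE P-" = gp("C5H14NO6P", class_nl = "C2H8NO4P", kinds = c("alkenyl", "acyl")),
    "LPE"   = gp("C5H14NO6P", class_nl = "C2H8NO4P", slots = "sn1", kinds = "acyl",
                 sn_rule = "lyso", chain_rule = "none"),
    "PG"    = gp("C6H15O8P", class_nl = "C3H9O6P"),
    "LPG"   = gp("C6H15O8P", class_nl = "C3H9O6P", slots = "sn1", kinds = "acyl",
                 sn_rule = "lyso", chain_rule = "none"),
    "PI"    = gp("C9H19O11P", class_nl = "C6H13O9P"),
    "LPI"   = gp("C9H19O11P", class_nl = "C6H13O9P", slots = "sn1", kinds = "acyl",
                 sn_rule = "lyso", chain_rule = "none"),
    "PS"    = gp("C6H14NO8P", class_nl = "C3H8NO6P"),
    "LPS"   = gp("C6H14NO8P", class_nl = "C3H8NO6P", slots = "sn1", kinds = "acyl",
                 sn_rule = "lyso", chain_rule = "none"),
    "BMP"   = gp("C6H15O8P", class_nl = "C3H9O6P"),
    # sphingolipids (5)
    "SM"      = sp("C5H12NO3P", class_ion = pc_ion, opt_ions = pc_opt),
    "Cer"     = sp("", class_nl = "H2O"),
    "HexCer"  = sp("C6H10O5", class_nl = "C6H10O5"),
    "Hex2Cer" = sp("C12H20O10", class_nl = "C12H20O10"),
    "SHexCer" = sp("C6H10O8S", class_nl = "C6H10O8S"),
    # glycerolipids (7)
    "DG"    = gp("C3H8O3", class_nl = "H2O", category = "GL", sn_rule = "na_sn1"),
    "TG"    = gp("C3H8O3", slots = c("sn1", "sn2", "sn3"),
                 kinds = c("acyl", "acyl", "acyl"), category = "GL",
                 sn_rule = "na_sn1", chain_rule = "nl_fa_class"),
    "DGTS"  = c(gp("C10H21NO5", category = "GL"), list(marker_dominant = "heavy")),
    "DGTA"  = c(gp("C10H21NO5", category = "GL"), list(marker_dominant = "light")),
    "LDGTS" = c(gp("C10H21NO5", category = "GL", slots = "sn1", kinds = "acyl",
                   chain_rule = "none"), list(marker_dominant = "heavy")),
    "LDGTA" = c(gp("C10H21NO5", category = "GL", slots = "sn1", kinds = "acyl",
                   chain_rule = "none"), list(marker_dominant = "light")),
    "CAR"   = gp("C7H15NO3", class_nl = "C3H9N", category = "GL",
                 slots = "sn1", kinds = "acyl", chain_rule = "acylium")
  )
})

#' Supported lipid subclasses
#'
#' @return character vector of the subclass tokens the engine annotates
#'   in depth (15 glycerophospholipid, 5 sphingolipid, 7 glycerolipid
#'   subclasses).
#' @export
supported_subclasses <- function() names(.SUBCLASS)

.subclass_def <- function(subclass) {
  def <- .SUBCLASS[[subclass]]
  if (is.null(def)) {
    stop("unsupported lipid subclass '", subclass, "'; supported: ",
         paste(names(.SUBCLASS), collapse = ", "))
  }
  def
}

# ---- chains ----------------------------------------------------------------

#' Construct an acyl/alkyl/sphingoid chain descriptor
#'
#' @param carbons chain carbon count (>= 1).
#' @param db number of C=C double bonds.
#' @param db_positions optional strictly increasing integer vector of delta
#'   positions (bond between carbons p and p+1, counted from the
#'   carbonyl/amino C1). Length must equal `db`.
#' @param kind one of `"acyl"`, `"alkyl"`, `"alkenyl"`, `"sphingoid"`,
#'   `"nacyl"`.
#' @param oh hydroxyl count on the chain.
#' @param oh_positions optional integer vector of hydroxyl carbon positions.
#' @return an `acyl_chain` object.
#' @export
acyl_chain <- function(carbons, db = 0L, db_positions = NULL, kind = "acyl",
                       oh = 0L, oh_positions = NULL) {
  carbons <- as.integer(carbons)
  db <- as.integer(db)
  if (carbons < 1L) stop("chain must have at least one carbon")
  if (db < 0L || oh < 0L) stop("negative double-bond or hydroxyl count")
  kind <- match.arg(kind, c("acyl", "alkyl", "alkenyl", "sphingoid", "nacyl"))
  if (!is.null(db_positions)) {
    db_positions <- as.integer(sort(db_positions))
    if (length(db_positions) != db) {
      stop("db_positions length (", length(db_positions),
           ") disagrees with double-bond count (", db, ")")
    }
    if (length(db_positions) &&
        (any(db_positions < 1L) || any(db_positions > carbons - 1L))) {
      stop("double-bond position out of range 1..", carbons - 1L)
    }
    if (length(db_positions) > 1L && any(diff(db_positions) < 2L)) {
      stop("double-bond positions must be at least 2 apart")
    }
  }
  if (!is.null(oh_positions)) {
    oh_positions <- as.integer(sort(oh_positions))
    if (length(oh_positions) != oh) {
      stop("oh_positions length disagrees with hydroxyl count")
    }
  }
  structure(list(carbons = carbons, db = db, db_positions = db_positions,
                 kind = kind, oh = as.integer(oh), oh_positions = oh_positions),
            class = "acyl_chain")
}

# Elemental contribution of a chain to the assembled lipid.
chain_formula <- function(chain) {
  n <- chain$carbons; d <- chain$db; oh <- chain$oh
  counts <- switch(chain$kind,
    acyl      = ,
    nacyl     = c(C = n, H = 2 * n - 2 - 2 * d, O = 1 + oh),
    alkyl     = c(C = n, H = 2 * n - 2 * d, O = oh),
    alkenyl   = c(C = n, H = 2 * n - 2 - 2 * d, O = oh),
    sphingoid = c(C = n, H = 2 * n + 3 - 2 * d, N = 1, O = oh)
  )
  chem_formula(counts[counts > 0])
}

# direct monoisotopic mass of a chain contribution (no formula object)
.chain_mass <- function(chain) {
  n <- chain$carbons; d <- chain$db; oh <- chain$oh
  h <- switch(chain$kind,
              acyl = , nacyl = , alkenyl = 2 * n - 2 - 2 * d,
              alkyl = 2 * n - 2 * d,
              sphingoid = 2 * n + 3 - 2 * d)
  o <- switch(chain$kind, acyl = , nacyl = 1 + oh, sphingoid = oh, oh)
  nn <- if (chain$kind == "sphingoid") 1L else 0L
  n * .ATOMIC_MASS[["C"]] + h * .ATOMIC_MASS[["H"]] +
    o * .ATOMIC_MASS[["O"]] + nn * .ATOMIC_MASS[["N"]]
}

.format_chain <- function(chain) {
  pos <- if (!is.null(chain$db_positions) && length(chain$db_positions)) {
    paste0("(", paste(chain$db_positions, collapse = ","), ")")
  } else ""
  ohtag <- if (chain$oh > 0L) {
    if (chain$oh == 1L) ";O" else paste0(";O", chain$oh)
  } else ""
  prefix <- switch(chain$kind, alkyl = "O-", alkenyl = "P-", "")
  paste0(prefix, chain$carbons, ":", chain$db, pos, ohtag)
}

# ---- lipid structure -------------------------------------------------------

.LEVELS <- c("species", "molecular_species", "sn_resolved", "oh_resolved",
             "db_resolved", "sn_db_resolved", "oh_db_resolved")

.structure_level <- function(subclass, chains, sn_assigned, species = FALSE) {
  if (species) return("species")
  def <- .subclass_def(subclass)
  db_ok <- all(vapply(chains, function(ch) {
    ch$db == 0L || !is.null(ch$db_positions)
  }, logical(1)))
  if (def$category == "SP") {
    sph <- chains[[1L]]
    oh_ok <- sph$oh == 0L || !is.null(sph$oh_positions)
    if (oh_ok && db_ok) return("oh_db_resolved")
    if (oh_ok) return("oh_resolved")
    if (db_ok) return("db_resolved")
    return("molecular_species")
  }
  multi <- length(def$slots) > 1L
  sn_ok <- sn_assigned && multi
  lyso <- identical(def$sn_rule, "lyso")
  if (lyso) sn_ok <- sn_assigned   # sn1 vs sn2 attachment of the single chain
  if (sn_ok && db_ok) return("sn_db_resolved")
  if (sn_ok) return("sn_resolved")
  if (db_ok) return("db_resolved")
  "molecular_species"
}

#' Construct a lipid structure
#'
#' @param subclass subclass token, see [supported_subclasses()].
#' @param chains list of [acyl_chain()] objects, in slot order when
#'   `sn_assigned = TRUE`.
#' @param sn_assigned are the chains assigned to their sn-/backbone slots
#'   (the `/` separator) rather than an unresolved bag (`_`)?
#' @param species_totals for species-level structures, a list with `carbons`,
#'   `db` and optionally `oh` totals instead of `chains`.
#' @param lyso_sn for single-chain (lyso) subclasses with `sn_assigned`,
#'   which backbone position carries the chain (1 or 2).
#' @return a `lipid_structure` object with its annotation `level` derived
#'   from how much of the structure is resolved.
#' @export
lipid_structure <- function(subclass, chains = NULL, sn_assigned = FALSE,
                            species_totals = NULL, lyso_sn = 1L) {
  def <- .subclass_def(subclass)
  if (!is.null(species_totals)) {
    s <- structure(list(subclass = subclass, chains = NULL,
                        sn_assigned = FALSE, lyso_sn = NA_integer_,
                        species_totals = species_totals,
                        level = "species"), class = "lipid_structure")
    return(s)
  }
  if (length(chains) != length(def$slots)) {
    stop(subclass, " expects ", length(def$slots), " chain(s), got ",
         length(chains))
  }
  # sphingolipid kinds are fixed by slot; others fixed by subclass table
  for (i in seq_along(chains)) {
    chains[[i]]$kind <- def$kinds[[i]]
  }
  structure(list(subclass = subclass, chains = chains,
                 sn_assigned = isTRUE(sn_assigned),
                 lyso_sn = as.integer(lyso_sn), species_totals = NULL,
                 level = .structure_level(subclass, chains, sn_assigned)),
            class = "lipid_structure")
}

#' @export
print.lipid_structure <- function(x, ...) {
  cat("<lipid_structure> ", format_lipid_name(x), "  [", x$level, "]\n",
      sep = "")
  invisible(x)
}

# totals across chains (species-level collapse)
.species_totals <- function(s) {
  if (!is.null(s$species_totals)) return(s$species_totals)
  list(carbons = sum(vapply(s$chains, `[[`, integer(1), "carbons")),
       db = sum(vapply(s$chains, `[[`, integer(1), "db")),
       oh = sum(vapply(s$chains, `[[`, integer(1), "oh")))
}

# ---- shorthand parsing -----------------------------------------------------

.parse_chain_token <- function(tok, full) {
  orig <- tok
  kind <- "acyl"
  if (startsWith(tok, "O-")) { kind <- "alkyl"; tok <- substring(tok, 3) }
  if (startsWith(tok, "P-")) { kind <- "alkenyl"; tok <- substring(tok, 3) }
  oh <- 0L
  m <- regexpr(";O([0-9]*)", tok)
  if (m > 0L) {
    ohs <- sub("^;O", "", regmatches(tok, m))
    oh <- if (nzchar(ohs)) as.integer(ohs) else 1L
    tok <- sub(";O[0-9]*", "", tok)
  }
  pos <- NULL
  m <- regexpr("\\(([^)]*)\\)", tok)
  if (m > 0L) {
    inner <- gsub("[EZ]", "", sub("^\\(", "", sub("\\)$", "", regmatches(tok, m))))
    pos <- suppressWarnings(as.integer(strsplit(inner, ",")[[1]]))
    if (anyNA(pos)) {
      stop("parse error in chain '", orig, "' of '", full,
           "': bad double-bond position list")
    }
    tok <- sub("\\([^)]*\\)", "", tok)
  }
  if (!grepl("^[0-9]+:[0-9]+$", tok)) {
    stop("parse error in chain '", orig, "' of '", full,
         "': expected <carbons>:<double bonds>")
  }
  cd <- as.integer(strsplit(tok, ":")[[1]])
  acyl_chain(cd[1], cd[2], db_positions = pos, kind = kind, oh = oh)
}

#' Parse a lipid shorthand name
#'
#' Understands the shorthand-nomenclature conventions used in lipidomics:
#' `/` separates sn-assigned chains, `_` an unresolved chain bag,
#' parenthesised lists give delta double-bond positions (E/Z letters are
#' accepted and ignored), and `;O`/`;On` gives the hydroxyl count. Ether
#' chains use the `O-`/`P-` prefix, e.g. `"PC O-16:0/18:1"`.
#'
#' @param text e.g. `"PC 16:0/18:1(9)"`, `"PC 16:0_20:4"`,
#'   `"Cer 18:1;O2/16:0"`, `"PC 34:1"`.
#' @return a [lipid_structure()].
#' @examples
#' parse_lipid_name("PC 16:0/18:1(9)")
#' parse_lipid_name("Cer 18:1;O2/16:0")
#' @export
parse_lipid_name <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) stop("empty lipid name")
  sp <- regexpr(" ", text)
  if (sp < 0L) stop("parse error in '", text, "': no chain descriptor")
  subclass <- substring(text, 1L, sp - 1L)
  rest <- trimws(substring(text, sp + 1L))
  # ether prefix on the first chain selects the O-/P- subclass variant
  base <- subclass
  if (grepl("^O-", rest) && (paste0(subclass, " O-") %in% names(.SUBCLASS))) {
    base <- paste0(subclass, " O-")
  } else if (grepl("^P-", rest) && (paste0(subclass, " P-") %in% names(.SUBCLASS))) {
    base <- paste0(subclass, " P-")
  }
  def <- .subclass_def(base)
  sn_assigned <- grepl("/", rest, fixed = TRUE)
  toks <- strsplit(rest, "[/_]")[[1]]
  if (sn_assigned && grepl("_", rest, fixed = TRUE)) {
    stop("parse error in '", text, "': mixed '/' and '_' separators")
  }
  # lyso written with an explicit 0:0 slot, e.g. "LPC 0:0/18:1"
  lyso_sn <- 1L
  if (identical(def$sn_rule, "lyso") && length(toks) == 2L) {
    zero <- vapply(toks, function(t) grepl("^0:0$", t), logical(1))
    if (sum(zero) != 1L) {
      stop("parse error in '", text, "': lyso subclass expects one chain")
    }
    lyso_sn <- if (zero[[1L]]) 2L else 1L
    toks <- toks[!zero]
  }
  if (length(toks) == 1L && length(def$slots) > 1L) {
    ch <- .parse_chain_token(toks[[1L]], text)
    return(lipid_structure(base, species_totals = list(
      carbons = ch$carbons, db = ch$db, oh = ch$oh)))
  }
  chains <- lapply(toks, .parse_chain_token, full = text)
  lipid_structure(base, chains, sn_assigned = sn_assigned, lyso_sn = lyso_sn)
}

#' Format a lipid structure as shorthand
#'
#' Companion formatter to [parse_lipid_name()]; `parse(format(x))`
#' round-trips every supported structure.
#' @param s a `lipid_structure`.
#' @return shorthand string.
#' @export
format_lipid_name <- function(s) {
  base <- sub(" [OP]-$", "", s$subclass)
  if (!is.null(s$species_totals)) {
    t <- s$species_totals
    ohtag <- if (!is.null(t$oh) && t$oh > 0L) paste0(";O", t$oh) else ""
    return(paste0(base, " ", t$carbons, ":", t$db, ohtag))
  }
  def <- .subclass_def(s$subclass)
  sep <- if (s$sn_assigned || def$category == "SP") "/" else "_"
  toks <- vapply(s$chains, .format_chain, character(1))
  if (identical(def$sn_rule, "lyso") && s$sn_assigned && s$lyso_sn == 2L) {
    toks <- c("0:0", toks)
  }
  paste0(base, " ", paste(toks, collapse = sep))
}

# ---- precursor -------------------------------------------------------------

#' Neutral elemental formula of a lipid structure
#'
#' Head-group backbone plus the contribution of every chain.
#' @param s a `lipid_structure` resolved at least to the molecular species
#'   level (chains known).
#' @return a `chem_formula`.
#' @export
lipid_formula <- function(s) {
  def <- .subclass_def(s$subclass)
  if (is.null(s$chains)) {
    stop("species-level structure '", format_lipid_name(s),
         "' has no resolved chains; cannot assemble a formula without them")
  }
  f <- chem_formula(def$head)
  for (ch in s$chains) f <- formula_add(f, chain_formula(ch))
  f
}

#' Precursor m/z of a lipid under an adduct
#'
#' @param s a `lipid_structure` (or shorthand string) with known chains.
#' @param adduct adduct name or object, e.g. `"[M+H]+"`.
#' @return m/z in Da, electron-mass corrected.
#' @examples
#' precursor_mz("PC 18:2/18:2", "[M+H]+") # 782.5694
#' @export
precursor_mz <- function(s, adduct = "[M+H]+") {
  if (is.character(s)) s <- parse_lipid_name(s)
  ad <- .as_adduct(adduct)
  if (ad$charge < 0L) {
    stop("negative-mode adducts are not supported for ", s$subclass)
  }
  adduct_mz(.neutral_mass(s), ad)
}

# neutral monoisotopic mass, bypassing formula-object arithmetic
.neutral_mass <- function(s) {
  def <- .subclass_def(s$subclass)
  if (is.null(s$chains)) {
    stop("species-level structure '", format_lipid_name(s),
         "' has no resolved chains; cannot assemble a formula without them")
  }
  monoisotopic_mass(def$head) +
    sum(vapply(s$chains, .chain_mass, numeric(1)))
}
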