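# Elemental-formula arithmetic and monoisotopic mass computation.

# CODATA/IUPAC monoisotopic atomic masses (Da), 6+ d.p.
.ATOMIC_MASS <- c(
  C  = 12.000000,
  H  = 1.00782503,
  N  = 14.00307401,
  O  = 15.99491462,
  P  = 30.97376200,
  S  = 31.97207117,
  Na = 22.98976928,
  K  = 38.96370649,
  Li = 7.01600344
)

.mass_cache <- new.env(parent = emptyenv())

#' Mass of the electron in Da
#'
#' Used to correct the mass of charged species: a cation is lighter than the
#' sum of its atoms by one electron mass per positive charge.
#' @export
ELECTRON_MASS <- 0.00054858

# Mass of a proton (H minus one electron), the [M+H]+ shift.
PROTON_MASS <- .ATOMIC_MASS[["H"]] - ELECTRON_MASS

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector of element counts with a
#' `charge` attribute. Supported elements: C, H, N, O, P, S, Na, K, Li.
#'
#' @param x either a Hill-style formula string such as `"C9H18NO4"` or a
#'   named numeric vector of element counts.
#' @param charge integer charge of the species (signed), default 0.
#' @return an object of class `chem_formula`.
#' @examples
#' chem_formula("C5H15NO4P", charge = 1)
#' @export
chem_formula <- function(x, charge = 0L) {
  if (inherits(x, "chem_formula")) {
    attr(x, "charge") <- as.integer(charge)
    return(x)
  }
  if (is.character(x)) {
    counts <- .parse_formula_string(x)
  } else {
    counts <- x
  }
  counts <- counts[counts != 0]
  if (length(counts)) {
    unknown <- setdiff(names(counts), names(.ATOMIC_MASS))
    if (length(unknown)) {
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    }
    if (any(counts < 0)) {
      stop("negative element count in formula: ",
           paste(names(counts)[counts < 0], collapse = ", "))
    }
    # canonical Hill order: C, H, then alphabetical
    ord <- c("C", "H", sort(setdiff(names(.ATOMIC_MASS), c("C", "H"))))
    counts <- counts[intersect(ord, names(counts))]
  }
  structure(as.integer(counts), names = names(counts),
            charge = as.integer(charge), class = "chem_formula")
}

.parse_formula_string <- function(s) {
  s <- gsub("\\s", "", s)
  if (!nzchar(s)) return(integer(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)
  toks <- regmatches(s, m)[[1]]
  if (sum(attr(m[[1]], "match.length")) != nchar(s)) {
    stop("cannot parse formula string: '", s, "'")
  }
  el <- sub("[0-9]*$", "", toks)
  n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  n[is.na(n)] <- 1L
  counts <- tapply(n, el, sum)
  structure(as.integer(counts), names = names(counts))
}

#' @export
format.chem_formula <- function(x, ...) {
  if (!length(x)) return("")
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  z <- attr(x, "charge")
  cat("<chem_formula> ", format(x),
      if (z != 0) sprintf(" (charge %+d)", z), "\n", sep = "")
  invisible(x)
}

.formula_counts <- function(f) {
  structure(as.integer(f), names = names(f))
}

#' Add two elemental formulas
#'
#' Element-wise addition; charges add.
#' @param a,b `chem_formula` objects (or formula strings).
#' @return a `chem_formula`.
#' @export
formula_add <- function(a, b) {
  a <- chem_formula(a, charge = .charge_of(a))
  b <- chem_formula(b, charge = .charge_of(b))
  els <- union(names(a), names(b))
  ca <- .formula_counts(a)[els]
  cb <- .formula_counts(b)[els]
  ca[is.na(ca)] <- 0L
  cb[is.na(cb)] <- 0L
  chem_formula(structure(ca + cb, names = els),
               charge = attr(a, "charge") + attr(b, "charge"))
}

#' Subtract one elemental formula from another
#'
#' Element-wise subtraction. A negative resulting count is a hard error: a
#' fragment can never contain more of an element than its precursor.
#' @param a,b `chem_formula` objects (or formula strings).
#' @return a `chem_formula`.
#' @export
formula_subtract <- function(a, b) {
  a <- chem_formula(a, charge = .charge_of(a))
  b <- chem_formula(b, charge = .charge_of(b))
  els <- union(names(a), names(b))
  ca <- .formula_counts(a)[els]
  cb <- .formula_counts(b)[els]
  ca[is.na(ca)] <- 0L
  cb[is.na(cb)] <- 0L
  d <- ca - cb
  if (any(d < 0)) {
    stop("formula subtraction yields negative count for: ",
         paste(els[d < 0], collapse = ", "))
  }
  chem_formula(structure(d, names = els),
               charge = attr(a, "charge") - attr(b, "charge"))
}

.charge_of <- function(x) {
  z <- attr(x, "charge")
  if (is.null(z)) 0L else z
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of monoisotopic atomic masses minus `charge` electron masses, so the
#' value for a singly charged cation is directly its m/z.
#'
#' @param formula a `chem_formula`, or a formula string such as `"C9H18NO4"`.
#' @param charge charge override; defaults to the charge carried by
#'   `formula` (0 for a plain string).
#' @return mass in Da (m/z for |charge| = 1).
#' @examples
#' monoisotopic_mass("C5H15NO4P", charge = 1) # 184.073, the PC head ion
#' @export
monoisotopic_mass <- function(formula, charge = NULL) {
  if (is.character(formula)) {
    z <- if (is.null(charge)) 0L else as.integer(charge)
    key <- paste0(formula, "#", z)
    hit <- .mass_cache[[key]]
    if (!is.null(hit)) return(hit)
    f <- .parse_formula_string(formula)
    if (!length(f)) {
      if (z != 0L) stop("charged species must contain at least one atom")
      return(0.0)
    }
    unknown <- setdiff(names(f), names(.ATOMIC_MASS))
    if (length(unknown)) {
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    }
    val <- sum(.ATOMIC_MASS[names(f)] * as.numeric(f)) - z * ELECTRON_MASS
    .mass_cache[[key]] <- val
    return(val)
  }
  f <- chem_formula(formula, charge = if (is.null(charge)) .charge_of(formula) else charge)
  z <- attr(f, "charge")
  if (!length(f)) {
    if (z != 0) stop("charged species must contain at least one atom")
    return(0.0)
  }
  sum(.ATOMIC_MASS[names(f)] * as.numeric(f)) - z * ELECTRON_MASS
}
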