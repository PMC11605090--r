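# Adduct definitions for positive-mode lipid ions.

.ADDUCTS <- list(
  "[M+H]+"      = list(add = "H",   remove = "",    charge = 1L),
  "[M+NH4]+"    = list(add = "NH4", remove = "",    charge = 1L),
  "[M+Na]+"     = list(add = "Na",  remove = "",    charge = 1L),
  "[M+K]+"      = list(add = "K",   remove = "",    charge = 1L),
  "[M+Li]+"     = list(add = "Li",  remove = "",    charge = 1L),
  "[M+H-H2O]+"  = list(add = "H",   remove = "H2O", charge = 1L)
)

#' Look up an adduct definition
#'
#' @param name adduct name, e.g. `"[M+H]+"`, `"[M+NH4]+"`, `"[M+Na]+"`.
#' @return a list with `name`, `shift` (Da, electron-mass corrected) and
#'   `charge`.
#' @export
adduct <- function(name) {
  if (inherits(name, "ead_adduct")) return(name)
  def <- .ADDUCTS[[name]]
  if (is.null(def)) {
    stop("unknown adduct '", name, "'; supported: ",
         paste(names(.ADDUCTS), collapse = ", "))
  }
  shift <- monoisotopic_mass(chem_formula(def$add)) -
    monoisotopic_mass(chem_formula(def$remove)) -
    def$charge * ELECTRON_MASS
  structure(list(name = name, shift = shift, charge = def$charge),
            class = "ead_adduct")
}

#' m/z of an ionized neutral under an adduct
#'
#' @param neutral_mass neutral monoisotopic mass in Da.
#' @param adduct adduct name or object.
#' @return m/z in Da.
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  ad <- .as_adduct(adduct)
  (neutral_mass + ad$shift) / abs(ad$charge)
}

.as_adduct <- function(x) if (inherits(x, "ead_adduct")) x else adduct(x)
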