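# In-silico EAD spectrum generation: charge-remote fragmentation (CRF) ion
# series along every chain, abundance-class labelling around double bonds,
# subclass diagnostic ions, and the rule-based intensity model.
#
# CRF of a chain produces three ions per C-C bond: H-loss, radical and
# H-gain, spaced by one hydrogen-atom mass. For the cleavage between chain
# carbons k and k+1 (k carbons retained on the charged fragment), the
# radical ion is the precursor minus the neutral radical
#   C(n-k) H(2(n-k)+1-2d) O(o)
# where d counts chain double bonds at position >= k (a bond spanning the
# cleavage counts toward the lost part) and o counts chain hydroxyls beyond
# carbon k.

H_ATOM <- 1.00782503

.SERIES <- c("H-loss", "radical", "H-gain")

# intensity triplets (H-loss, radical, H-gain) of the model
.INTENSITY_PROFILE <- list(
  plain        = c(0.5, 1.0, 0.05),
  cc_low       = c(0.25, 0.5, 0.05),
  # at k = p - 2 the H-loss ion is the amplified one (McLafferty-stabilized
  # below the bond), at k = p + 2 the radical (allyl resonance above it)
  hloss_high   = c(4.0, 2.0, 0.05),
  radical_high = c(2.0, 4.0, 0.05)
)
.PUFA_HGAIN_FACTOR <- 4.0

.resolved_chain <- function(chain) {
  if (chain$db > 0L && is.null(chain$db_positions)) {
    stop("chain ", .format_chain(chain),
         " has unresolved double-bond positions")
  }
  chain
}

# neutral radical lost when k carbons are retained (vectorized over k)
.crf_loss_mass <- function(chain, k) {
  n <- chain$carbons
  if (any(k < 1L) || any(k > n - 1L)) {
    stop("cleavage position k = ", paste(k[k < 1L | k > n - 1L], collapse = ","),
         " out of range 1..", n - 1L)
  }
  pos <- chain$db_positions
  d_lost <- vapply(k, function(kk) sum(pos >= kk), integer(1))
  o_lost <- if (is.null(chain$oh_positions)) 0L else
    vapply(k, function(kk) sum(chain$oh_positions >= kk + 1L), integer(1))
  cn <- n - k
  h <- 2L * cn + 1L - 2L * d_lost
  if (any(h < 0L)) stop("inconsistent unsaturation for cleavage at k = ", k)
  cn * .ATOMIC_MASS[["C"]] + h * .ATOMIC_MASS[["H"]] +
    o_lost * .ATOMIC_MASS[["O"]]
}

#' m/z of a single CRF fragment ion
#'
#' @param s a `lipid_structure` (or shorthand) with resolved double-bond
#'   positions on the fragmenting chain.
#' @param adduct adduct name or object.
#' @param chain index (or slot position) of the chain that fragments.
#' @param k carbons retained on the charged fragment (cleavage between
#'   chain carbons k and k+1).
#' @param series `"H-loss"`, `"radical"` or `"H-gain"`.
#' @return m/z in Da.
#' @examples
#' # the H-loss "valley" ion of PC 16:0/18:1(9) at the C9 cleavage
#' crf_fragment_mz("PC 16:0/18:1(9)", "[M+H]+", chain = 2, k = 9, "H-loss")
#' @export
crf_fragment_mz <- function(s, adduct = "[M+H]+", chain, k,
                            series = c("radical", "H-loss", "H-gain")) {
  if (is.character(s)) s <- parse_lipid_name(s)
  series <- match.arg(series)
  ch <- .resolved_chain(s$chains[[chain]])
  radical <- precursor_mz(s, adduct) - .crf_loss_mass(ch, as.integer(k))
  switch(series,
         "radical" = radical,
         "H-loss" = radical - H_ATOM,
         "H-gain" = radical + H_ATOM)
}

#' Abundance classes of the CRF ions of a chain
#'
#' Around each double bond at delta position p the CRF pattern is
#' V-shaped: the ions at the bond itself (k = p) are suppressed
#' (`cc_low`), the H-loss ion two carbons below (k = p - 2) and the
#' radical ion two carbons above (k = p + 2) are amplified
#' (`cc_high_hloss` / `cc_high_radical`). In chains with three or more
#' double bonds, the H-gain ion at the methylene carbon between two
#' methylene-interrupted bonds (k = p + 1 with p + 3 also a bond) is
#' amplified (`cc_pufa_high`). Everything else is `plain`.
#'
#' @param chain an [acyl_chain()] with resolved double-bond positions.
#' @return data.frame with columns `k`, `series`, `class` covering all
#'   3(n-1) CRF ions of the chain.
#' @export
classify_abundance <- function(chain) {
  chain <- .resolved_chain(chain)
  n <- chain$carbons
  grid <- expand.grid(k = seq_len(n - 1L), series = .SERIES,
                      stringsAsFactors = FALSE)
  grid$class <- "plain"
  pos <- chain$db_positions
  set_class <- function(k, series, cls) {
    if (k >= 1L && k <= n - 1L) {
      grid$class[grid$k == k & grid$series == series] <<- cls
    }
  }
  for (p in pos) {
    set_class(p - 2L, "H-loss", "cc_high_hloss")
    set_class(p + 2L, "radical", "cc_high_radical")
  }
  if (chain$db >= 3L) {
    for (p in pos) {
      if ((p + 3L) %in% pos) set_class(p + 1L, "H-gain", "cc_pufa_high")
    }
  }
  # the valley overrides any amplification that lands on the bond itself
  for (p in pos) {
    set_class(p, "H-loss", "cc_low")
    set_class(p, "radical", "cc_low")
  }
  grid
}

# per-k intensity triplet implied by the abundance classes
.chain_intensity <- function(classes) {
  ints <- numeric(nrow(classes))
  for (i in seq_len(nrow(classes))) {
    k <- classes$k[i]
    cls_here <- classes$class[classes$k == k]
    profile <- .INTENSITY_PROFILE$plain
    if (any(cls_here == "cc_low")) profile <- .INTENSITY_PROFILE$cc_low
    if (any(cls_here == "cc_high_hloss")) {
      profile <- pmax(profile, .INTENSITY_PROFILE$hloss_high)
    }
    if (any(cls_here == "cc_high_radical")) {
      profile <- pmax(profile, .INTENSITY_PROFILE$radical_high)
    }
    ints[i] <- profile[match(classes$series[i], .SERIES)]
    if (classes$class[i] == "cc_pufa_high") ints[i] <- .PUFA_HGAIN_FACTOR
  }
  ints
}

# ---- diagnostic ions -------------------------------------------------------

.CH3O <- "CH3O"   # CH2OH radical / backbone CH2 + O, lost in sn diagnostics

.slot_label <- function(def, i) def$slots[[i]]

#' Subclass diagnostic ions of a candidate structure
#'
#' Builds the decision-tree diagnostic ions for the candidate: subclass
#' ("class" role) head-group ions and neutral losses, chain-level ions
#' (neutral loss of each chain, sphingobase ion, acylium), and position
#' ions (neutral loss of sn1 + CH2 from homolytic glycerol C1-C2
#' cleavage for protonated PC; CH2OH loss specific to sn2 lysolipids;
#' hydroxyl-adjacent cleavage ions on sphingoid bases).
#'
#' @param s a `lipid_structure` (or shorthand) with chains resolved.
#' @param adduct adduct name or object.
#' @return data.frame with columns `mz`, `role` (class/chain/position),
#'   `label`, `required` (counts toward its role's score), `expect`
#'   ("present" or "absent": sn1 lysolipids are diagnosed by the absence
#'   of the sn2-specific ion), `intensity` (model intensity).
#' @export
diagnostic_ions <- function(s, adduct = "[M+H]+") {
  if (is.character(s)) s <- parse_lipid_name(s)
  ad <- .as_adduct(adduct)
  def <- .subclass_def(s$subclass)
  neutral <- monoisotopic_mass(lipid_formula(s))
  mh <- neutral + PROTON_MASS      # protonated-fragment reference
  v_mz <- numeric(0); v_role <- character(0); v_label <- character(0)
  v_req <- logical(0); v_exp <- character(0); v_int <- numeric(0)
  add <- function(mz, role, label, required = TRUE, expect = "present",
                  intensity = 1.0) {
    v_mz[length(v_mz) + 1L] <<- mz
    v_role[length(v_role) + 1L] <<- role
    v_label[length(v_label) + 1L] <<- label
    v_req[length(v_req) + 1L] <<- required
    v_exp[length(v_exp) + 1L] <<- expect
    v_int[length(v_int) + 1L] <<- intensity
  }
  # class ions
  if (!is.null(def$marker_dominant)) {
    # betaine-lipid head markers: the isomer pair is told apart by which
    # of the two ions dominates (m/z 204.123 vs 236.149)
    dom <- def$marker_dominant
    add(monoisotopic_mass("C9H18NO4", charge = 1L), "class",
        "marker C9H18NO4", intensity = if (dom == "light") 2.0 else 1.0)
    add(monoisotopic_mass("C10H22NO5", charge = 1L), "class",
        "marker C10H22NO5", intensity = if (dom == "heavy") 2.0 else 1.0)
  }
  for (f in def$class_ion) {
    add(monoisotopic_mass(f, charge = 1L), "class", paste0("head ion ", f),
        intensity = 2.0)
  }
  for (f in def$class_nl) {
    add(mh - monoisotopic_mass(chem_formula(f)), "class",
        paste0("NL of ", f), intensity = 2.0)
  }
  for (f in def$opt_ions) {
    add(monoisotopic_mass(f, charge = 1L), "class",
        paste0("head ion ", f), required = FALSE, intensity = 0.5)
  }
  # chain ions
  if (identical(def$chain_rule, "nl_fa") || identical(def$chain_rule, "nl_fa_class")) {
    for (i in seq_along(s$chains)) {
      ch <- s$chains[[i]]
      lost <- monoisotopic_mass(formula_add(chain_formula(ch), "H2O"))
      add(mh - lost, "chain",
          paste0("NL of ", .slot_label(def, i), "-", .format_chain(ch)))
    }
  } else if (identical(def$chain_rule, "sp")) {
    base <- s$chains[[1L]]
    spb <- monoisotopic_mass(chain_formula(base)) + PROTON_MASS -
      base$oh * monoisotopic_mass(chem_formula("H2O"))
    add(spb, "chain", paste0("sphingobase ion ", .format_chain(base)))
    nacyl <- s$chains[[2L]]
    add(mh - monoisotopic_mass(chain_formula(nacyl)), "chain",
        paste0("NL of N-acyl ", .format_chain(nacyl)))
  } else if (identical(def$chain_rule, "acylium")) {
    ch <- s$chains[[1L]]
    add(monoisotopic_mass(chain_formula(ch)) + PROTON_MASS, "chain",
        paste0("acylium ", .format_chain(ch)))
  }
  # position ions
  if (identical(def$sn_rule, "pc_sn1") && s$sn_assigned &&
      ad$name %in% c("[M+H]+", "[M+Na]+")) {
    sn1 <- s$chains[[1L]]
    lost <- monoisotopic_mass(formula_add(chain_formula(sn1), .CH3O))
    ref <- if (ad$name == "[M+Na]+") precursor_mz(s, ad) else mh
    add(ref - lost, "position",
        paste0("NL of sn1-", .format_chain(sn1), " + CH2"))
  }
  if (identical(def$sn_rule, "lyso") && s$sn_assigned) {
    expect <- if (s$lyso_sn == 2L) "present" else "absent"
    add(mh - monoisotopic_mass(chem_formula(.CH3O)), "position",
        "NL of CH2OH (sn2-specific)", expect = expect)
  }
  if (identical(def$sn_rule, "na_sn1") && s$sn_assigned &&
      identical(ad$name, "[M+Na]+")) {
    sn1 <- s$chains[[1L]]
    lost <- monoisotopic_mass(formula_add(chain_formula(sn1), .CH3O))
    add(precursor_mz(s, ad) - lost, "position",
        paste0("NL of sn1-", .format_chain(sn1), " + CH2 (Na)"))
  }
  if (def$category == "SP") {
    base <- s$chains[[1L]]
    if (!is.null(base$oh_positions)) {
      for (q in base$oh_positions[base$oh_positions >= 2L]) {
        for (k in c(q - 1L, q)) {
          if (k >= 1L && k <= base$carbons - 1L) {
            add(crf_fragment_mz(s, ad, chain = 1L, k = k, series = "radical"),
                "position", paste0("OH-", q, " cleavage at C", k))
          }
        }
      }
    }
  }
  data.frame(mz = v_mz, role = v_role, label = v_label, required = v_req,
             expect = v_exp, intensity = v_int, stringsAsFactors = FALSE)
}

# Is a position-level rule available for this candidate under this adduct?
position_applicable <- function(s, adduct = "[M+H]+") {
  ad <- .as_adduct(adduct)
  def <- .subclass_def(s$subclass)
  if (identical(def$sn_rule, "pc_sn1")) {
    return(ad$name %in% c("[M+H]+", "[M+Na]+"))
  }
  if (identical(def$sn_rule, "lyso")) return(TRUE)
  if (identical(def$sn_rule, "na_sn1")) return(identical(ad$name, "[M+Na]+"))
  if (def$category == "SP") {
    base <- s$chains[[1L]]
    return(!is.null(base$oh_positions) && any(base$oh_positions >= 2L))
  }
  FALSE
}

# ---- full in-silico spectrum ----------------------------------------------

#' Generate the theoretical EAD spectrum of a resolved candidate
#'
#' CRF ion series over all chains with the rule-based intensity model
#' (saturated positions 0.5 / 1 / 0.05 for H-loss / radical / H-gain;
#' suppressed at the double bond; amplified two carbons either side; H-gain
#' factor 4.0 at PUFA methylene positions), plus the subclass diagnostic
#' ions. Peaks closer than `merge_tol` are merged by intensity summation,
#' and ions below `min_mz` (the TOF start mass) are dropped.
#'
#' @param s fully resolved `lipid_structure` (or shorthand).
#' @param adduct adduct name or object.
#' @param min_mz low-mass reporting cutoff in Da.
#' @param merge_tol peak-merging tolerance in Da.
#' @return data.frame of class `insilico_spectrum`, sorted by m/z, with
#'   columns `mz`, `intensity`, `series`, `chain`, `k`, `class`, `label`;
#'   attributes `candidate`, `adduct`, `precursor_mz`.
#' @export
build_insilico_spectrum <- function(s, adduct = "[M+H]+", min_mz = 150,
                                    merge_tol = 1e-4) {
  if (is.character(s)) s <- parse_lipid_name(s)
  ad <- .as_adduct(adduct)
  pre <- precursor_mz(s, ad)
  rows <- list()
  for (ci in seq_along(s$chains)) {
    ch <- .resolved_chain(s$chains[[ci]])
    classes <- classify_abundance(ch)
    classes$intensity <- .chain_intensity(classes)
    radical <- pre - vapply(classes$k, function(k) .crf_loss_mass(ch, k),
                            numeric(1))
    offset <- c("H-loss" = -H_ATOM, "radical" = 0, "H-gain" = H_ATOM)
    classes$mz <- radical + offset[classes$series]
    classes$chain <- ci
    classes$label <- paste0(classes$series, " at ", .format_chain(ch),
                            " C", classes$k)
    rows[[length(rows) + 1L]] <- classes[, c("mz", "intensity", "series",
                                             "chain", "k", "class", "label")]
  }
  diag <- diagnostic_ions(s, ad)
  diag <- diag[diag$expect == "present", , drop = FALSE]
  if (nrow(diag)) {
    rows[[length(rows) + 1L]] <- data.frame(
      mz = diag$mz, intensity = diag$intensity, series = "diagnostic",
      chain = NA_integer_, k = NA_integer_, class = "diagnostic",
      label = diag$label, stringsAsFactors = FALSE)
  }
  pk <- do.call(rbind, rows)
  pk <- pk[pk$mz >= min_mz & pk$mz < pre, , drop = FALSE]
  pk <- pk[order(pk$mz), , drop = FALSE]
  # merge coincident peaks (identical chains double their shared ions)
  if (nrow(pk) > 1L) {
    grp <- cumsum(c(TRUE, diff(pk$mz) > merge_tol))
    merged <- lapply(split(pk, grp), function(g) {
      first <- g[which.max(g$intensity), , drop = FALSE]
      first$intensity <- sum(g$intensity)
      # a merged peak keeps the most informative abundance class
      pref <- c("diagnostic", "cc_pufa_high", "cc_high_hloss",
                "cc_high_radical", "cc_low", "plain")
      first$class <- pref[min(match(g$class, pref))]
      first
    })
    pk <- do.call(rbind, merged)
  }
  rownames(pk) <- NULL
  structure(pk, class = c("insilico_spectrum", "data.frame"),
            candidate = s, adduct = ad$name, precursor_mz = pre)
}
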