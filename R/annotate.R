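# Decision-tree annotation and candidate scoring.
#
# The composite annotation score is
#   total = class + chain + position + double_bond
# with the binary class/chain/position diagnostic scores, and
#   double_bond = reverse dot product + matched peaks percentage
#                 + V-shape bonus + PUFA H-gain bonus
# (maximum 3), giving a maximum total of 6. A total above 4.8 is flagged
# high-confidence.

#' Evaluation context for diagnostics
#'
#' Bundles the noise-filtered spectrum, its minimum peak intensity and the
#' matching tolerance used by every diagnostic evaluation.
#'
#' @param spectrum a raw `centroid_spectrum`.
#' @param tolerance MS2 m/z matching tolerance (Da).
#' @param model a [noise_model()].
#' @return list with `spectrum` (filtered), `min_peak_intensity`,
#'   `tolerance`, `model`.
#' @export
noise_context <- function(spectrum, tolerance = 0.025, model = noise_model()) {
  flt <- apply_noise_model(spectrum, model)
  list(spectrum = flt$spectrum, min_peak_intensity = flt$min_peak_intensity,
       tolerance = tolerance, model = model)
}

.detected <- function(mz, ctx) {
  vapply(mz, is_detected, logical(1), spectrum = ctx$spectrum,
         min_peak_intensity = ctx$min_peak_intensity,
         tolerance = ctx$tolerance, model = ctx$model)
}

#' Evaluate the class / chain / position diagnostic scores
#'
#' Each score is 1 iff every required ion of that role passes the
#' detection rule (and every ion expected absent is indeed not detected).
#' The position score is 0 whenever the subclass/adduct combination
#' offers no practical sn- or OH-position rule.
#'
#' @param candidate resolved `lipid_structure`.
#' @param ctx a [noise_context()].
#' @param adduct adduct name or object.
#' @return list with `class_score`, `chain_score`, `position_score`,
#'   `position_applicable`.
#' @export
evaluate_diagnostics <- function(candidate, ctx, adduct = "[M+H]+") {
  def <- .subclass_def(candidate$subclass)
  d <- diagnostic_ions(candidate, adduct)
  d$hit <- .detected(d$mz, ctx)
  role_pass <- function(role) {
    rows <- d[d$role == role & d$required, , drop = FALSE]
    if (!nrow(rows)) return(NA)
    all(rows$hit[rows$expect == "present"]) &&
      !any(rows$hit[rows$expect == "absent"])
  }
  cls <- role_pass("class")
  chain <- role_pass("chain")
  if (!is.null(def$marker_dominant) && isTRUE(cls)) {
    # marker-ratio rule: the dominant head ion decides DGTS vs DGTA
    light <- d$mz[d$label == "marker C9H18NO4"]
    heavy <- d$mz[d$label == "marker C10H22NO5"]
    il <- .match_library(light, ctx$spectrum, ctx$tolerance)
    ih <- .match_library(heavy, ctx$spectrum, ctx$tolerance)
    cls <- if (def$marker_dominant == "heavy") ih > il else il > ih
  }
  if (identical(def$chain_rule, "nl_fa_class")) {
    # no head-group ion: the subclass is asserted by any chain loss
    chain_rows <- d[d$role == "chain", , drop = FALSE]
    cls <- any(chain_rows$hit)
  }
  if (is.na(cls)) cls <- FALSE
  if (is.na(chain)) chain <- cls   # single-chain species: implied by precursor
  applicable <- position_applicable(candidate, adduct)
  pos <- if (!applicable) FALSE else isTRUE(role_pass("position"))
  list(class_score = as.integer(cls), chain_score = as.integer(chain),
       position_score = as.integer(pos), position_applicable = applicable)
}

#' Double-bond presence check
#'
#' Every expected amplified peak (`cc_high_hloss`, `cc_high_radical`,
#' `cc_pufa_high`) of a candidate must be detected; for a chain
#' predicting more than five amplified peaks (three or more double
#' bonds) exactly one may be missing.
#'
#' @param candidate resolved `lipid_structure`.
#' @param ctx a [noise_context()].
#' @param adduct adduct name or object.
#' @param min_mz low-mass cutoff; expected peaks below it are not required.
#' @return logical pass/fail.
#' @export
cc_presence_check <- function(candidate, ctx, adduct = "[M+H]+",
                              min_mz = 150) {
  for (ci in seq_along(candidate$chains)) {
    ch <- candidate$chains[[ci]]
    if (ch$db == 0L) next
    classes <- classify_abundance(ch)
    high <- classes[classes$class %in% c("cc_high_hloss", "cc_high_radical",
                                         "cc_pufa_high"), , drop = FALSE]
    if (!nrow(high)) next
    pre <- precursor_mz(candidate, adduct)
    offset <- c("H-loss" = -H_ATOM, "radical" = 0, "H-gain" = H_ATOM)
    mzs <- pre - .crf_loss_mass(ch, high$k) + offset[high$series]
    mzs <- mzs[mzs >= min_mz]
    if (!length(mzs)) next
    missing <- sum(!.detected(mzs, ctx))
    allowance <- if (length(mzs) > 5L) 1L else 0L
    if (missing > allowance) return(FALSE)
  }
  TRUE
}

# match each library peak to the nearest experimental peak within tol;
# returns experimental intensity per library peak (0 when unmatched)
.match_library <- function(lib_mz, exp, tol) {
  if (!nrow(exp$peaks)) return(rep(0, length(lib_mz)))
  vapply(lib_mz, function(m) {
    d <- abs(exp$peaks$mz - m)
    i <- which.min(d)
    if (d[i] <= tol) exp$peaks$intensity[i] else 0
  }, numeric(1))
}

#' Reverse dot product similarity
#'
#' Cosine similarity computed only over the library (in-silico) peaks,
#' with square-root intensity weighting; unmatched library peaks
#' contribute zero. Equals 1 for proportional spectra and 0 with no
#' overlap.
#'
#' @param experimental `centroid_spectrum`.
#' @param library_peaks data.frame with `mz`, `intensity` (the in-silico
#'   acyl-chain CRF subset).
#' @param tolerance matching tolerance (Da).
#' @return similarity in \[0, 1\].
#' @export
reverse_dot_product <- function(experimental, library_peaks,
                                tolerance = 0.025) {
  if (!nrow(library_peaks)) stop("empty in-silico library subset")
  if (!nrow(experimental$peaks)) return(0)
  ie <- .match_library(library_peaks$mz, experimental, tolerance)
  il <- library_peaks$intensity
  num <- sum(sqrt(ie * il))^2
  den <- sum(il) * sum(ie)
  if (den == 0) return(0)
  num / den
}

#' Matched fragment peaks percentage
#'
#' Fraction of in-silico CRF ions with an experimental peak within
#' tolerance.
#'
#' @inheritParams reverse_dot_product
#' @return fraction in \[0, 1\].
#' @export
matched_peaks_percentage <- function(experimental, library_peaks,
                                     tolerance = 0.025) {
  if (!nrow(library_peaks)) return(0)
  ie <- .match_library(library_peaks$mz, experimental, tolerance)
  mean(ie > 0)
}

#' V-shape bonus score
#'
#' 0.5 when the average experimental intensity at the predicted
#' `cc_high` positions is more than 1.5 times that at the `cc_low`
#' positions (strict); 0 otherwise, including when no low peak is
#' matched.
#'
#' @param experimental `centroid_spectrum`.
#' @param insilico an `insilico_spectrum` of the candidate.
#' @param tolerance matching tolerance (Da).
#' @return 0 or 0.5.
#' @export
vshape_bonus <- function(experimental, insilico, tolerance = 0.025) {
  high <- insilico$mz[insilico$class %in% c("cc_high_hloss", "cc_high_radical")]
  low <- insilico$mz[insilico$class == "cc_low"]
  if (!length(high) || !length(low)) return(0)
  ih <- .match_library(high, experimental, tolerance)
  il <- .match_library(low, experimental, tolerance)
  if (!any(il > 0)) return(0)
  if (mean(ih) > 1.5 * mean(il)) 0.5 else 0
}

#' PUFA H-gain bonus score
#'
#' For candidates with a chain of three or more double bonds: 0.5 when
#' the experimental intensity of the `cc_pufa_high` H-gain peak is more
#' than three times the average of the other matched H-gain ions
#' (strict); 0 otherwise.
#'
#' @inheritParams vshape_bonus
#' @return 0 or 0.5.
#' @export
pufa_hgain_bonus <- function(experimental, insilico, tolerance = 0.025) {
  pufa <- insilico$mz[insilico$class == "cc_pufa_high"]
  if (!length(pufa)) return(0)
  other <- insilico$mz[insilico$series == "H-gain" &
                         insilico$class != "cc_pufa_high"]
  if (!length(other)) return(0)
  ip <- max(.match_library(pufa, experimental, tolerance))
  io <- .match_library(other, experimental, tolerance)
  if (ip > 3 * mean(io)) 0.5 else 0
}

#' Score one candidate against a spectrum
#'
#' Runs the diagnostic evaluation, the double-bond presence check and the
#' spectral-fitting components, and assembles the composite score.
#'
#' @param candidate resolved `lipid_structure`.
#' @param ctx a [noise_context()].
#' @param adduct adduct name or object.
#' @param min_mz low-mass cutoff for the in-silico spectrum.
#' @param diagnostics optional precomputed result of
#'   [evaluate_diagnostics()], to avoid re-evaluating it.
#' @return a `score_breakdown` list, or `NULL` when the candidate fails
#'   the double-bond presence check (eliminated, not scored).
#' @export
score_candidate <- function(candidate, ctx, adduct = "[M+H]+", min_mz = 150,
                            diagnostics = NULL) {
  diag <- if (is.null(diagnostics)) {
    evaluate_diagnostics(candidate, ctx, adduct)
  } else {
    diagnostics
  }
  if (!cc_presence_check(candidate, ctx, adduct, min_mz)) return(NULL)
  insil <- build_insilico_spectrum(candidate, adduct, min_mz = min_mz)
  crf <- insil[insil$series != "diagnostic", , drop = FALSE]
  rdp <- reverse_dot_product(ctx$spectrum, crf, ctx$tolerance)
  mpp <- matched_peaks_percentage(ctx$spectrum, crf, ctx$tolerance)
  vs <- vshape_bonus(ctx$spectrum, insil, ctx$tolerance)
  pf <- pufa_hgain_bonus(ctx$spectrum, insil, ctx$tolerance)
  db <- rdp + mpp + vs + pf
  total <- diag$class_score + diag$chain_score + diag$position_score + db
  structure(c(diag, list(rdp = rdp, mpp = mpp, vshape_bonus = vs,
                         pufa_bonus = pf, double_bond_score = db,
                         total = total, high_confidence = total > 4.8)),
            class = "score_breakdown")
}

# annotation level implied by which diagnostics passed
.assigned_level <- function(candidate, breakdown) {
  def <- .subclass_def(candidate$subclass)
  if (breakdown$chain_score != 1L) return("species")
  pos <- breakdown$position_score == 1L
  db <- TRUE  # scored candidates passed the C=C presence check
  if (def$category == "SP") {
    if (pos && db) return("oh_db_resolved")
    if (pos) return("oh_resolved")
    return("db_resolved")
  }
  if (pos && db) return("sn_db_resolved")
  if (pos) return("sn_resolved")
  if (db) return("db_resolved")
  "molecular_species"
}

#' Annotate an EAD-MS/MS spectrum
#'
#' Executes the decision tree: noise filtering, candidate enumeration
#' (species -> molecular species -> sn/OH -> C=C), subclass diagnostic
#' gating, the double-bond presence check, spectral fitting and ranking.
#' All surviving candidates are reported so co-eluting isomers remain
#' visible.
#'
#' @param spectrum a `centroid_spectrum` with precursor m/z.
#' @param query a `lipid_structure`, shorthand string, or
#'   `candidate_set`; species- or molecular-species-level queries are
#'   expanded with [enumerate_candidates()].
#' @param adduct adduct hypothesis.
#' @param tolerance MS2 matching tolerance (Da).
#' @param model a [noise_model()].
#' @param config a [candidate_config()].
#' @param min_mz low-mass cutoff (Da).
#' @return an `annotation_result`: list with `query`, `ranking`
#'   (data.frame: name, level, scores, high_confidence), `candidates`
#'   (surviving structures in ranked order), `breakdowns`, and `top`
#'   (best candidate or `NULL` for an unannotated spectrum).
#' @export
annotate_spectrum <- function(spectrum, query, adduct = "[M+H]+",
                              tolerance = 0.025, model = noise_model(),
                              config = candidate_config(), min_mz = 150) {
  ctx <- noise_context(spectrum, tolerance, model)
  cset <- if (inherits(query, "candidate_set")) query else
    enumerate_candidates(query, config)
  cands <- cset$candidates
  kept <- list(); scores <- list()
  any_class <- FALSE
  for (cand in cands) {
    diag_only <- evaluate_diagnostics(cand, ctx, adduct)
    if (diag_only$class_score == 1L) any_class <- TRUE
    if (diag_only$class_score != 1L) next
    br <- score_candidate(cand, ctx, adduct, min_mz, diagnostics = diag_only)
    if (is.null(br)) next
    kept[[length(kept) + 1L]] <- cand
    scores[[length(scores) + 1L]] <- br
  }
  if (!length(kept)) {
    ranking <- data.frame(rank = integer(0), name = character(0),
                          level = character(0))
    level <- if (any_class) "species" else "unannotated"
    name <- if (any_class) {
      t <- .species_totals(cset$query)
      format_lipid_name(lipid_structure(cset$query$subclass,
                                        species_totals = t))
    } else NA_character_
    return(structure(list(query = cset$query, ranking = ranking,
                          candidates = list(), breakdowns = list(),
                          top = NULL, fallback_level = level,
                          fallback_name = name),
                     class = "annotation_result"))
  }
  totals <- vapply(scores, `[[`, numeric(1), "total")
  ord <- order(-totals)   # stable: ties keep candidate-space order
  kept <- kept[ord]; scores <- scores[ord]
  ranking <- do.call(rbind, lapply(seq_along(kept), function(i) {
    br <- scores[[i]]
    data.frame(rank = i, name = format_lipid_name(kept[[i]]),
               level = .assigned_level(kept[[i]], br),
               class_score = br$class_score, chain_score = br$chain_score,
               position_score = br$position_score, rdp = br$rdp,
               mpp = br$mpp, vshape_bonus = br$vshape_bonus,
               pufa_bonus = br$pufa_bonus, total = br$total,
               high_confidence = br$high_confidence,
               stringsAsFactors = FALSE)
  }))
  structure(list(query = cset$query, ranking = ranking, candidates = kept,
                 breakdowns = scores, top = kept[[1L]],
                 fallback_level = NULL, fallback_name = NULL),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("<annotation_result> query:", format_lipid_name(x$query), "\n")
  if (!nrow(x$ranking)) {
    cat("  ", if (identical(x$fallback_level, "species"))
      paste0("species-level only: ", x$fallback_name) else "unannotated",
      "\n")
  } else {
    print(utils::head(x$ranking[, c("rank", "name", "level", "total",
                                    "high_confidence")], 10L))
  }
  invisible(x)
}
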