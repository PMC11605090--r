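# Mass-spectrometry-imaging feature annotation: 2-D (m/z x drift time)
# accumulation, peak picking, matching against an m/z + CCS reference
# table, and ion-image extraction.

#' Read an m/z + CCS reference table
#'
#' @param path TSV with columns `name`, `adduct`, `mz`, `ccs`, `source`
#'   (experimental | predicted).
#' @return data.frame of reference entries.
#' @export
read_ccs_reference <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "adduct", "mz", "ccs")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("reference table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(tab$mz <= 0) || any(tab$ccs <= 0)) {
    stop("reference m/z and CCS must be positive")
  }
  if (is.null(tab$source)) tab$source <- "experimental"
  tab
}

#' Read an MSI spot table
#'
#' @param path TSV with columns `x`, `y`, `mz`, `drift_time`, `intensity`
#'   and optionally `ccs`.
#' @return data.frame of spot peaks.
#' @export
read_msi_spots <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "mz", "drift_time", "intensity")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("spot table lacks column(s): ", paste(missing, collapse = ", "))
  }
  tab
}

#' Accumulate MALDI spot spectra into a 2-D histogram
#'
#' Sums intensities over all spots on a fixed (m/z, drift time) grid.
#'
#' @param spots data.frame with `mz`, `drift_time`, `intensity` (and any
#'   pixel columns, ignored here).
#' @param mz_bin m/z bin width in Da (default 0.005).
#' @param dt_bin drift-time bin width in ms (default 0.01).
#' @return data.frame of occupied cells: `mz` (bin center), `drift_time`
#'   (bin center), `intensity` (summed), with the bin widths as
#'   attributes.
#' @export
accumulate_msi <- function(spots, mz_bin = 0.005, dt_bin = 0.01) {
  if (!nrow(spots)) stop("empty spot stream")
  imz <- floor(spots$mz / mz_bin)
  idt <- floor(spots$drift_time / dt_bin)
  key <- paste(imz, idt)
  inten <- tapply(spots$intensity, key, sum)
  ik <- do.call(rbind, strsplit(names(inten), " "))
  out <- data.frame(mz = (as.numeric(ik[, 1]) + 0.5) * mz_bin,
                    drift_time = (as.numeric(ik[, 2]) + 0.5) * dt_bin,
                    intensity = as.numeric(inten))
  out <- out[order(out$mz, out$drift_time), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mz_bin") <- mz_bin
  attr(out, "dt_bin") <- dt_bin
  out
}

#' Pick features from an accumulated 2-D histogram
#'
#' 8-neighborhood local maxima above an intensity threshold on the
#' (m/z, drift time) grid.
#'
#' @param histogram output of [accumulate_msi()].
#' @param min_intensity minimum summed intensity of a feature.
#' @param ccs_from_dt optional function mapping drift time (ms) to CCS
#'   (Angstrom^2); a single-field linear calibration by default is left
#'   to the caller.
#' @return data.frame of features: `mz`, `drift_time`, `ccs` (NA without
#'   a calibration), `intensity`.
#' @export
pick_features <- function(histogram, min_intensity = 0, ccs_from_dt = NULL) {
  mz_bin <- attr(histogram, "mz_bin")
  dt_bin <- attr(histogram, "dt_bin")
  imz <- round(histogram$mz / mz_bin - 0.5)
  idt <- round(histogram$drift_time / dt_bin - 0.5)
  cellmap <- new.env(hash = TRUE)
  for (i in seq_len(nrow(histogram))) {
    assign(paste(imz[i], idt[i]), histogram$intensity[i], envir = cellmap)
  }
  keep <- logical(nrow(histogram))
  for (i in seq_len(nrow(histogram))) {
    if (histogram$intensity[i] < min_intensity) next
    ismax <- TRUE
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0L && dy == 0L) next
      nb <- mget(paste(imz[i] + dx, idt[i] + dy), envir = cellmap,
                 ifnotfound = list(NULL))[[1]]
      if (!is.null(nb) && nb > histogram$intensity[i]) ismax <- FALSE
    }
    keep[i] <- ismax
  }
  feats <- histogram[keep, , drop = FALSE]
  feats$ccs <- if (is.null(ccs_from_dt)) rep(NA_real_, nrow(feats)) else
    ccs_from_dt(feats$drift_time)
  rownames(feats) <- NULL
  feats[, c("mz", "drift_time", "ccs", "intensity")]
}

#' Match MSI features against an m/z + CCS reference table
#'
#' A feature is annotated with every reference entry inside both the m/z
#' and CCS tolerances; the nearest-m/z entry is flagged as the best
#' match.
#'
#' @param features data.frame with `mz` and `ccs` columns.
#' @param reference reference table from [read_ccs_reference()].
#' @param mz_tol m/z tolerance in Da (default 0.01).
#' @param ccs_tol CCS tolerance in Angstrom^2 (default 20).
#' @return data.frame with one row per (feature, matching entry):
#'   `feature`, `mz`, `ccs`, `name`, `adduct`, `ref_mz`, `ref_ccs`,
#'   `best`. Unmatched features appear once with `NA` annotation.
#' @export
match_features <- function(features, reference, mz_tol = 0.01,
                           ccs_tol = 20) {
  rows <- list()
  for (i in seq_len(nrow(features))) {
    dmz <- abs(reference$mz - features$mz[i])
    dccs <- abs(reference$ccs - features$ccs[i])
    hit <- which(dmz <= mz_tol & dccs <= ccs_tol)
    if (!length(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature = i, mz = features$mz[i], ccs = features$ccs[i],
        name = NA_character_, adduct = NA_character_,
        ref_mz = NA_real_, ref_ccs = NA_real_, best = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    best <- hit[which.min(dmz[hit])]
    rows[[length(rows) + 1L]] <- data.frame(
      feature = i, mz = features$mz[i], ccs = features$ccs[i],
      name = reference$name[hit], adduct = reference$adduct[hit],
      ref_mz = reference$mz[hit], ref_ccs = reference$ccs[hit],
      best = hit == best, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(feature = integer(0), mz = numeric(0),
                      ccs = numeric(0), name = character(0),
                      adduct = character(0), ref_mz = numeric(0),
                      ref_ccs = numeric(0), best = logical(0)))
  }
  do.call(rbind, rows)
}

#' Extract an ion image for one feature
#'
#' Per-pixel summed intensity of all spot peaks within the m/z and CCS
#' tolerances of the feature.
#'
#' @param spots spot table with `x`, `y`, `mz`, `intensity` and `ccs`
#'   (or `drift_time` plus a `ccs_from_dt` calibration).
#' @param feature list or one-row data.frame with `mz` and `ccs`.
#' @param mz_tol m/z tolerance in Da (default 0.01).
#' @param ccs_tol CCS tolerance in Angstrom^2 (default 5).
#' @param ccs_from_dt optional drift-time to CCS calibration function.
#' @return data.frame `x`, `y`, `intensity` (only nonzero pixels).
#' @export
ion_image <- function(spots, feature, mz_tol = 0.01, ccs_tol = 5,
                      ccs_from_dt = NULL) {
  ccs <- spots$ccs
  if (is.null(ccs) && !is.null(ccs_from_dt)) ccs <- ccs_from_dt(spots$drift_time)
  if (is.null(ccs)) stop("spots carry no CCS and no calibration was supplied")
  sel <- abs(spots$mz - feature$mz) <= mz_tol &
    abs(ccs - feature$ccs) <= ccs_tol
  if (!any(sel)) {
    return(data.frame(x = integer(0), y = integer(0), intensity = numeric(0)))
  }
  sub <- spots[sel, , drop = FALSE]
  agg <- stats::aggregate(intensity ~ x + y, data = sub, FUN = sum)
  agg[order(agg$x, agg$y), , drop = FALSE]
}
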