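# Centroid spectrum container, file formats (MSP / MGF / mzML), scan
# accumulation, background subtraction, and the instrument noise model.

#' Construct a centroided MS/MS spectrum
#'
#' @param mz numeric vector of peak m/z values (Da).
#' @param intensity non-negative peak intensities (arbitrary counts).
#' @param precursor_mz precursor m/z or `NA`.
#' @param metadata named list (retention time, kinetic energy eV, collision
#'   energy, polarity, title, ...).
#' @param merge_tol peaks closer than this are merged by intensity
#'   summation.
#' @return a `centroid_spectrum`: list with `precursor_mz`, `peaks`
#'   (data.frame `mz`, `intensity` sorted by m/z) and `metadata`.
#' @export
centroid_spectrum <- function(mz, intensity, precursor_mz = NA_real_,
                              metadata = list(), merge_tol = 1e-6) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("negative peak intensity")
  ord <- order(mz)
  mz <- as.numeric(mz[ord])
  intensity <- as.numeric(intensity[ord])
  if (length(mz) > 1L) {
    grp <- cumsum(c(TRUE, diff(mz) > merge_tol))
    mz <- vapply(split(mz, grp), `[`, numeric(1), 1L)
    intensity <- vapply(split(intensity, grp), sum, numeric(1))
  }
  structure(list(precursor_mz = precursor_mz,
                 peaks = data.frame(mz = unname(mz),
                                    intensity = unname(intensity)),
                 metadata = metadata),
            class = "centroid_spectrum")
}

#' @export
print.centroid_spectrum <- function(x, ...) {
  cat("<centroid_spectrum> ", nrow(x$peaks), " peaks",
      if (!is.na(x$precursor_mz)) sprintf(", precursor m/z %.4f", x$precursor_mz),
      "\n", sep = "")
  invisible(x)
}

# ---- MSP -------------------------------------------------------------------

#' Read a NIST MSP spectral library file
#'
#' @param path MSP text file with `Name:` / `PrecursorMZ:` / `Num Peaks:`
#'   blocks followed by one `m/z intensity` pair per line.
#' @return list of `centroid_spectrum`.
#' @export
read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    while (i <= n && !grepl("^Name:", lines[i], ignore.case = TRUE)) {
      if (nzchar(trimws(lines[i]))) {
        stop("malformed MSP at line ", i, ": expected 'Name:' header")
      }
      i <- i + 1L
    }
    if (i > n) break
    meta <- list()
    npeaks <- NA_integer_
    pre <- NA_real_
    while (i <= n && grepl(":", lines[i], fixed = TRUE)) {
      key <- trimws(sub(":.*", "", lines[i]))
      val <- trimws(sub("^[^:]*:", "", lines[i]))
      lk <- tolower(key)
      if (lk == "num peaks") {
        npeaks <- as.integer(val)
      } else if (lk %in% c("precursormz", "precursor_mz")) {
        pre <- as.numeric(val)
      } else {
        meta[[key]] <- val
      }
      i <- i + 1L
      if (!is.na(npeaks)) break
    }
    if (is.na(npeaks)) stop("malformed MSP near line ", i, ": no 'Num Peaks:'")
    pk <- matrix(NA_real_, nrow = npeaks, ncol = 2L)
    for (j in seq_len(npeaks)) {
      if (i > n || !nzchar(trimws(lines[i]))) {
        stop("malformed MSP at line ", i, ": expected ", npeaks,
             " peak lines, got ", j - 1L)
      }
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                   "[ \t]+")[[1]]))
      if (length(vals) < 2L || anyNA(vals[1:2])) {
        stop("malformed MSP peak line ", i, ": '", lines[i], "'")
      }
      pk[j, ] <- vals[1:2]
      i <- i + 1L
    }
    out[[length(out) + 1L]] <- centroid_spectrum(pk[, 1L], pk[, 2L],
                                                 precursor_mz = pre,
                                                 metadata = meta)
  }
  out
}

#' Write spectra to a NIST MSP file
#'
#' Lossless companion to [read_msp()].
#' @param spectra a `centroid_spectrum` or list thereof.
#' @param path output file.
#' @export
write_msp <- function(spectra, path) {
  if (inherits(spectra, "centroid_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    name <- sp$metadata$Name
    if (is.null(name)) name <- "spectrum"
    writeLines(paste0("Name: ", name), con)
    for (key in setdiff(names(sp$metadata), "Name")) {
      writeLines(paste0(key, ": ", sp$metadata[[key]]), con)
    }
    if (!is.na(sp$precursor_mz)) {
      writeLines(sprintf("PrecursorMZ: %.6f", sp$precursor_mz), con)
    }
    writeLines(paste0("Num Peaks: ", nrow(sp$peaks)), con)
    writeLines(sprintf("%.6f %.6g", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines("", con)
  }
  invisible(path)
}

# ---- MGF -------------------------------------------------------------------

#' Read a Mascot generic format (MGF) file
#'
#' @param path MGF text file (`BEGIN IONS` ... `END IONS` blocks).
#' @return list of `centroid_spectrum`.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  inblock <- FALSE
  meta <- list(); pre <- NA_real_; mzv <- numeric(0); iv <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (identical(ln, "BEGIN IONS")) {
      if (inblock) stop("malformed MGF at line ", i, ": nested BEGIN IONS")
      inblock <- TRUE
      meta <- list(); pre <- NA_real_; mzv <- numeric(0); iv <- numeric(0)
    } else if (identical(ln, "END IONS")) {
      if (!inblock) stop("malformed MGF at line ", i, ": stray END IONS")
      out[[length(out) + 1L]] <- centroid_spectrum(mzv, iv, precursor_mz = pre,
                                                   metadata = meta)
      inblock <- FALSE
    } else if (inblock && grepl("=", ln, fixed = TRUE)) {
      key <- sub("=.*", "", ln)
      val <- sub("^[^=]*=", "", ln)
      if (identical(key, "PEPMASS")) {
        pre <- as.numeric(strsplit(val, "[ \t]+")[[1]][1])
      } else {
        meta[[key]] <- val
      }
    } else if (inblock) {
      vals <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]]))
      if (length(vals) < 2L || anyNA(vals[1:2])) {
        stop("malformed MGF peak line ", i, ": '", ln, "'")
      }
      mzv <- c(mzv, vals[1]); iv <- c(iv, vals[2])
    }
  }
  if (inblock) stop("malformed MGF: unterminated BEGIN IONS block")
  out
}

# ---- mzML ------------------------------------------------------------------

#' Read centroided MS2 scans from an mzML file
#'
#' Imports only MS level-2 scans; profile-mode spectra are rejected
#' (centroid data required). Requires the `mzR` package.
#'
#' @param path mzML file.
#' @return list of `centroid_spectrum` with retention time metadata.
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package")
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  ms2 <- which(hd$msLevel == 2L)
  out <- vector("list", length(ms2))
  for (j in seq_along(ms2)) {
    i <- ms2[j]
    if (!is.null(hd$centroided) && isFALSE(hd$centroided[i])) {
      stop("profile-mode scan ", i, ": centroid required")
    }
    pk <- mzR::peaks(fh, i)
    out[[j]] <- centroid_spectrum(
      pk[, 1L], pk[, 2L],
      precursor_mz = hd$precursorMZ[i],
      metadata = list(rt = hd$retentionTime[i], scan = hd$acquisitionNum[i]))
  }
  out
}

# ---- accumulation & subtraction -------------------------------------------

#' Accumulate DDA scans across an elution window
#'
#' Bins all peaks of the selected scans on a fixed m/z grid and reports the
#' per-bin average intensity; the bin-center m/z represents each bin.
#'
#' @param scans list of `centroid_spectrum`.
#' @param rt_window optional numeric length-2 retention-time window
#'   (seconds); scans without an `rt` metadata entry are kept.
#' @param bin bin width in Da (default 0.05).
#' @return a `centroid_spectrum` on the binned grid.
#' @export
accumulate_scans <- function(scans, rt_window = NULL, bin = 0.05) {
  if (inherits(scans, "centroid_spectrum")) scans <- list(scans)
  if (!is.null(rt_window)) {
    scans <- Filter(function(s) {
      rt <- s$metadata$rt
      is.null(rt) || (rt >= rt_window[1] && rt <= rt_window[2])
    }, scans)
  }
  if (!length(scans)) stop("no scans in the accumulation window")
  nscan <- length(scans)
  mz <- unlist(lapply(scans, function(s) s$peaks$mz))
  it <- unlist(lapply(scans, function(s) s$peaks$intensity))
  idx <- floor(mz / bin)
  inten <- tapply(it, idx, sum) / nscan      # average over accumulated scans
  centers <- (as.numeric(names(inten)) + 0.5) * bin
  pre <- stats::median(vapply(scans, function(s) s$precursor_mz, numeric(1)),
                       na.rm = TRUE)
  centroid_spectrum(centers, as.numeric(inten), precursor_mz = pre,
                    metadata = list(bin = bin, n_scans = nscan))
}

#' Subtract a background spectrum
#'
#' Element-wise intensity subtraction on a shared bin grid; negative
#' results are clamped to zero and zero-intensity bins dropped.
#'
#' @param spectrum,background `centroid_spectrum`s binned identically
#'   (same `bin` metadata).
#' @return background-subtracted `centroid_spectrum`.
#' @export
subtract_background <- function(spectrum, background) {
  if (!nrow(background$peaks)) return(spectrum)
  b1 <- spectrum$metadata$bin
  b2 <- background$metadata$bin
  if (!is.null(b1) && !is.null(b2) && !isTRUE(all.equal(b1, b2))) {
    stop("spectrum and background use different bin widths (",
         b1, " vs ", b2, ")")
  }
  key <- match(round(spectrum$peaks$mz, 6), round(background$peaks$mz, 6))
  sub <- ifelse(is.na(key), 0, background$peaks$intensity[key])
  inten <- pmax(spectrum$peaks$intensity - sub, 0)
  keep <- inten > 0
  centroid_spectrum(spectrum$peaks$mz[keep], inten[keep],
                    precursor_mz = spectrum$precursor_mz,
                    metadata = spectrum$metadata)
}

# ---- noise model -----------------------------------------------------------

#' Instrument noise ("barcode ion") model
#'
#' On the reference instrument, product-ion peaks with intensity below 11
#' counts appear randomly over the whole m/z range and are treated as
#' noise; a diagnostic ion must additionally exceed twice the minimum
#' retained peak intensity to count as detected. Both constants are
#' instrument characteristics and therefore parameters.
#'
#' @param barcode_threshold intensity floor (counts); peaks strictly below
#'   are removed, and a diagnostic at or below it is never "detected".
#' @param detection_multiplier detection requires intensity strictly
#'   greater than this multiple of the minimum peak intensity.
#' @return a `noise_model` list.
#' @export
noise_model <- function(barcode_threshold = 11, detection_multiplier = 2.0) {
  stopifnot(barcode_threshold >= 0, detection_multiplier >= 1)
  structure(list(barcode_threshold = barcode_threshold,
                 detection_multiplier = detection_multiplier),
            class = "noise_model")
}

#' Remove barcode noise and compute the minimum peak intensity
#'
#' @param spectrum a `centroid_spectrum`.
#' @param model a [noise_model()].
#' @return list with `spectrum` (filtered) and `min_peak_intensity`
#'   (minimum intensity among the retained peaks; the detection floor).
#' @export
apply_noise_model <- function(spectrum, model = noise_model()) {
  keep <- spectrum$peaks$intensity >= model$barcode_threshold
  pk <- spectrum$peaks[keep, , drop = FALSE]
  if (!nrow(pk)) {
    warning("all peaks fall below the barcode threshold")
    mpi <- NA_real_
  } else {
    mpi <- min(pk$intensity)
  }
  filtered <- centroid_spectrum(pk$mz, pk$intensity,
                                precursor_mz = spectrum$precursor_mz,
                                metadata = spectrum$metadata)
  list(spectrum = filtered, min_peak_intensity = mpi)
}

#' Is a diagnostic ion detected?
#'
#' TRUE iff a peak within `tolerance` of `target_mz` exists whose
#' intensity is strictly greater than both the barcode threshold and
#' `detection_multiplier` times the minimum peak intensity.
#'
#' @param target_mz theoretical ion m/z (Da).
#' @param spectrum noise-filtered `centroid_spectrum`.
#' @param min_peak_intensity from [apply_noise_model()].
#' @param tolerance m/z matching tolerance (Da).
#' @param model a [noise_model()].
#' @return logical.
#' @export
is_detected <- function(target_mz, spectrum, min_peak_intensity,
                        tolerance = 0.025, model = noise_model()) {
  stopifnot(tolerance > 0)
  if (is.na(min_peak_intensity)) return(FALSE)
  hit <- abs(spectrum$peaks$mz - target_mz) <= tolerance
  if (!any(hit)) return(FALSE)
  inten <- max(spectrum$peaks$intensity[hit])
  inten > model$detection_multiplier * min_peak_intensity &&
    inten > model$barcode_threshold
}
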