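# Ground-truthed synthetic inputs: noisy EAD spectra, co-elution mixtures,
# dilution series and MSI phantoms. Everything is deterministic under the
# seed carried by the config, so fixtures regenerate bit-identically.

#' Noise configuration for synthetic spectra
#'
#' The noise model is the simplest one consistent with the reference
#' instrument's behaviour: multiplicative log-normal intensity jitter,
#' Gaussian m/z jitter, random peak dropout, and uniform-m/z "barcode"
#' noise peaks at the intensity floor.
#'
#' @param seed RNG seed.
#' @param base_intensity intensity (counts) assigned to the model base
#'   peak.
#' @param intensity_jitter relative s.d. of the log-normal intensity
#'   jitter.
#' @param mz_jitter s.d. of the m/z jitter (Da).
#' @param dropout per-peak dropout probability.
#' @param n_noise_peaks number of barcode noise peaks injected.
#' @param noise_level intensity level of the barcode peaks (at/below the
#'   default barcode threshold of 11).
#' @return a `spectrum_noise_config` list.
#' @export
spectrum_noise_config <- function(seed = 1L, base_intensity = 2000,
                                  intensity_jitter = 0.2, mz_jitter = 0.002,
                                  dropout = 0.02, n_noise_peaks = 30L,
                                  noise_level = 10) {
  stopifnot(dropout >= 0, dropout <= 1, intensity_jitter >= 0,
            mz_jitter >= 0)
  structure(list(seed = as.integer(seed), base_intensity = base_intensity,
                 intensity_jitter = intensity_jitter, mz_jitter = mz_jitter,
                 dropout = dropout, n_noise_peaks = as.integer(n_noise_peaks),
                 noise_level = noise_level),
            class = "spectrum_noise_config")
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.apply_noise <- function(mz, inten, pre, config) {
  if (config$dropout > 0) {
    keep <- stats::runif(length(mz)) >= config$dropout
    mz <- mz[keep]; inten <- inten[keep]
  }
  if (config$intensity_jitter > 0 && length(inten)) {
    inten <- inten * stats::rlnorm(length(inten),
                                   sdlog = config$intensity_jitter)
  }
  if (config$mz_jitter > 0 && length(mz)) {
    mz <- mz + stats::rnorm(length(mz), sd = config$mz_jitter)
  }
  if (config$n_noise_peaks > 0L) {
    nmz <- stats::runif(config$n_noise_peaks, 150, max(pre - 1, 151))
    mz <- c(mz, nmz)
    inten <- c(inten, rep(config$noise_level, config$n_noise_peaks))
  }
  list(mz = mz, intensity = inten)
}

#' Synthesize an EAD spectrum with ground truth
#'
#' Scales the in-silico spectrum of a fully resolved candidate to the
#' configured base-peak intensity, applies the noise model and returns
#' the spectrum together with the truth record.
#'
#' @param s fully resolved `lipid_structure` (or shorthand).
#' @param adduct adduct name or object.
#' @param config a [spectrum_noise_config()].
#' @param min_mz low-mass cutoff passed to the in-silico generator.
#' @return list with `spectrum` (`centroid_spectrum`) and `truth`
#'   (list: `name`, `adduct`, `precursor_mz`).
#' @export
synth_spectrum <- function(s, adduct = "[M+H]+",
                           config = spectrum_noise_config(), min_mz = 150) {
  if (is.character(s)) s <- parse_lipid_name(s)
  insil <- build_insilico_spectrum(s, adduct, min_mz = min_mz)
  pre <- attr(insil, "precursor_mz")
  scale <- config$base_intensity / max(insil$intensity)
  noisy <- .with_seed(config$seed,
                      .apply_noise(insil$mz, insil$intensity * scale, pre,
                                   config))
  sp <- centroid_spectrum(noisy$mz, noisy$intensity, precursor_mz = pre,
                          metadata = list(Name = format_lipid_name(s),
                                          adduct = attr(insil, "adduct")))
  list(spectrum = sp,
       truth = list(name = format_lipid_name(s),
                    adduct = attr(insil, "adduct"), precursor_mz = pre))
}

#' Synthesize a co-elution mixture spectrum
#'
#' Linear combination of the component in-silico spectra (shared peaks
#' sum) before a single noise-injection pass.
#'
#' @param structures list of resolved `lipid_structure`s (or shorthand).
#' @param ratios positive mixing weights, one per structure.
#' @param adduct adduct name or object.
#' @param config a [spectrum_noise_config()].
#' @param min_mz low-mass cutoff.
#' @return list with `spectrum` and `truth` (components, ratios, major
#'   component name).
#' @export
synth_mixture <- function(structures, ratios, adduct = "[M+H]+",
                          config = spectrum_noise_config(), min_mz = 150) {
  stopifnot(length(structures) == length(ratios), all(ratios > 0))
  structures <- lapply(structures, function(x) {
    if (is.character(x)) parse_lipid_name(x) else x
  })
  mz <- numeric(0); inten <- numeric(0); pre <- NA_real_
  for (i in seq_along(structures)) {
    insil <- build_insilico_spectrum(structures[[i]], adduct, min_mz = min_mz)
    scale <- config$base_intensity / max(insil$intensity) * ratios[i] /
      max(ratios)
    mz <- c(mz, insil$mz)
    inten <- c(inten, insil$intensity * scale)
    pre <- attr(insil, "precursor_mz")
  }
  # sum shared peaks on a fine grid before noise
  merged <- centroid_spectrum(mz, inten, precursor_mz = pre,
                              merge_tol = 1e-4)
  noisy <- .with_seed(config$seed,
                      .apply_noise(merged$peaks$mz, merged$peaks$intensity,
                                   pre, config))
  names <- vapply(structures, format_lipid_name, character(1))
  sp <- centroid_spectrum(noisy$mz, noisy$intensity, precursor_mz = pre,
                          metadata = list(Name = paste(names, collapse = " + ")))
  list(spectrum = sp,
       truth = list(components = names, ratios = ratios,
                    major = names[which.max(ratios)]))
}

#' Synthesize a dilution series
#'
#' Spectra whose intensities scale linearly with concentration level;
#' peaks falling below the barcode threshold vanish, reproducing the
#' level-dependent degradation of structure annotation.
#'
#' @param s resolved `lipid_structure` (or shorthand).
#' @param levels numeric vector of relative concentration levels
#'   (1 = full intensity).
#' @param adduct adduct name or object.
#' @param config a [spectrum_noise_config()]; `base_intensity` is the
#'   base-peak intensity at level 1.
#' @param threshold intensity floor below which peaks are not recorded.
#' @return list of `centroid_spectrum`, one per level.
#' @export
synth_dilution_series <- function(s, levels, adduct = "[M+H]+",
                                  config = spectrum_noise_config(),
                                  threshold = 11) {
  lapply(seq_along(levels), function(i) {
    cfg <- config
    cfg$base_intensity <- config$base_intensity * levels[i]
    cfg$seed <- config$seed + i
    if (levels[i] <= 0) {
      return(centroid_spectrum(numeric(0), numeric(0)))
    }
    sp <- synth_spectrum(s, adduct, cfg)$spectrum
    keep <- sp$peaks$intensity >= threshold
    centroid_spectrum(sp$peaks$mz[keep], sp$peaks$intensity[keep],
                      precursor_mz = sp$precursor_mz,
                      metadata = c(sp$metadata, list(level = levels[i])))
  })
}

#' Synthesize an MSI phantom
#'
#' Rectangular pixel grid with per-region lipid assignments drawn from a
#' reference table; each pixel of a region carries one spot peak per
#' assigned lipid, jittered in m/z and CCS. The truth table links
#' regions, pixels and reference entries for automatic precision/recall
#' scoring.
#'
#' @param reference reference table (see [read_ccs_reference()]).
#' @param regions list of regions, each a list with `rows` (integer
#'   range), `cols` (integer range) and `entries` (row indices into
#'   `reference`).
#' @param nx,ny grid size in pixels.
#' @param mz_jitter,ccs_jitter s.d. of the per-spot jitter.
#' @param intensity mean spot intensity.
#' @param seed RNG seed.
#' @return list with `spots` (spot table), `truth` (region-entry table).
#' @export
synth_msi_phantom <- function(reference, regions, nx = 50L, ny = 50L,
                              mz_jitter = 0, ccs_jitter = 0,
                              intensity = 100, seed = 1L) {
  .with_seed(seed, {
    rows <- list()
    truth <- list()
    for (ri in seq_along(regions)) {
      rg <- regions[[ri]]
      px <- expand.grid(x = rg$cols, y = rg$rows)
      for (ei in rg$entries) {
        n <- nrow(px)
        rows[[length(rows) + 1L]] <- data.frame(
          x = px$x, y = px$y,
          mz = reference$mz[ei] + stats::rnorm(n, sd = mz_jitter),
          drift_time = reference$ccs[ei] / 100,   # placeholder mobility axis
          ccs = reference$ccs[ei] + stats::rnorm(n, sd = ccs_jitter),
          intensity = stats::rlnorm(n, log(intensity), 0.1))
        truth[[length(truth) + 1L]] <- data.frame(
          region = ri, entry = ei, name = reference$name[ei],
          mz = reference$mz[ei], ccs = reference$ccs[ei])
      }
    }
    list(spots = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Noise-free synthesis configuration
#'
#' Convenience wrapper: all jitters, dropout and barcode noise set to
#' zero, for oracle round-trip experiments.
#'
#' @param seed RNG seed (kept for interface symmetry; no randomness is
#'   consumed).
#' @param base_intensity base-peak intensity.
#' @return a [spectrum_noise_config()].
#' @export
noise_free_config <- function(seed = 1L, base_intensity = 2000) {
  spectrum_noise_config(seed = seed, base_intensity = base_intensity,
                        intensity_jitter = 0, mz_jitter = 0, dropout = 0,
                        n_noise_peaks = 0L)
}

# chain sampled from the curated chemical space so that the candidate
# enumeration can recover it
.chains_key <- function(chains, config) {
  # mirrors the enumeration ordering: provenance, positions, name
  prov <- 1L
  for (ch in chains) {
    if (ch$db == 1L && ch$kind != "sphingoid" &&
        !(ch$db_positions %in% config$mufa_curated[[as.character(ch$carbons)]])) {
      prov <- 2L
    }
    if (ch$db >= 2L && ch$kind != "sphingoid") prov <- 2L
  }
  paste(prov,
        paste(sprintf("%02d", unlist(lapply(chains, `[[`, "db_positions"))),
              collapse = ","),
        paste(vapply(chains, .format_chain, character(1)), collapse = "/"),
        sep = "|")
}

# Omega-offset alias variants of a chain set. CRF fragment masses depend
# only on the distance of each double bond from the methyl (omega)
# terminus, so chains with equal double-bond counts can swap their omega
# offsets without changing the combined spectrum. The canonical truth is
# the alias-class member the candidate ordering ranks first.
.offset_variants <- function(chains, config) {
  unsat <- which(vapply(chains, function(ch) {
    ch$db >= 1L && ch$kind != "sphingoid"
  }, logical(1)))
  if (length(unsat) < 2L) return(list(chains))
  groups <- split(unsat, vapply(chains[unsat], `[[`, integer(1), "db"))
  variants <- list(chains)
  for (grp in groups) {
    if (length(grp) < 2L) next
    offs <- vapply(chains[grp], function(ch) {
      ch$carbons - max(ch$db_positions)
    }, integer(1))
    new_variants <- list()
    for (v in variants) {
      for (perm in .permutations(length(grp))) {
        w <- v
        ok <- TRUE
        for (j in seq_along(grp)) {
          i <- grp[j]
          off <- offs[perm[j]]
          ch <- w[[i]]
          if (ch$db == 1L) {
            p <- ch$carbons - off
            if (!(p %in% mufa_positions(ch$carbons, config))) { ok <- FALSE; break }
            ch$db_positions <- p
          } else {
            fams <- pufa_series(ch$carbons, ch$db, config)
            fam <- paste0("n-", off)
            if (!fam %in% names(fams)) { ok <- FALSE; break }
            ch$db_positions <- fams[[fam]]
          }
          w[[i]] <- ch
        }
        if (ok) new_variants[[length(new_variants) + 1L]] <- w
      }
    }
    if (length(new_variants)) variants <- new_variants
  }
  variants
}

# canonical representative: tie-break minimum over arrangement permutations
# (where the sn slots are not spectrally distinguishable) and omega-offset
# alias assignments
.canonical_truth <- function(chains, def, config) {
  sn_discernible <- identical(def$sn_rule, "pc_sn1") ||
    identical(def$sn_rule, "lyso")
  sig <- vapply(chains, function(ch) {
    paste(ch$kind, ch$carbons, ch$db, ch$oh)
  }, character(1))
  perms <- if (def$category != "SP" && length(chains) > 1L &&
               (!sn_discernible || anyDuplicated(sig) > 0L)) {
    .permutations(length(chains))
  } else {
    list(seq_along(chains))
  }
  best <- NULL
  best_key <- NULL
  for (v in .offset_variants(chains, config)) {
    for (ix in perms) {
      w <- v[ix]
      key <- .chains_key(w, config)
      if (is.null(best_key) || key < best_key) {
        best <- w
        best_key <- key
      }
    }
  }
  best
}

.random_chain <- function(kind, config) {
  if (kind == "sphingoid") {
    db <- sample(0:2, 1L, prob = c(0.2, 0.6, 0.2))
    pos <- sphingoid_positions(db, config)
    pick <- pos[[sample(length(pos), 1L)]]
    return(acyl_chain(18L, db, db_positions = pick, kind = "sphingoid",
                      oh = 2L, oh_positions = c(1L, 3L)))
  }
  n <- sample(c(14L, 16L, 18L, 20L, 22L), 1L)
  db_opts <- c(0L, 1L)
  if (n >= 18L) db_opts <- c(db_opts, 3L)
  if (n >= 20L) db_opts <- c(db_opts, 4L)
  db <- sample(db_opts, 1L)
  if (kind %in% c("alkyl", "alkenyl")) db <- min(db, 1L)
  pos <- NULL
  if (db == 1L) {
    cand <- mufa_positions(n, config)
    pos <- sample(cand, 1L)
  } else if (db >= 2L) {
    fams <- pufa_series(n, db, config)
    if (!length(fams)) {
      db <- 1L
      pos <- sample(mufa_positions(n, config), 1L)
    } else {
      pos <- fams[[sample(length(fams), 1L)]]
    }
  }
  acyl_chain(n, db, db_positions = pos, kind = kind)
}

#' Draw a random fully resolved candidate with its round-trip query
#'
#' Samples chains from the curated candidate space of a subclass, so the
#' returned structure is guaranteed to be recoverable by
#' [enumerate_candidates()] on the accompanying molecular-species query.
#' For subclasses whose sn-positions cannot be told apart under the
#' protonated adduct, chains are emitted in the canonical (tie-break)
#' order so the round trip is well defined.
#'
#' @param subclass one of [supported_subclasses()].
#' @param seed RNG seed.
#' @param config a [candidate_config()].
#' @return list with `truth` (resolved `lipid_structure`) and `query`
#'   (molecular-species shorthand string).
#' @export
random_resolved_lipid <- function(subclass, seed = 1L,
                                  config = candidate_config()) {
  def <- .subclass_def(subclass)
  .with_seed(seed, {
    chains <- lapply(def$kinds, .random_chain, config = config)
    chains <- .canonical_truth(chains, def, config)
    lyso_sn <- if (identical(def$sn_rule, "lyso")) sample(1:2, 1L) else 1L
    truth <- lipid_structure(subclass, chains, sn_assigned = TRUE,
                             lyso_sn = lyso_sn)
    bare <- vapply(truth$chains, function(ch) {
      ch$db_positions <- NULL
      ch$oh_positions <- NULL
      .format_chain(ch)
    }, character(1))
    base <- sub(" [OP]-$", "", subclass)
    query <- if (def$category == "SP") {
      paste0(base, " ", paste(bare, collapse = "/"))
    } else if (length(bare) == 1L) {
      paste0(base, " ", bare)
    } else {
      paste0(base, " ", paste(bare, collapse = "_"))
    }
    list(truth = truth, query = query)
  })
}
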