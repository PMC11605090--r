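# Spectrum information content and similarity metrics used for kinetic-
# energy optimization: spectral entropy, a modified dot product with fixed
# preprocessing constants, and molecular-network edge construction.

#' Spectral entropy
#'
#' Shannon entropy of the intensity-normalized peak distribution,
#' \eqn{-\sum_i p_i \log p_i} with \eqn{p_i} the intensity fraction of
#' peak i. Invariant under intensity rescaling; 0 for a single peak and
#' log(n) for n equal peaks.
#'
#' @param spectrum a `centroid_spectrum` (or data.frame with
#'   `intensity`).
#' @param base logarithm base; the default `exp(1)` reports nats.
#' @return entropy >= 0.
#' @export
spectral_entropy <- function(spectrum, base = exp(1)) {
  inten <- if (inherits(spectrum, "centroid_spectrum"))
    spectrum$peaks$intensity else spectrum$intensity
  inten <- inten[inten > 0]
  if (!length(inten)) stop("spectral entropy of an empty spectrum")
  p <- inten / sum(inten)
  -sum(p * log(p, base = base))
}

#' Network / similarity parameters
#'
#' Preprocessing and matching constants for [modified_dot_product()] and
#' [build_network()]: peaks below the relative (fraction of base peak)
#' or absolute intensity cutoff are discarded, intensities are raised to
#' `scale_factor` and rescaled so the base peak equals `max_scale`, and
#' peaks are compared on a `binning`-Da grid with `tolerance`-Da
#' matching.
#'
#' @param relative_cutoff percent of base-peak intensity (default 0.1).
#' @param absolute_cutoff absolute intensity cutoff (default 50).
#' @param tolerance product-ion mass tolerance, Da (default 0.05).
#' @param binning mass binning value, Da (default 1.0).
#' @param scale_factor intensity scale exponent (default 0.5).
#' @param max_scale maximum scale value (default 100).
#' @param edge_threshold minimum similarity for a network edge.
#' @return a `network_params` list.
#' @export
network_params <- function(relative_cutoff = 0.1, absolute_cutoff = 50,
                           tolerance = 0.05, binning = 1.0,
                           scale_factor = 0.5, max_scale = 100,
                           edge_threshold = 0.7) {
  stopifnot(relative_cutoff >= 0, absolute_cutoff >= 0, tolerance >= 0,
            binning > 0, tolerance <= binning, scale_factor > 0,
            max_scale > 0)
  structure(list(relative_cutoff = relative_cutoff,
                 absolute_cutoff = absolute_cutoff, tolerance = tolerance,
                 binning = binning, scale_factor = scale_factor,
                 max_scale = max_scale, edge_threshold = edge_threshold),
            class = "network_params")
}

.preprocess_spectrum <- function(spectrum, params) {
  pk <- spectrum$peaks
  if (!nrow(pk)) return(pk)
  base <- max(pk$intensity)
  keep <- pk$intensity >= base * params$relative_cutoff / 100 &
    pk$intensity >= params$absolute_cutoff
  pk <- pk[keep, , drop = FALSE]
  if (!nrow(pk)) return(pk)
  inten <- pk$intensity^params$scale_factor
  inten <- inten / max(inten) * params$max_scale
  # collapse to the binning grid, keeping the intensity-weighted m/z
  bin <- floor(pk$mz / params$binning)
  data.frame(
    mz = as.numeric(tapply(pk$mz * inten, bin, sum) / tapply(inten, bin, sum)),
    intensity = as.numeric(tapply(inten, bin, sum)))
}

#' Modified dot product similarity
#'
#' Symmetric cosine similarity after the preprocessing of
#' [network_params()]: cutoffs, intensity scaling/rescaling and mass
#' binning, with peaks matched within the product-ion tolerance. 1 for
#' identical spectra, 0 for disjoint ones.
#'
#' @param a,b `centroid_spectrum`s.
#' @param params a [network_params()].
#' @return similarity in \[0, 1\].
#' @export
modified_dot_product <- function(a, b, params = network_params()) {
  pa <- .preprocess_spectrum(a, params)
  pb <- .preprocess_spectrum(b, params)
  if (!nrow(pa) || !nrow(pb)) {
    warning("spectrum empty after intensity cutoffs")
    return(0)
  }
  ia <- numeric(0); ib <- numeric(0)
  used <- rep(FALSE, nrow(pb))
  for (i in seq_len(nrow(pa))) {
    d <- abs(pb$mz - pa$mz[i])
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= params$tolerance) {
      ia <- c(ia, pa$intensity[i]); ib <- c(ib, pb$intensity[j])
      used[j] <- TRUE
    }
  }
  if (!length(ia)) return(0)
  sum(ia * ib) / (sqrt(sum(pa$intensity^2)) * sqrt(sum(pb$intensity^2)))
}

#' Build a molecular spectral network
#'
#' All unordered spectrum pairs with modified-dot-product similarity at
#' or above the edge threshold.
#'
#' @param spectra list of `centroid_spectrum` (>= 2).
#' @param params a [network_params()].
#' @return data.frame with columns `source`, `target`, `similarity`.
#' @export
build_network <- function(spectra, params = network_params()) {
  if (length(spectra) < 2L) stop("a network needs at least two spectra")
  nm <- names(spectra)
  if (is.null(nm)) nm <- as.character(seq_along(spectra))
  edges <- list()
  for (i in seq_len(length(spectra) - 1L)) {
    for (j in (i + 1L):length(spectra)) {
      sim <- suppressWarnings(modified_dot_product(spectra[[i]], spectra[[j]],
                                                   params))
      if (sim >= params$edge_threshold) {
        edges[[length(edges) + 1L]] <- data.frame(
          source = nm[i], target = nm[j], similarity = sim,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(edges)) {
    return(data.frame(source = character(0), target = character(0),
                      similarity = numeric(0)))
  }
  do.call(rbind, edges)
}
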