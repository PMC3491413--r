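#' Configuration for synthetic chromatograms
#'
#' Each species receives one Gaussian elution peak whose area is its
#' weight times the total ion current, sampled on a shared dense
#' retention-time grid with optional multiplicative noise.
#'
#' @param weights named non-negative weights over the species, summing
#'   to 1.
#' @param peakCenters retention-time centers (min); default 2 min apart
#'   starting at 10.
#' @param peakWidths Gaussian sigma per peak (min), recycled.
#' @param totalIonCurrent summed true peak area over all species.
#' @param noiseSdFraction per-sample multiplicative noise SD.
#' @param rtStep grid step in minutes.
#' @param seed integer seed.
#' @return a validated config (list).
#' @export
simMSConfig <- function(weights, peakCenters = NULL, peakWidths = 0.15,
                        totalIonCurrent = 1e6, noiseSdFraction = 0,
                        rtStep = 0.005, seed = 1) {
  stopIfNot(!is.null(names(weights)) && all(nzchar(names(weights))),
            "weights must be named by species")
  stopIfNot(all(weights >= 0), "weights must be non-negative")
  stopIfNot(abs(sum(weights) - 1) < 1e-8, "weights must sum to 1")
  k <- length(weights)
  if (is.null(peakCenters)) peakCenters <- 10 + 2 * (seq_len(k) - 1)
  peakWidths <- rep_len(peakWidths, k)
  stopIfNot(all(peakWidths > 0), "peak widths must be positive")
  structure(list(weights = weights, peakCenters = peakCenters,
                 peakWidths = peakWidths,
                 totalIonCurrent = totalIonCurrent,
                 noiseSdFraction = noiseSdFraction, rtStep = rtStep,
                 seed = as.integer(seed)),
            class = "SimMSConfig")
}

#' Simulate extracted ion chromatograms with known areas
#'
#' @param config a \code{\link{simMSConfig}}.
#' @return list with \code{chromatograms} (one
#'   \linkS4class{Chromatogram} per species) and \code{truth} (true
#'   areas and weights). Deterministic for a fixed seed.
#' @export
simulateXic <- function(config) {
  stopIfNot(inherits(config, "SimMSConfig"),
            "config must come from simMSConfig()")
  w <- config$weights
  lo <- max(0, min(config$peakCenters - 8 * config$peakWidths))
  hi <- max(config$peakCenters + 8 * config$peakWidths)
  rt <- seq(lo, hi, by = config$rtStep)
  withSeed(subSeed(config$seed, "xic"), {
    chroms <- lapply(seq_along(w), function(i) {
      base <- config$totalIonCurrent * w[i] *
        stats::dnorm(rt, config$peakCenters[i], config$peakWidths[i])
      if (config$noiseSdFraction > 0)
        base <- pmax(base * (1 + stats::rnorm(length(rt), 0,
                                              config$noiseSdFraction)), 0)
      chromatogram(names(w)[i], rt, base)
    })
    names(chroms) <- names(w)
    list(chromatograms = chroms,
         truth = list(areas = config$totalIonCurrent * w, weights = w))
  })
}

#' Simulate a composite b-ion spectrum from known isomer weights
#'
#' Isomer labels name the acetylated site(s), e.g. \code{"K7"} for a
#' monoacetyl isomer or \code{"K4+K11"} for a diacetyl pair; all isomers
#' must carry the same number of acetyls. At each site the acetyl and
#' propionyl ion currents equal the weight-implied expected fractions of
#' the per-site current, times optional multiplicative noise.
#'
#' @param weights named non-negative isomer weights summing to 1.
#' @param sites full site set (default the five H2A.Z tail lysines).
#' @param acetylCount expected acetyls per isomer (1 or 2); checked
#'   against the labels, inferred when \code{NULL}.
#' @param noiseSdFraction multiplicative noise SD on each current.
#' @param siteCurrent total informative b-ion current per site.
#' @param seed integer seed.
#' @return list with \code{spectrum} (\linkS4class{CompositeSpectrum})
#'   and \code{truth} (per-site marginal occupancies, summing to the
#'   acetyl count, and the weights).
#' @export
simulateCompositeSpectrum <- function(weights,
                                      sites = c("K4", "K7", "K11",
                                                "K13", "K15"),
                                      acetylCount = NULL,
                                      noiseSdFraction = 0,
                                      siteCurrent = 1e6, seed = 1) {
  stopIfNot(!is.null(names(weights)), "weights must be named by isomer")
  stopIfNot(all(weights >= 0) && abs(sum(weights) - 1) < 1e-8,
            "weights must be simplex-valued")
  parts <- strsplit(names(weights), "+", fixed = TRUE)
  sizes <- lengths(parts)
  if (length(unique(sizes)) != 1L)
    stop("all isomers must carry the same number of acetyls")
  if (is.null(acetylCount)) acetylCount <- sizes[1]
  if (acetylCount != sizes[1])
    stop("acetyl count ", acetylCount,
         " inconsistent with the isomer set (labels carry ", sizes[1],
         ")")
  bad <- setdiff(unlist(parts), sites)
  if (length(bad))
    stop("isomer site(s) not in the site set: ",
         paste(bad, collapse = ", "))
  f <- vapply(sites, function(s)
    sum(weights[vapply(parts, function(p) s %in% p, TRUE)]), 0)
  withSeed(subSeed(seed, "spec"), {
    noise <- function(x) {
      if (noiseSdFraction > 0)
        pmax(x * (1 + stats::rnorm(length(x), 0, noiseSdFraction)), 0)
      else x
    }
    spec <- compositeSpectrum(sites, noise(siteCurrent * f),
                              noise(siteCurrent * (1 - f)))
    list(spectrum = spec,
         truth = list(marginals = stats::setNames(f, sites),
                      weights = weights))
  })
}
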