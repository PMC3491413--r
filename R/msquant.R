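#' Construct a chromatogram
#' @param species species label.
#' @param rt retention times (min, strictly increasing).
#' @param intensity intensities (>= 0), same length.
#' @return a \linkS4class{Chromatogram}.
#' @export
chromatogram <- function(species, rt, intensity)
  new("Chromatogram", species = as.character(species),
      rt = as.numeric(rt), intensity = as.numeric(intensity))

#' Construct a composite b-ion spectrum
#' @param sites site labels.
#' @param acetylCurrent,propionylCurrent per-site ion currents of the
#'   acetylated and d5-propionylated (non-acetylated) forms.
#' @return a \linkS4class{CompositeSpectrum}.
#' @export
compositeSpectrum <- function(sites, acetylCurrent, propionylCurrent)
  new("CompositeSpectrum", sites = as.character(sites),
      acetylCurrent = as.numeric(acetylCurrent),
      propionylCurrent = as.numeric(propionylCurrent))

#' Integrate a chromatographic peak
#'
#' Trapezoidal integral of the intensity over a retention-time window.
#' With \code{bounds = NULL} the window is chosen valley-to-valley around
#' the global maximum: walking outward from the peak, the bound is the
#' first local minimum whose intensity falls below 5\% of the peak
#' height, or the trace edge. Integration is linear: scaling the trace
#' scales the area.
#'
#' @param chrom a \linkS4class{Chromatogram}.
#' @param bounds numeric length-2 retention-time window, or \code{NULL}
#'   for automatic valley-to-valley bounds.
#' @param valleyFraction valley threshold as a fraction of peak height.
#' @return the integrated area. An all-zero trace returns 0 with a
#'   warning.
#' @export
integratePeak <- function(chrom, bounds = NULL, valleyFraction = 0.05) {
  y <- chrom@intensity
  x <- chrom@rt
  if (max(y) == 0) {
    warning("all-zero chromatogram '", chrom@species, "'; area 0")
    return(0)
  }
  if (!is.null(bounds)) {
    stopIfNot(length(bounds) == 2L && bounds[1] < bounds[2],
              "bounds must be an increasing length-2 window")
    stopIfNot(bounds[1] >= x[1] && bounds[2] <= x[length(x)],
              "bounds must lie within the trace extent")
    keep <- x >= bounds[1] & x <= bounds[2]
    stopIfNot(sum(keep) >= 2, "bounds contain fewer than two samples")
    return(pracma::trapz(x[keep], y[keep]))
  }
  peak <- which.max(y)
  thr <- valleyFraction * y[peak]
  l <- peak
  while (l > 1L && !(y[l] < thr && y[l] <= y[l - 1L])) l <- l - 1L
  r <- peak
  n <- length(y)
  while (r < n && !(y[r] < thr && y[r] <= y[r + 1L])) r <- r + 1L
  pracma::trapz(x[l:r], y[l:r])
}

#' Positional-isomer fractions from extracted ion chromatograms
#'
#' Integrates each species' XIC and normalizes the areas to sum to one,
#' the standard area-fraction quantification of co-measured positional
#' isomers (e.g. ubiquitin acceptor sites K120/K121/K125).
#'
#' @param chroms list of \linkS4class{Chromatogram}s (or a single one).
#' @param bounds optional common integration window passed to
#'   \code{\link{integratePeak}}.
#' @return an \linkS4class{IsomerQuant}. All-zero areas are an error.
#' @export
isomerFractions <- function(chroms, bounds = NULL) {
  if (is(chroms, "Chromatogram")) chroms <- list(chroms)
  stopIfNot(length(chroms) >= 1, "need at least one chromatogram")
  areas <- vapply(chroms, function(ch)
    suppressWarnings(integratePeak(ch, bounds)), 0)
  labels <- vapply(chroms, function(ch) ch@species, "")
  total <- sum(areas)
  if (total <= 0) stop("all chromatogram areas are zero")
  new("IsomerQuant", labels = labels, areas = areas,
      fractions = areas / total)
}

#' Precursor-level acetyl stoichiometry
#'
#' Normalized area fractions of the tryptic N-terminal precursor forms
#' bearing zero to four acetyls, and the derived total acetylation
#' ("any acetyl" = 1 - fraction of the 0ac form).
#'
#' @param chroms list of five \linkS4class{Chromatogram}s labelled
#'   \code{"0ac".."4ac"} (any order).
#' @param bounds optional integration window.
#' @return list with \code{quant} (\linkS4class{IsomerQuant} ordered
#'   0ac..4ac), \code{fractions} (named vector) and \code{anyAcetyl}.
#' @export
precursorAcetylDistribution <- function(chroms, bounds = NULL) {
  labels <- vapply(chroms, function(ch) ch@species, "")
  wanted <- paste0(0:4, "ac")
  missing <- setdiff(wanted, labels)
  if (length(missing))
    stop("missing precursor form(s): ", paste(missing, collapse = ", "))
  stopIfNot(length(chroms) == 5L, "exactly five labelled traces required")
  chroms <- chroms[match(wanted, labels)]
  q <- isomerFractions(chroms, bounds)
  fr <- stats::setNames(q@fractions, q@labels)
  list(quant = q, fractions = fr, anyAcetyl = unname(1 - fr["0ac"]))
}

#' Monoacetyl site occupancy from a composite b-ion spectrum
#'
#' The raw proxy for acetylation at site k is the acetyl share of the
#' informative b-ion current, \code{r_k = ac_k / (ac_k + prop_k)}. Since
#' a monoacetyl precursor carries exactly one acetyl, occupancies are the
#' proxies renormalized to unit sum; both are returned.
#'
#' @param spec a \linkS4class{CompositeSpectrum} of the monoacetyl
#'   precursor.
#' @return list with \code{raw} proxies and \code{occupancy} (sums to 1),
#'   both named by site.
#' @export
monoacetylSiteOccupancy <- function(spec) {
  tot <- spec@acetylCurrent + spec@propionylCurrent
  dead <- spec@sites[tot == 0]
  if (length(dead))
    stop("no ion current at site(s): ", paste(dead, collapse = ", "))
  r <- spec@acetylCurrent / tot
  if (sum(r) == 0) stop("no acetyl signal at any site")
  list(raw = stats::setNames(r, spec@sites),
       occupancy = stats::setNames(r / sum(r), spec@sites))
}

# Euclidean projection of v onto the probability simplex (Duchi et al.).
projectSimplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Deconvolute diacetyl positional isomers from a composite spectrum
#'
#' Co-eluting diacetyl positional isomers are modelled as a mixture over
#' the site pairs: the expected acetyl-current fraction at site k is the
#' summed weight of the pairs containing k. Non-negative pair weights on
#' the probability simplex are fitted by least squares (projected
#' gradient descent on the convex objective), and per-site marginal
#' occupancies \code{o_k = sum of w_p over pairs containing k} (summing
#' to 2, one per acetyl group) are reported as the primary output. With
#' 5 sites the 10 pair weights are generally not identifiable from 5
#' marginals; \code{nonUnique} flags this, and the marginals remain
#' well-determined.
#'
#' @param spec a \linkS4class{CompositeSpectrum} of the diacetyl
#'   precursor.
#' @param maxIter,tol projected-gradient iteration controls.
#' @return list with \code{weights} (named by pair, sums to 1),
#'   \code{marginals} (named by site, sums to 2), \code{perAcetyl}
#'   (marginals / 2), \code{objective} (residual sum of squares),
#'   \code{observed} per-site acetyl fractions, and \code{nonUnique}.
#' @export
diacetylDeconvolution <- function(spec, maxIter = 20000, tol = 1e-14) {
  tot <- spec@acetylCurrent + spec@propionylCurrent
  dead <- spec@sites[tot == 0]
  if (length(dead))
    stop("no ion current at site(s): ", paste(dead, collapse = ", "))
  f <- spec@acetylCurrent / tot
  if (sum(f) == 0) stop("infeasible spectrum: no acetyl signal anywhere")
  n <- length(spec@sites)
  stopIfNot(n >= 2, "need at least two sites for diacetyl modelling")
  pairs <- utils::combn(n, 2)
  P <- ncol(pairs)
  A <- matrix(0, n, P)
  for (p in seq_len(P)) A[pairs[, p], p] <- 1
  L <- 2 * max(eigen(crossprod(A), symmetric = TRUE,
                     only.values = TRUE)$values)
  w <- rep(1 / P, P)
  for (it in seq_len(maxIter)) {
    g <- 2 * crossprod(A, A %*% w - f)
    wNew <- projectSimplex(w - as.vector(g) / L)
    if (max(abs(wNew - w)) < tol) { w <- wNew; break }
    w <- wNew
  }
  marg <- as.vector(A %*% w)
  obj <- sum((marg - f)^2)
  pairNames <- apply(pairs, 2, function(ij)
    paste(spec@sites[ij], collapse = "+"))
  list(weights = stats::setNames(w, pairNames),
       marginals = stats::setNames(marg, spec@sites),
       perAcetyl = stats::setNames(marg / 2, spec@sites),
       objective = obj,
       observed = stats::setNames(f, spec@sites),
       nonUnique = sum(w > 1e-8) > qr(A)$rank)
}

#' Knockout / wild-type abundance ratio of ubiquityl peptides
#'
#' Ratio of summed integrated XIC areas (KO over WT) across the
#' positional-isomer traces, with a qualitative "dramatically reduced"
#' flag below a configurable threshold.
#'
#' @param wt,ko lists of \linkS4class{Chromatogram}s for the wild-type
#'   and knockout samples.
#' @param reducedThreshold flag threshold on the ratio (default 0.2).
#' @param bounds optional integration window.
#' @return list with \code{ratio}, \code{reduced}, \code{wtTotal},
#'   \code{koTotal}. A zero WT total is an error.
#' @export
koAbundanceRatio <- function(wt, ko, reducedThreshold = 0.2,
                             bounds = NULL) {
  if (is(wt, "Chromatogram")) wt <- list(wt)
  if (is(ko, "Chromatogram")) ko <- list(ko)
  wtTotal <- sum(vapply(wt, function(ch)
    suppressWarnings(integratePeak(ch, bounds)), 0))
  koTotal <- sum(vapply(ko, function(ch)
    suppressWarnings(integratePeak(ch, bounds)), 0))
  if (wtTotal <= 0) stop("wild-type total area is zero")
  ratio <- koTotal / wtTotal
  list(ratio = ratio, reduced = ratio < reducedThreshold,
       wtTotal = wtTotal, koTotal = koTotal)
}

#' Assemble the full acetyl stoichiometry of the H2A.Z tail
#'
#' Combines the precursor-level 0-4ac distribution with site-resolved
#' occupancies of the mono- and diacetyl pools into one object.
#'
#' @param precursorChroms five \code{0ac..4ac} chromatograms.
#' @param monoSpec optional monoacetyl \linkS4class{CompositeSpectrum}.
#' @param diSpec optional diacetyl \linkS4class{CompositeSpectrum}.
#' @param bounds optional integration window for the precursors.
#' @return an \linkS4class{AcetylStoichiometry}.
#' @export
acetylStoichiometry <- function(precursorChroms, monoSpec = NULL,
                                diSpec = NULL, bounds = NULL) {
  pre <- precursorAcetylDistribution(precursorChroms, bounds)
  mono <- if (is.null(monoSpec)) numeric() else
    monoacetylSiteOccupancy(monoSpec)$occupancy
  if (is.null(diSpec)) {
    dm <- numeric(); dw <- numeric(); nu <- FALSE
  } else {
    d <- diacetylDeconvolution(diSpec)
    dm <- d$marginals; dw <- d$weights; nu <- d$nonUnique
  }
  new("AcetylStoichiometry", precursor = pre$quant,
      anyAcetyl = pre$anyAcetyl, monoOccupancy = mono,
      diMarginals = dm, diWeights = dw, diWeightsNonUnique = nu)
}
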