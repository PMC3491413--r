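#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import GenomeInfoDb
NULL

#' Windowed read-count scan of a genome
#'
#' Container for a sliding-window scan: one row per window, with the
#' per-window read (fragment-midpoint) count and, after scoring against a
#' null model, the expected count \code{lambda} and upper-tail P-value.
#'
#' @slot windows \code{GRanges} of the windows, tiling each chromosome at
#'   the stated step, with metadata column \code{count} and (after
#'   \code{\link{scoreWindows}}) \code{lambda} and \code{pvalue}.
#' @slot windowSize window width in bp.
#' @slot step distance between successive window starts in bp.
#' @slot nPoints number of counting points (fragment midpoints) scanned.
#'
#' @seealso \code{\link{scanWindows}}, \code{\link{scoreWindows}},
#'   \code{\link{callEnriched}}
#' @export
setClass("WindowScan",
  slots = c(
    windows = "GRanges",
    windowSize = "integer",
    step = "integer",
    nPoints = "integer"
  )
)

setValidity("WindowScan", function(object) {
  msg <- character()
  if (length(object@windowSize) != 1L || object@windowSize < 1L)
    msg <- c(msg, "windowSize must be a single positive integer")
  if (length(object@step) != 1L || object@step < 1L)
    msg <- c(msg, "step must be a single positive integer")
  mc <- mcols(object@windows)
  if (!"count" %in% colnames(mc))
    msg <- c(msg, "windows must carry a 'count' metadata column")
  else if (any(mc$count < 0))
    msg <- c(msg, "window counts must be non-negative")
  if ("pvalue" %in% colnames(mc)) {
    p <- mc$pvalue
    if (any(p < 0 | p > 1)) msg <- c(msg, "P-values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Null model for window counts
#'
#' Background distribution of per-window counts used to assign upper-tail
#' P-values. Either a Poisson model with genome-wide uniform rate, or a
#' pooled empirical null built by re-placing the observed points uniformly
#' at random over the genome several times.
#'
#' @slot mode \code{"poisson"} or \code{"empirical"}.
#' @slot lambda expected count per window under genome-wide uniformity.
#' @slot nullCounts pooled randomized window counts (empirical mode;
#'   empty for poisson mode).
#' @slot nRandomizations number of randomizations pooled (empirical mode).
#' @slot windowSize window width the null refers to, in bp.
#'
#' @seealso \code{\link{nullRate}}, \code{\link{pvalueTail}}
#' @export
setClass("NullModel",
  slots = c(
    mode = "character",
    lambda = "numeric",
    nullCounts = "integer",
    nRandomizations = "integer",
    windowSize = "integer"
  )
)

setValidity("NullModel", function(object) {
  msg <- character()
  if (!object@mode %in% c("poisson", "empirical"))
    msg <- c(msg, "mode must be 'poisson' or 'empirical'")
  if (object@lambda <= 0)
    msg <- c(msg, "lambda must be positive")
  if (object@mode == "empirical" && length(object@nullCounts) == 0L)
    msg <- c(msg, "empirical null requires pooled null counts")
  if (length(msg)) msg else TRUE
})

#' Set of merged enriched intervals for one ChIP mark
#'
#' Windows significant against the null (upper-tail P strictly below
#' \code{alpha}) merged into maximal intervals: two significant windows are
#' joined when the distance between them (next start minus previous end) is
#' strictly less than \code{mergeGap}.
#'
#' @slot mark name of the ChIP mark (e.g. \code{"H2A.Z"}).
#' @slot alpha significance threshold on the per-window tail P-value.
#' @slot mergeGap merge distance in bp (strictly-less-than rule).
#' @slot intervals sorted, disjoint \code{GRanges} of merged intervals.
#' @slot nSignificantWindows number of windows below \code{alpha}.
#'
#' @seealso \code{\link{callEnriched}}
#' @export
setClass("EnrichedWindowSet",
  slots = c(
    mark = "character",
    alpha = "numeric",
    mergeGap = "integer",
    intervals = "GRanges",
    nSignificantWindows = "integer"
  )
)

setValidity("EnrichedWindowSet", function(object) {
  msg <- character()
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in [0, 1]")
  gr <- object@intervals
  if (length(gr) > 1L) {
    if (GenomicRanges::isDisjoint(gr) == FALSE)
      msg <- c(msg, "merged intervals must be disjoint")
    if (S4Vectors::isSorted(gr) == FALSE)
      msg <- c(msg, "merged intervals must be sorted")
  }
  if (length(msg)) msg else TRUE
})

#' TSS-anchored signal matrix
#'
#' Regions-by-bins matrix of ChIP signal around anchors (typically TSSs),
#' reads-per-million scaled, strand-oriented so that bin order always runs
#' 5' to 3' relative to the anchored feature. Bins that would fall outside
#' the chromosome are \code{NA}.
#'
#' @slot values numeric matrix, regions x bins, in reads per million.
#' @slot counts integer matrix of raw midpoint counts (same shape).
#' @slot binCenters bp offsets of bin centers relative to the anchor.
#' @slot binSize bin width in bp.
#' @slot span half-width of the profiled region in bp.
#' @slot librarySize total number of counting points used for scaling.
#'
#' @seealso \code{\link{profileMatrix}}, \code{\link{composite}}
#' @export
setClass("ProfileMatrix",
  slots = c(
    values = "matrix",
    counts = "matrix",
    binCenters = "numeric",
    binSize = "integer",
    span = "integer",
    librarySize = "numeric"
  )
)

setValidity("ProfileMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@binCenters))
    msg <- c(msg, "column count must equal number of bin centers")
  if (!identical(dim(object@values), dim(object@counts)))
    msg <- c(msg, "values and counts must have identical shape")
  if (ncol(object@values) != 2L * object@span / object@binSize)
    msg <- c(msg, "column count must equal 2*span/binSize")
  if (any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "signal values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Composite (metagene) profile
#'
#' Per-bin arithmetic mean of a \linkS4class{ProfileMatrix} over a region
#' subset, ignoring out-of-bounds (\code{NA}) bins.
#'
#' @slot binCenters bp offsets of bin centers relative to the anchor.
#' @slot mean mean signal per bin (reads per million).
#' @slot nRegions number of regions averaged.
#' @export
setClass("CompositeProfile",
  slots = c(
    binCenters = "numeric",
    mean = "numeric",
    nRegions = "integer"
  )
)

setValidity("CompositeProfile", function(object) {
  if (length(object@binCenters) != length(object@mean))
    "mean must have one entry per bin" else TRUE
})

#' Extracted ion chromatogram
#'
#' Intensity versus retention time for one species (a positional isomer,
#' or an n-acetyl precursor form).
#'
#' @slot species label of the species the trace was extracted for.
#' @slot rt retention time in minutes, strictly increasing.
#' @slot intensity ion intensity (arbitrary units, non-negative).
#' @export
setClass("Chromatogram",
  slots = c(
    species = "character",
    rt = "numeric",
    intensity = "numeric"
  )
)

setValidity("Chromatogram", function(object) {
  msg <- character()
  if (length(object@rt) != length(object@intensity))
    msg <- c(msg, "rt and intensity must have equal length")
  if (length(object@rt) < 2L)
    msg <- c(msg, "a chromatogram needs at least two samples")
  if (any(diff(object@rt) <= 0))
    msg <- c(msg, "retention times must be strictly increasing")
  if (any(object@intensity < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Normalized positional-isomer quantification
#'
#' Integrated peak areas over a set of positional isomers (ubiquitin
#' acceptor sites, or n-acetyl precursor forms) and the area fractions,
#' normalized to sum to one.
#'
#' @slot labels isomer labels.
#' @slot areas integrated areas, same length as labels.
#' @slot fractions areas normalized to unit sum.
#' @export
setClass("IsomerQuant",
  slots = c(
    labels = "character",
    areas = "numeric",
    fractions = "numeric"
  )
)

setValidity("IsomerQuant", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (length(object@areas) != n || length(object@fractions) != n)
    msg <- c(msg, "labels, areas and fractions must have equal length")
  if (any(object@fractions < 0))
    msg <- c(msg, "fractions must be non-negative")
  if (n > 0L && abs(sum(object@fractions) - 1) > 1e-9)
    msg <- c(msg, "fractions must sum to 1 (within 1e-9)")
  if (length(msg)) msg else TRUE
})

#' Composite b-ion spectrum summarised per site
#'
#' For each potentially acetylated lysine, the ion current of the
#' acetylated form and of the d5-propionylated (non-acetylated) form of
#' its informative b-series fragment ions, averaged across the elution
#' frame. Positional isomers that co-elute are quantified from this
#' object rather than from chromatographic separation.
#'
#' @slot sites site labels, e.g. \code{c("K4","K7","K11","K13","K15")}.
#' @slot acetylCurrent ion current of the acetylated form per site.
#' @slot propionylCurrent ion current of the propionylated form per site.
#' @export
setClass("CompositeSpectrum",
  slots = c(
    sites = "character",
    acetylCurrent = "numeric",
    propionylCurrent = "numeric"
  )
)

setValidity("CompositeSpectrum", function(object) {
  msg <- character()
  n <- length(object@sites)
  if (length(object@acetylCurrent) != n ||
      length(object@propionylCurrent) != n)
    msg <- c(msg, "per-site currents must match the number of sites")
  if (any(object@acetylCurrent < 0) || any(object@propionylCurrent < 0))
    msg <- c(msg, "ion currents must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Pairwise interval-set overlap report
#'
#' Counts of intervals in each set that overlap at least one interval of
#' the other set (an interval counts once no matter how many partners it
#' touches), with the corresponding fractions.
#'
#' @slot nA,nB set sizes.
#' @slot nAOverlapping,nBOverlapping counts of overlapping intervals.
#' @slot fractionA,fractionB overlapping fractions.
#' @slot minOverlap minimum overlap in bp required to count.
#' @export
setClass("OverlapReport",
  slots = c(
    nA = "integer", nB = "integer",
    nAOverlapping = "integer", nBOverlapping = "integer",
    fractionA = "numeric", fractionB = "numeric",
    minOverlap = "integer"
  )
)

setValidity("OverlapReport", function(object) {
  msg <- character()
  if (object@nAOverlapping > object@nA || object@nBOverlapping > object@nB)
    msg <- c(msg, "overlap counts cannot exceed set sizes")
  fr <- c(object@fractionA, object@fractionB)
  if (any(!is.na(fr) & (fr < 0 | fr > 1)))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Acetylation stoichiometry of the H2A.Z N-terminal tail
#'
#' Bundles the precursor-level distribution over 0-4 acetyl forms with
#' the site-resolved occupancies of the mono- and diacetyl pools.
#'
#' @slot precursor \linkS4class{IsomerQuant} over the 0ac..4ac precursors.
#' @slot anyAcetyl fraction of molecules carrying at least one acetyl.
#' @slot monoOccupancy per-site occupancy of the monoacetyl pool
#'   (sums to 1), or empty if not measured.
#' @slot diMarginals per-site marginal occupancy of the diacetyl pool
#'   (sums to 2), or empty.
#' @slot diWeights fitted weights over site pairs (sums to 1), or empty.
#' @slot diWeightsNonUnique flag: the pair weights are not uniquely
#'   determined by the per-site marginals.
#' @export
setClass("AcetylStoichiometry",
  slots = c(
    precursor = "IsomerQuant",
    anyAcetyl = "numeric",
    monoOccupancy = "numeric",
    diMarginals = "numeric",
    diWeights = "numeric",
    diWeightsNonUnique = "logical"
  )
)

setValidity("AcetylStoichiometry", function(object) {
  msg <- character()
  if (length(object@anyAcetyl) != 1L ||
      object@anyAcetyl < 0 || object@anyAcetyl > 1)
    msg <- c(msg, "anyAcetyl must be a single value in [0, 1]")
  if (length(object@monoOccupancy) &&
      abs(sum(object@monoOccupancy) - 1) > 1e-6)
    msg <- c(msg, "monoacetyl occupancies must sum to 1")
  if (length(object@diMarginals) &&
      abs(sum(object@diMarginals) - 2) > 1e-6)
    msg <- c(msg, "diacetyl marginals must sum to 2")
  if (length(msg)) msg else TRUE
})
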