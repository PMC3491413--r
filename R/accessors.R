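#' @describeIn WindowScan-class windows as a \code{GRanges} with count /
#'   lambda / pvalue metadata columns.
#' @param x,object a \linkS4class{WindowScan}.
#' @export
setGeneric("scanWindowsGR", function(x) standardGeneric("scanWindowsGR"))

#' @export
setMethod("scanWindowsGR", "WindowScan", function(x) x@windows)

#' Per-window read counts
#' @param x a \linkS4class{WindowScan}.
#' @return integer vector of counts, one per window.
#' @export
setGeneric("windowCounts", function(x) standardGeneric("windowCounts"))

#' @export
setMethod("windowCounts", "WindowScan", function(x) mcols(x@windows)$count)

#' Per-window tail P-values (after scoring)
#' @param x a \linkS4class{WindowScan}.
#' @return numeric vector of P-values, or NULL before scoring.
#' @export
setGeneric("windowPvalues", function(x) standardGeneric("windowPvalues"))

#' @export
setMethod("windowPvalues", "WindowScan", function(x) mcols(x@windows)$pvalue)

#' Merged enriched intervals
#' @param x an \linkS4class{EnrichedWindowSet}.
#' @return sorted disjoint \code{GRanges}.
#' @export
setGeneric("enrichedIntervals",
  function(x) standardGeneric("enrichedIntervals"))

#' @export
setMethod("enrichedIntervals", "EnrichedWindowSet", function(x) x@intervals)

#' Mark name of an enriched-interval set
#' @param x an \linkS4class{EnrichedWindowSet}.
#' @export
setGeneric("markName", function(x) standardGeneric("markName"))

#' @export
setMethod("markName", "EnrichedWindowSet", function(x) x@mark)

#' Signal matrix in reads per million
#' @param x a \linkS4class{ProfileMatrix}.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @export
setMethod("profileValues", "ProfileMatrix", function(x) x@values)

#' Raw count matrix of a profile
#' @param x a \linkS4class{ProfileMatrix}.
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @export
setMethod("profileCounts", "ProfileMatrix", function(x) x@counts)

#' Bin centers relative to the anchor
#' @param x a \linkS4class{ProfileMatrix} or \linkS4class{CompositeProfile}.
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @export
setMethod("binCenters", "ProfileMatrix", function(x) x@binCenters)

#' @export
setMethod("binCenters", "CompositeProfile", function(x) x@binCenters)

#' Mean signal per bin of a composite profile
#' @param x a \linkS4class{CompositeProfile}.
#' @export
setGeneric("compositeMean", function(x) standardGeneric("compositeMean"))

#' @export
setMethod("compositeMean", "CompositeProfile", function(x) x@mean)

#' Isomer fractions (areas normalized to unit sum)
#' @param x an \linkS4class{IsomerQuant}.
#' @return named numeric vector of fractions.
#' @export
setGeneric("isomerFractionsOf",
  function(x) standardGeneric("isomerFractionsOf"))

#' @export
setMethod("isomerFractionsOf", "IsomerQuant",
  function(x) stats::setNames(x@fractions, x@labels))

#' Integrated areas underlying an isomer quantification
#' @param x an \linkS4class{IsomerQuant}.
#' @export
setGeneric("isomerAreas", function(x) standardGeneric("isomerAreas"))

#' @export
setMethod("isomerAreas", "IsomerQuant",
  function(x) stats::setNames(x@areas, x@labels))

setMethod("show", "WindowScan", function(object) {
  cat("WindowScan:", length(object@windows), "windows of",
      object@windowSize, "bp (step", object@step, "bp),",
      object@nPoints, "points\n")
  if (!is.null(windowPvalues(object)))
    cat("  scored: min P =",
        format(min(windowPvalues(object)), digits = 3), "\n")
})

setMethod("show", "NullModel", function(object) {
  cat("NullModel (", object@mode, "): lambda = ",
      format(object@lambda, digits = 4), " per ",
      object@windowSize, "-bp window\n", sep = "")
  if (object@mode == "empirical")
    cat("  pooled counts:", length(object@nullCounts), "from",
        object@nRandomizations, "randomizations\n")
})

setMethod("show", "EnrichedWindowSet", function(object) {
  cat("EnrichedWindowSet '", object@mark, "': ",
      length(object@intervals), " merged intervals (",
      object@nSignificantWindows, " significant windows, alpha = ",
      format(object@alpha), ", merge gap < ", object@mergeGap,
      " bp)\n", sep = "")
})

setMethod("show", "ProfileMatrix", function(object) {
  cat("ProfileMatrix:", nrow(object@values), "regions x",
      ncol(object@values), "bins of", object@binSize,
      "bp spanning +/-", object@span, "bp (RPM, library size",
      object@librarySize, ")\n")
})

setMethod("show", "CompositeProfile", function(object) {
  cat("CompositeProfile over", object@nRegions, "regions,",
      length(object@mean), "bins; peak",
      format(max(object@mean, na.rm = TRUE), digits = 4), "RPM\n")
})

setMethod("show", "Chromatogram", function(object) {
  cat("Chromatogram '", object@species, "': ", length(object@rt),
      " samples, rt ", format(min(object@rt)), "-",
      format(max(object@rt)), " min\n", sep = "")
})

setMethod("show", "IsomerQuant", function(object) {
  cat("IsomerQuant over", length(object@labels), "species:\n")
  print(round(stats::setNames(object@fractions, object@labels), 4))
})

setMethod("show", "CompositeSpectrum", function(object) {
  cat("CompositeSpectrum over sites:",
      paste(object@sites, collapse = ", "), "\n")
})

setMethod("show", "OverlapReport", function(object) {
  cat("OverlapReport: ", object@nAOverlapping, "/", object@nA,
      " of A (", format(object@fractionA, digits = 4), "), ",
      object@nBOverlapping, "/", object@nB, " of B (",
      format(object@fractionB, digits = 4), ")\n", sep = "")
})

setMethod("show", "AcetylStoichiometry", function(object) {
  cat("AcetylStoichiometry: any-acetyl fraction",
      format(object@anyAcetyl, digits = 4), "\n")
  print(round(stats::setNames(object@precursor@fractions,
                              object@precursor@labels), 4))
})
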