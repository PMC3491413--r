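#' Pairwise interval-set overlap (Venn) fractions
#'
#' Counts intervals of each set overlapping at least \code{minOverlap}
#' bp of any interval of the other set; an interval counts once no
#' matter how many partners it touches. Overlap is counted per region,
#' not per base pair.
#'
#' @param A,B interval sets (\code{GRanges} or
#'   \linkS4class{EnrichedWindowSet}).
#' @param minOverlap minimum overlap in bp (default 1).
#' @return an \linkS4class{OverlapReport}. Fractions of an empty set
#'   are \code{NaN}.
#' @export
overlapFraction <- function(A, B, minOverlap = 1) {
  a <- asIntervals(A); b <- asIntervals(B)
  aHit <- countOverlaps(a, b, minoverlap = minOverlap,
                        ignore.strand = TRUE) > 0
  bHit <- countOverlaps(b, a, minoverlap = minOverlap,
                        ignore.strand = TRUE) > 0
  new("OverlapReport",
      nA = length(a), nB = length(b),
      nAOverlapping = sum(aHit), nBOverlapping = sum(bHit),
      fractionA = if (length(a)) sum(aHit) / length(a) else NaN,
      fractionB = if (length(b)) sum(bHit) / length(b) else NaN,
      minOverlap = as.integer(minOverlap))
}

#' Extend intervals symmetrically
#'
#' @param gr a \code{GRanges}.
#' @param extension bp added on each side; clipped at chromosome bounds
#'   when lengths are known.
#' @return the extended \code{GRanges}.
#' @export
extendIntervals <- function(gr, extension) {
  s <- pmax(start(gr) - extension, 1)
  e <- end(gr) + extension
  len <- seqlengths(gr)[as.character(seqnames(gr))]
  e <- ifelse(is.na(len), e, pmin(e, len))
  GRanges(seqnames(gr), IRanges(s, e), strand = strand(gr),
          seqinfo = GenomeInfoDb::seqinfo(gr))
}

#' H2A.Z occupancy of intergenic MTLs
#'
#' Multiple transcription-factor binding loci (MTLs) are extended by
#' \code{extension} bp on each side, restricted to the intergenic subset
#' (at least \code{exclusion} bp from every promoter, TSS/TES and gene
#' body, the same rule as \code{\link{intergenicElements}}), and
#' intersected with the H2A.Z enriched intervals.
#'
#' @param mtls raw MTL \code{GRanges}.
#' @param genes gene \code{GRanges}.
#' @param h2az H2A.Z \linkS4class{EnrichedWindowSet} (or \code{GRanges}).
#' @param extension bp added on each side of an MTL (default 2000).
#' @param exclusion intergenic distance rule in bp (default 4000).
#' @param minOverlap minimum overlap in bp (default 1).
#' @param up,down promoter geometry, see \code{\link{promoterRegions}}.
#' @return list with \code{fraction} (intergenic MTLs occupied by
#'   H2A.Z), \code{nRaw}, \code{nIntergenic}, the \code{report}
#'   (\linkS4class{OverlapReport}) and the retained \code{intergenicMtls}.
#'   An empty intergenic subset is an error (explicit division by zero).
#' @export
mtlOccupancy <- function(mtls, genes, h2az, extension = 2000,
                         exclusion = 4000, minOverlap = 1,
                         up = 500, down = 2000) {
  ext <- extendIntervals(mtls, extension)
  zones <- if (length(genes))
    c(granges(promoterRegions(genes, up, down), use.mcols = FALSE),
      granges(genes)) else GRanges()
  strand(zones) <- "*"
  keep <- keepDistal(ext, zones, exclusion)
  inter <- ext[keep]
  if (length(inter) == 0L)
    stop("no intergenic MTLs remain after the ", exclusion,
         "-bp exclusion; occupancy fraction undefined")
  report <- overlapFraction(inter, asIntervals(h2az),
                            minOverlap = minOverlap)
  list(fraction = report@fractionA, nRaw = length(mtls),
       nIntergenic = length(inter), report = report,
       intergenicMtls = inter)
}
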