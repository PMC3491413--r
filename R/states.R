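# Accept either an EnrichedWindowSet or a plain GRanges of intervals.
asIntervals <- function(x) {
  if (is(x, "EnrichedWindowSet")) return(enrichedIntervals(x))
  if (is(x, "GRanges")) return(x)
  stop("expected an EnrichedWindowSet or GRanges, got ", class(x)[1])
}

#' Strand-aware promoter regions around annotated TSSs
#'
#' The promoter is 0.5 kb upstream to 2 kb downstream of the TSS by
#' default: \code{[tss - up, tss + down)} on the plus strand and
#' \code{[tss - down, tss + up)} on the minus strand (0-based half-open),
#' clipped at the chromosome boundaries. Each annotated TSS yields its
#' own promoter; promoters of neighbouring genes may overlap and are not
#' deduplicated.
#'
#' @param genes gene \code{GRanges} (see \code{\link{readGeneTable}}).
#' @param up bp upstream of the TSS (default 500).
#' @param down bp downstream of the TSS (default 2000).
#' @return \code{GRanges} of promoter regions, carrying \code{gene_id}.
#' @examples
#' g <- makeGeneTable("g1", "chr1", 10000, 15000, "+")
#' promoterRegions(g)  # bases 9500..11999 (0-based half-open)
#' @export
promoterRegions <- function(genes, up = 500, down = 2000) {
  t0 <- mcols(genes)$tss
  stopIfNot(!is.null(t0), "genes must carry a 'tss' column")
  plus <- as.character(strand(genes)) == "+"
  s0 <- ifelse(plus, t0 - up, t0 - down)
  e0 <- ifelse(plus, t0 + down, t0 + up)
  s0 <- pmax(s0, 0)
  len <- seqlengths(genes)[as.character(seqnames(genes))]
  e0 <- ifelse(is.na(len), e0, pmin(e0, len))
  out <- gr0(as.character(seqnames(genes)), s0, e0,
             strand = as.character(strand(genes)))
  if (!any(is.na(seqlengths(genes))))
    out <- applyLayout(out, seqlengths(genes))
  mcols(out)$gene_id <- mcols(genes)$gene_id
  out
}

#' Classify promoters into chromatin states
#'
#' A promoter is positive for a mark iff its region overlaps at least
#' \code{minOverlap} bp of any enriched interval of that mark. The state
#' is a pure function of the two flags: K4 only -> \code{K4-only}; both
#' -> \code{bivalent}; K27 only -> \code{K27-only}; neither ->
#' \code{no-mark}. Every input gene yields exactly one record.
#'
#' @param genes gene \code{GRanges}.
#' @param k4 H3K4me3 \linkS4class{EnrichedWindowSet} (or \code{GRanges}).
#' @param k27 H3K27me3 \linkS4class{EnrichedWindowSet} (or \code{GRanges}).
#' @param minOverlap minimum overlap in bp to count a mark (default 1).
#' @param up,down promoter geometry, see \code{\link{promoterRegions}}.
#' @return promoter \code{GRanges} with columns \code{gene_id},
#'   \code{k4}, \code{k27} and \code{state} (factor over
#'   \code{\link{chromatinStates}()}).
#' @export
classifyPromoters <- function(genes, k4, k27, minOverlap = 1,
                              up = 500, down = 2000) {
  prom <- promoterRegions(genes, up = up, down = down)
  k4f <- countOverlaps(prom, asIntervals(k4),
                       minoverlap = minOverlap) > 0
  k27f <- countOverlaps(prom, asIntervals(k27),
                        minoverlap = minOverlap) > 0
  state <- ifelse(k4f, ifelse(k27f, "bivalent", "K4-only"),
                  ifelse(k27f, "K27-only", "no-mark"))
  mcols(prom)$k4 <- k4f
  mcols(prom)$k27 <- k27f
  mcols(prom)$state <- factor(state, levels = chromatinStates())
  prom
}

#' Count promoters per chromatin state
#'
#' @param promoters output of \code{\link{classifyPromoters}}.
#' @return named integer vector over the four states; always partitions
#'   the gene universe.
#' @export
stateCounts <- function(promoters) {
  tab <- table(mcols(promoters)$state)
  stats::setNames(as.integer(tab), names(tab))
}

# Keep intervals whose distance to every exclusion zone is >= exclusion
# (distance 0 for any overlap or adjacency).
keepDistal <- function(iv, zones, exclusion) {
  if (length(zones) == 0L || length(iv) == 0L) return(rep(TRUE, length(iv)))
  hits <- distanceToNearest(iv, zones)
  keep <- rep(TRUE, length(iv))
  keep[queryHits(hits)] <- mcols(hits)$distance >= exclusion
  keep
}

#' Intergenic regulatory elements of a mark
#'
#' Retains enriched intervals at least \code{exclusion} bp (default
#' 4 kb) away from every promoter region and every gene body, to avoid
#' contamination by proximal or alternate promoters. Distance is the
#' number of bases between an interval and a zone; any overlap counts as
#' distance 0.
#'
#' @param marks \linkS4class{EnrichedWindowSet} (or \code{GRanges}).
#' @param genes gene \code{GRanges}; with an empty gene list all
#'   intervals are retained.
#' @param exclusion minimum distance in bp (default 4000).
#' @param up,down promoter geometry, see \code{\link{promoterRegions}}.
#' @return \code{GRanges} of the retained intergenic intervals.
#' @export
intergenicElements <- function(marks, genes, exclusion = 4000,
                               up = 500, down = 2000) {
  iv <- asIntervals(marks)
  zones <- if (length(genes))
    c(granges(promoterRegions(genes, up, down), use.mcols = FALSE),
      granges(genes)) else GRanges()
  strand(zones) <- "*"
  iv[keepDistal(iv, zones, exclusion)]
}

#' Chromatin-state transition table between two conditions
#'
#' Cross-tabulates promoter states of the same gene universe in two
#' classifications (e.g. stem cells versus neural progenitors), e.g. to
#' expose bivalent-to-K27-only resolution during differentiation.
#'
#' @param recordsA,recordsB outputs of \code{\link{classifyPromoters}}
#'   over the same gene ids.
#' @return 4x4 contingency matrix (rows: state in A, columns: state in
#'   B); entries sum to the number of shared genes.
#' @export
stateTransitionTable <- function(recordsA, recordsB) {
  idsA <- mcols(recordsA)$gene_id
  idsB <- mcols(recordsB)$gene_id
  onlyA <- setdiff(idsA, idsB)
  onlyB <- setdiff(idsB, idsA)
  if (length(onlyA) || length(onlyB))
    stop("gene sets differ; only in A: [",
         paste(onlyA, collapse = ", "), "], only in B: [",
         paste(onlyB, collapse = ", "), "]")
  m <- match(idsA, idsB)
  tab <- table(A = factor(mcols(recordsA)$state,
                          levels = chromatinStates()),
               B = factor(mcols(recordsB)$state[m],
                          levels = chromatinStates()))
  unclass(tab)
}
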