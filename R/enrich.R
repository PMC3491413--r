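#' Reduce reads to extended-fragment midpoints
#'
#' Each read is extended to \code{fragmentLength} bp in its strand
#' direction from its 5' end; the midpoint of the extended fragment,
#' clipped to the chromosome, is the counting point used by all
#' window and profile operations. Counting midpoints (rather than full
#' fragments) makes every read contribute to exactly one window per
#' scan, avoiding width-dependent double counting.
#'
#' @param reads stranded \code{GRanges} of aligned reads.
#' @param layout named chromosome-length vector.
#' @param fragmentLength sonication fragment length in bp (> 0).
#' @return a \code{GPos} of counting points (1-based positions).
#' @examples
#' layout <- c(chr1 = 1000)
#' r <- GenomicRanges::GRanges("chr1:101-136:+")
#' assignFragments(r, layout, fragmentLength = 200)  # midpoint base 200
#' @export
assignFragments <- function(reads, layout, fragmentLength = 200) {
  stopIfNot(fragmentLength > 0, "fragmentLength must be positive")
  layout <- checkLayout(layout)
  bad <- setdiff(unique(as.character(seqnames(reads))), names(layout))
  if (length(bad))
    stop("read chromosome(s) not in genome layout: ",
         paste(bad, collapse = ", "))
  st <- as.character(strand(reads))
  if (any(st == "*"))
    stop("reads must be stranded ('+' or '-') to assign fragments")
  half <- floor(fragmentLength / 2)
  mid0 <- ifelse(st == "+", start0(reads) + half, end0(reads) - half)
  len <- layout[as.character(seqnames(reads))]
  mid0 <- pmin(pmax(mid0, 0), len - 1)
  pts <- GPos(seqnames = as.character(seqnames(reads)), pos = mid0 + 1)
  applyLayout(pts, layout)
}

#' Count points in sliding windows across the genome
#'
#' Windows of \code{windowSize} bp start every \code{step} bp at
#' positions 0, step, 2*step, ... on each chromosome; only windows fully
#' inside the chromosome are kept. The count is the number of points in
#' the half-open window.
#'
#' @param points \code{GPos}/\code{GRanges} of counting points, from
#'   \code{\link{assignFragments}}.
#' @param layout named chromosome-length vector.
#' @param windowSize window width in bp (default the 1-kb analysis
#'   window); must be a multiple of \code{step}.
#' @param step sliding step in bp.
#' @return a \linkS4class{WindowScan}.
#' @export
scanWindows <- function(points, layout, windowSize = 1000, step = 200) {
  layout <- checkLayout(layout)
  stopIfNot(windowSize %% step == 0, "windowSize must be a multiple of step")
  wins <- GRanges()
  for (chr in names(layout)) {
    len <- layout[[chr]]
    if (len < windowSize) {
      warning("chromosome ", chr, " is shorter than one window; skipped")
      next
    }
    starts0 <- seq(0, len - windowSize, by = step)
    wins <- c(wins, gr0(chr, starts0, starts0 + windowSize))
  }
  wins <- applyLayout(wins, layout)
  mcols(wins)$count <- countOverlaps(wins, points)
  new("WindowScan", windows = wins, windowSize = as.integer(windowSize),
      step = as.integer(step), nPoints = length(points))
}

#' Background null model for window counts
#'
#' Poisson mode: the expected count per window is
#' \code{lambda = n_points * windowSize / genome_length} and the tail is
#' the exact Poisson upper tail P(X >= k). Empirical mode: the observed
#' points are re-placed uniformly over the genome
#' \code{nRandomizations} times; all randomized counts in non-overlapping
#' \code{windowSize} tiles are pooled into one empirical null with tail
#' \code{P(k) = (1 + #null >= k) / (1 + #null)}. The Poisson model is the
#' large-pool limit of the randomization null.
#'
#' @param points counting points (\code{GPos}).
#' @param layout named chromosome-length vector.
#' @param windowSize window width in bp.
#' @param mode \code{"poisson"} or \code{"empirical"}.
#' @param nRandomizations randomizations pooled in empirical mode.
#' @param seed seed for the randomizations.
#' @return a \linkS4class{NullModel}.
#' @export
nullRate <- function(points, layout, windowSize = 1000,
                     mode = c("poisson", "empirical"),
                     nRandomizations = 10, seed = 1) {
  mode <- match.arg(mode)
  layout <- checkLayout(layout)
  n <- length(points)
  stopIfNot(n >= 1, "need at least one point")
  lambda <- n * windowSize / sum(layout)
  if (mode == "poisson")
    return(new("NullModel", mode = "poisson", lambda = lambda,
               nullCounts = integer(), nRandomizations = 0L,
               windowSize = as.integer(windowSize)))
  stopIfNot(nRandomizations >= 1, "nRandomizations must be >= 1")
  nullCounts <- withSeed(subSeed(seed, "null"), {
    out <- vector("list", nRandomizations)
    probs <- layout / sum(layout)
    for (r in seq_len(nRandomizations)) {
      nper <- as.vector(stats::rmultinom(1, n, probs))
      cts <- integer()
      for (ci in seq_along(layout)) {
        ntile <- floor(layout[[ci]] / windowSize)
        if (ntile < 1L || nper[ci] == 0L) {
          cts <- c(cts, integer(ntile))
          next
        }
        pos0 <- floor(stats::runif(nper[ci], 0, layout[[ci]]))
        tile <- pos0 %/% windowSize + 1
        cts <- c(cts, tabulate(tile[tile <= ntile], nbins = ntile))
      }
      out[[r]] <- cts
    }
    sort(unlist(out))
  })
  new("NullModel", mode = "empirical", lambda = lambda,
      nullCounts = as.integer(nullCounts),
      nRandomizations = as.integer(nRandomizations),
      windowSize = as.integer(windowSize))
}

#' Upper-tail probability of a window count under a null model
#'
#' @param null a \linkS4class{NullModel}.
#' @param k integer count(s).
#' @return P(X >= k), vectorized over \code{k}. For the empirical null
#'   this is \code{(1 + #null >= k) / (1 + #null)}, never exactly zero.
#' @export
pvalueTail <- function(null, k) {
  stopIfNot(is(null, "NullModel"), "null must be a NullModel")
  if (null@mode == "poisson")
    return(stats::ppois(k - 1, null@lambda, lower.tail = FALSE))
  N <- length(null@nullCounts)
  nLess <- findInterval(k - 0.5, null@nullCounts)
  (1 + (N - nLess)) / (1 + N)
}

#' Score a window scan against a null model
#'
#' Attaches the expected count \code{lambda} and the upper-tail P-value
#' to every window.
#'
#' @param scan a \linkS4class{WindowScan}.
#' @param null a \linkS4class{NullModel} built with the same window size.
#' @return the scan with \code{lambda} and \code{pvalue} columns filled.
#' @export
scoreWindows <- function(scan, null) {
  stopIfNot(is(scan, "WindowScan"), "scan must be a WindowScan")
  stopIfNot(null@windowSize == scan@windowSize,
            "null model window size does not match the scan")
  mcols(scan@windows)$lambda <- null@lambda
  mcols(scan@windows)$pvalue <- pvalueTail(null, windowCounts(scan))
  validObject(scan)
  scan
}

#' Call enriched intervals from a scored window scan
#'
#' Windows with tail P strictly below \code{alpha} are retained;
#' overlapping or adjacent retained windows, and retained windows whose
#' end-to-start distance is strictly less than \code{mergeGap}, are
#' merged into maximal intervals. The output is sorted and disjoint, and
#' the operation is idempotent and invariant to window order.
#'
#' @param scan a scored \linkS4class{WindowScan} (see
#'   \code{\link{scoreWindows}}).
#' @param alpha per-window significance threshold (default 1e-4).
#' @param mergeGap merge distance in bp (default 2000; strict less-than).
#' @param mark mark name recorded on the result.
#' @return an \linkS4class{EnrichedWindowSet}.
#' @export
callEnriched <- function(scan, alpha = 1e-4, mergeGap = 2000,
                         mark = "mark") {
  stopIfNot(is(scan, "WindowScan"), "scan must be a WindowScan")
  p <- windowPvalues(scan)
  stopIfNot(!is.null(p), "scan has no P-values; run scoreWindows() first")
  sig <- scan@windows[p < alpha]
  merged <- reduce(granges(sort(sig)), min.gapwidth = mergeGap)
  new("EnrichedWindowSet", mark = mark, alpha = alpha,
      mergeGap = as.integer(mergeGap), intervals = merged,
      nSignificantWindows = length(sig))
}

#' Non-overlapping window track for display export
#'
#' Subsets a scan to its non-overlapping tiling (every
#' windowSize/step-th window) and attaches the count, or
#' reads-per-million, as the bedGraph score.
#'
#' @param scan a \linkS4class{WindowScan}.
#' @param rpm scale counts to reads per million of the scanned points.
#' @return \code{GRanges} with a \code{score} column, suitable for
#'   \code{\link{writeBedGraph}}.
#' @export
windowTrack <- function(scan, rpm = FALSE) {
  keep <- (start0(scan@windows) %% scan@windowSize) == 0
  gr <- granges(scan@windows[keep])
  sc <- windowCounts(scan)[keep]
  mcols(gr)$score <- if (rpm) sc * 1e6 / max(scan@nPoints, 1) else sc
  gr
}
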