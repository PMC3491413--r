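# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# Exact Poisson upper tail by direct summation in log space.
brutePoissonTail <- function(lambda, k, upper = 500) {
  if (k <= 0) return(1)
  i <- k:max(upper, k + 50)
  sum(exp(-lambda + i * log(lambda) - lgamma(i + 1)))
}

# O(n^2) merge of 0-based half-open intervals: merge while the distance
# (next start - previous end) of any pair is < gap or they overlap/abut.
bruteMerge <- function(starts0, ends0, gap) {
  n <- length(starts0)
  if (n == 0L) return(data.frame(start0 = numeric(), end0 = numeric()))
  iv <- data.frame(start0 = starts0, end0 = ends0)
  repeat {
    merged <- FALSE
    for (i in seq_len(nrow(iv))) {
      for (j in seq_len(nrow(iv))) {
        if (i == j) next
        d <- max(iv$start0[j] - iv$end0[i], iv$start0[i] - iv$end0[j], 0)
        overlapping <- iv$start0[i] < iv$end0[j] && iv$start0[j] < iv$end0[i]
        if (overlapping || d < gap) {
          iv$start0[i] <- min(iv$start0[i], iv$start0[j])
          iv$end0[i] <- max(iv$end0[i], iv$end0[j])
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  iv[order(iv$start0), , drop = FALSE]
}

# O(|A||B|) overlap oracle on 0-based half-open intervals.
bruteOverlapCount <- function(aS, aE, bS, bE, minOverlap = 1) {
  hits <- 0L
  for (i in seq_along(aS)) {
    for (j in seq_along(bS)) {
      ov <- min(aE[i], bE[j]) - max(aS[i], bS[j])
      if (ov >= minOverlap) { hits <- hits + 1L; break }
    }
  }
  hits
}

# Enumerate all weight vectors with k parts summing to `steps` units of
# 1/steps (compositions), as a matrix with one row per grid point.
simplexGrid <- function(k, steps) {
  if (k == 1L) return(matrix(steps, ncol = 1L))
  out <- list()
  for (first in 0:steps) {
    rest <- simplexGrid(k - 1L, steps - first)
    out[[first + 1L]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

# Best objective over the step-1/steps simplex grid for the diacetyl
# least-squares problem: minimize ||A w - f||^2. The grid is cached.
.gridCache <- new.env(parent = emptyenv())
gridOracleObjective <- function(A, f, steps = 10) {
  key <- paste(ncol(A), steps, sep = "_")
  if (is.null(.gridCache[[key]]))
    .gridCache[[key]] <- simplexGrid(ncol(A), steps) / steps
  W <- .gridCache[[key]]
  R <- W %*% t(A)
  resid <- sweep(R, 2, f)
  min(rowSums(resid^2))
}

# WindowScan built directly from window starts and P-values, for merge
# tests that do not need real reads.
makeScan <- function(starts0, pvalues, windowSize = 1000, step = 200,
                     chrom = "chrS", layout = c(chrS = 1e7)) {
  wins <- GRanges(chrom, IRanges(starts0 + 1, starts0 + windowSize))
  seqlevels(wins) <- names(layout)
  seqlengths(wins) <- layout
  mcols(wins)$count <- rep(1L, length(wins))
  mcols(wins)$lambda <- 1
  mcols(wins)$pvalue <- pvalues
  new("WindowScan", windows = wins, windowSize = as.integer(windowSize),
      step = as.integer(step), nPoints = length(wins))
}

# Gene table with explicit states, for classification fixtures.
statefulGenes <- function(states, spacing = 50000, chrom = "chrS",
                          layout = c(chrS = 1e7), strand = "+") {
  n <- length(states)
  tss <- (seq_len(n)) * spacing
  g <- makeGeneTable(sprintf("g%03d", seq_len(n)), rep(chrom, n),
                     tss, tss + 8000, rep_len(strand, n),
                     layout = layout)
  mcols(g)$state <- states
  g
}

# Flat-topped trace with a known rectangular area for integration tests.
rectTrace <- function(species = "rect", height = 10, from = 5, to = 7,
                      step = 0.001) {
  rt <- seq(from - 2, to + 2, by = step)
  chromatogram(species, rt, ifelse(rt >= from & rt <= to, height, 0))
}
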