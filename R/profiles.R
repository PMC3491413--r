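# Anchor positions (0-based) and strands from a gene table or any
# GRanges: gene tables anchor at the TSS, other ranges at their start.
anchorPositions <- function(anchors) {
  t0 <- mcols(anchors)$tss
  if (is.null(t0)) t0 <- start0(anchors)
  ids <- mcols(anchors)$gene_id
  if (is.null(ids)) ids <- names(anchors)
  if (is.null(ids)) ids <- sprintf("region_%04d", seq_along(anchors))
  st <- as.character(strand(anchors))
  st[st == "*"] <- "+"
  list(chrom = as.character(seqnames(anchors)), t0 = t0, strand = st,
       ids = ids)
}

#' TSS-anchored signal matrix (heatmap input)
#'
#' Counts fragment midpoints in fixed-width bins spanning +/-\code{span}
#' around each anchor and scales to reads per million. Bin 1 starts at
#' -span relative to the anchor; for minus-strand anchors the bin order
#' is flipped so columns always run 5' to 3' relative to the gene. Bins
#' extending beyond the chromosome are \code{NA}.
#'
#' @param points counting points (\code{GPos}, from
#'   \code{\link{assignFragments}}).
#' @param anchors gene \code{GRanges} (anchored at the TSS) or any
#'   \code{GRanges} (anchored at the range start).
#' @param span half-width in bp (default 5000); must be a multiple of
#'   \code{bin}.
#' @param bin bin width in bp (default 200, non-overlapping tiles).
#' @param librarySize total points for the per-million scaling; defaults
#'   to \code{length(points)}.
#' @return a \linkS4class{ProfileMatrix} with one row per anchor.
#' @export
profileMatrix <- function(points, anchors, span = 5000, bin = 200,
                          librarySize = length(points)) {
  stopIfNot(span %% bin == 0, "span must be a multiple of bin")
  stopIfNot(librarySize > 0, "librarySize must be positive")
  nb <- as.integer(2 * span / bin)
  a <- anchorPositions(anchors)
  n <- length(a$t0)
  # generous fetch window covering both strand orientations
  qs <- pmax(a$t0 - span - 1, 0)
  q <- gr0(a$chrom, qs, a$t0 + span + 1)
  p0 <- start(points) - 1L
  hits <- findOverlaps(q, GRanges(seqnames(points),
                                  IRanges(start(points), width = 1L)))
  qi <- queryHits(hits)
  off <- ifelse(a$strand[qi] == "+",
                p0[subjectHits(hits)] - a$t0[qi],
                a$t0[qi] - p0[subjectHits(hits)])
  keep <- off >= -span & off < span
  qi <- qi[keep]; off <- off[keep]
  binIdx <- (off + span) %/% bin + 1
  counts <- matrix(tabulate((qi - 1L) * nb + binIdx, nbins = n * nb),
                   nrow = n, byrow = TRUE)
  rownames(counts) <- a$ids
  values <- counts * 1e6 / librarySize
  # NA out bins that fall off the chromosome
  len <- seqlengths(anchors)[a$chrom]
  if (any(!is.na(len))) {
    j <- seq_len(nb)
    for (i in which(!is.na(len))) {
      if (a$strand[i] == "+") {
        g1 <- a$t0[i] - span + (j - 1) * bin
        g2 <- g1 + bin
      } else {
        g2 <- a$t0[i] + span - (j - 1) * bin + 1
        g1 <- g2 - bin
      }
      oob <- g1 < 0 | g2 > len[i]
      values[i, oob] <- NA_real_
    }
  }
  new("ProfileMatrix", values = values, counts = counts,
      binCenters = seq(-span + bin / 2, span - bin / 2, by = bin),
      binSize = as.integer(bin), span = as.integer(span),
      librarySize = as.numeric(librarySize))
}

#' Composite (metagene) profile over a region subset
#'
#' Per-bin arithmetic mean of the reads-per-million matrix, ignoring
#' \code{NA} (out-of-bounds) bins. Invariant to row order.
#'
#' @param matrix a \linkS4class{ProfileMatrix}.
#' @param rows row subset: indices, logical mask, or region ids; default
#'   all rows. An empty subset is an error.
#' @return a \linkS4class{CompositeProfile}.
#' @export
composite <- function(matrix, rows = NULL) {
  v <- profileValues(matrix)
  if (is.null(rows)) rows <- seq_len(nrow(v))
  if (is.character(rows)) rows <- match(rows, rownames(v))
  if (is.logical(rows)) rows <- which(rows)
  stopIfNot(length(rows) > 0, "empty region subset")
  stopIfNot(!anyNA(rows), "unknown region id in subset")
  sub <- v[rows, , drop = FALSE]
  new("CompositeProfile", binCenters = matrix@binCenters,
      mean = colMeans(sub, na.rm = TRUE), nRegions = length(rows))
}

#' Assign genes to expression quartiles
#'
#' Genes are ranked by expression (ties broken by their order in
#' \code{genes}, a stable rule) and split into \code{nQuartiles} groups
#' whose sizes differ by at most one. Quartile 1 is the lowest-expressed,
#' quartile \code{nQuartiles} the top.
#'
#' @param expression named numeric expression vector.
#' @param genes character vector of gene ids to stratify (typically the
#'   H3K4me3-only genes); must all have expression values.
#' @param nQuartiles number of strata (default 4).
#' @return named integer vector of quartile labels over \code{genes}.
#' @export
expressionQuartiles <- function(expression, genes = names(expression),
                                nQuartiles = 4) {
  missing <- genes[!genes %in% names(expression)]
  if (length(missing))
    stop("no expression value for gene(s): ",
         paste(missing, collapse = ", "))
  stopIfNot(length(genes) >= nQuartiles,
            "need at least nQuartiles genes")
  vals <- expression[genes]
  ord <- order(vals)  # stable: ties keep gene order
  m <- length(genes)
  q <- integer(m)
  q[ord] <- ((seq_len(m) - 1L) * nQuartiles) %/% m + 1L
  stats::setNames(q, genes)
}

#' Export a state-organised heatmap matrix
#'
#' Rows are grouped by chromatin state in canonical order (K4-only,
#' bivalent, K27-only, no-mark) and, within each group, sorted by
#' descending mean signal. The TSV round-trips exactly (values are
#' written with full double precision). Empty groups are omitted with a
#' recorded notice.
#'
#' @param matrix a \linkS4class{ProfileMatrix}.
#' @param states named character/factor vector of states, indexed by
#'   region id.
#' @param path output TSV path.
#' @return invisibly, the ordered data frame written; attribute
#'   \code{"emptyGroups"} lists omitted states.
#' @export
heatmapExport <- function(matrix, states, path) {
  v <- profileValues(matrix)
  ids <- rownames(v)
  stopIfNot(all(ids %in% names(states)),
            "every region needs a state label")
  st <- as.character(states[ids])
  ord <- integer(0)
  empty <- character(0)
  for (s in chromatinStates()) {
    i <- which(st == s)
    if (length(i) == 0L) { empty <- c(empty, s); next }
    i <- i[order(-rowMeans(v[i, , drop = FALSE], na.rm = TRUE))]
    ord <- c(ord, i)
  }
  if (length(empty))
    message("heatmapExport: empty state group(s) omitted: ",
            paste(empty, collapse = ", "))
  df <- data.frame(region_id = ids[ord], state = st[ord],
                   check.names = FALSE)
  vals <- v[ord, , drop = FALSE]
  colnames(vals) <- sprintf("bin_%g", matrix@binCenters)
  fmt <- apply(vals, 2, function(x)
    ifelse(is.na(x), "NA", sprintf("%.17g", x)))
  if (length(ord) == 1L) fmt <- matrix(fmt, nrow = 1L,
                                       dimnames = list(NULL, colnames(vals)))
  out <- cbind(df, as.data.frame(fmt, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  res <- cbind(df, as.data.frame(vals, check.names = FALSE))
  attr(res, "emptyGroups") <- empty
  invisible(res)
}

#' Read back an exported heatmap matrix
#' @param path TSV written by \code{\link{heatmapExport}}.
#' @return data frame with region_id, state and numeric bin columns.
#' @export
readHeatmapTable <- function(path) {
  utils::read.delim(path, check.names = FALSE,
                    colClasses = c(region_id = "character",
                                   state = "character"))
}

#' Plot a composite profile
#'
#' Thin display helper; the tested artifact is the matrix itself.
#'
#' @param x a \linkS4class{CompositeProfile} (or a named list of them,
#'   drawn on common axes).
#' @param ... passed to \code{matplot}/\code{plot}.
#' @export
plotComposite <- function(x, ...) {
  if (is(x, "CompositeProfile")) x <- list(profile = x)
  xs <- binCenters(x[[1]])
  ys <- sapply(x, compositeMean)
  graphics::matplot(xs, ys, type = "l", lty = 1,
                    xlab = "position relative to TSS (bp)",
                    ylab = "mean signal (RPM)", ...)
  if (length(x) > 1)
    graphics::legend("topright", legend = names(x), lty = 1,
                     col = seq_along(x))
  invisible(NULL)
}
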