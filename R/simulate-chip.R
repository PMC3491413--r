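#' Promoter chromatin-state labels used throughout the package
#'
#' @return character vector of the four states, in canonical order:
#'   H3K4me3-only, bivalent (H3K4me3 + H3K27me3), H3K27me3-only, no-mark.
#' @export
chromatinStates <- function() c("K4-only", "bivalent", "K27-only", "no-mark")

# Which chromatin states carry each simulated mark. H2A.Z tracks H3K4
# methylation: present at K4-only and bivalent promoters, absent from
# K27-only and no-mark promoters.
statesWithMark <- function(mark) {
  switch(mark,
    "H2A.Z" = c("K4-only", "bivalent"),
    "H3K4me3" = c("K4-only", "bivalent"),
    "H3K27me3" = c("bivalent", "K27-only"),
    stop("unknown mark '", mark, "'; supply statesWith= explicitly"))
}

#' Configuration for the synthetic chromatin generator
#'
#' Defines a desk-scale genome with gene annotations, promoter chromatin
#' states and planted ChIP enrichment, all deterministic under
#' \code{seed}. Defaults: one 10-Mb chromosome carrying 200 genes at
#' least 20 kb apart; background midpoint density 0.005 reads/bp; 5-fold
#' enrichment; H2A.Z deposited as two summits at TSS +/- 150 bp
#' (nucleosomes flanking the nucleosome-free region); H3K4me3/H3K27me3
#' as a 2-kb block over the promoter.
#'
#' @param genome named vector of chromosome lengths.
#' @param nGenes number of genes.
#' @param classProbs probabilities over \code{\link{chromatinStates}()};
#'   must sum to 1.
#' @param backgroundRate background fragment-midpoint density, reads/bp.
#' @param enrichmentFold total read density inside planted regions as a
#'   multiple of \code{backgroundRate}; must exceed 1.
#' @param flankOffset bp distance of each H2A.Z summit from the TSS.
#' @param summitSd Gaussian spread (bp) of fragment midpoints around an
#'   H2A.Z summit.
#' @param blockWidth width (bp) of the planted promoter block for
#'   block-type marks, laid out 500 bp upstream to
#'   \code{blockWidth - 500} bp downstream of the TSS.
#' @param fragmentLength sonication fragment length (bp); reads are
#'   placed so the extended-fragment midpoint is the sampled position.
#' @param readLength sequenced read length (bp).
#' @param nIntergenicSites number of planted intergenic H2A.Z sites
#'   (distal regulatory elements), placed in large intergenic gaps.
#' @param intergenicWidth width (bp) of each intergenic site.
#' @param depletionMax maximum fractional depletion of planted H2A.Z
#'   reads at the most highly expressed gene (elongation-coupled
#'   eviction); 0 disables.
#' @param backgroundExcludesPromoters if TRUE, background reads avoid all
#'   promoter regions, giving noiseless chromatin-state labels.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated config (list).
#' @export
simChromatinConfig <- function(genome = c(chrS = 1e7),
                               nGenes = 200,
                               classProbs = c("K4-only" = 0.45,
                                              "bivalent" = 0.25,
                                              "K27-only" = 0.10,
                                              "no-mark" = 0.20),
                               backgroundRate = 0.005,
                               enrichmentFold = 5,
                               flankOffset = 150,
                               summitSd = 50,
                               blockWidth = 2000,
                               fragmentLength = 200,
                               readLength = 36,
                               nIntergenicSites = 40,
                               intergenicWidth = 1000,
                               depletionMax = 0,
                               backgroundExcludesPromoters = FALSE,
                               seed = 1) {
  genome <- checkLayout(genome)
  stopIfNot(abs(sum(classProbs) - 1) < 1e-8, "classProbs must sum to 1")
  stopIfNot(all(names(classProbs) %in% chromatinStates()) &&
              length(classProbs) == 4L,
            "classProbs must be named by chromatinStates()")
  stopIfNot(enrichmentFold >= 1, "enrichmentFold must be >= 1")
  stopIfNot(backgroundRate > 0, "backgroundRate must be positive")
  stopIfNot(depletionMax >= 0 && depletionMax < 1,
            "depletionMax must lie in [0, 1)")
  structure(list(genome = genome, nGenes = nGenes,
                 classProbs = classProbs[chromatinStates()],
                 backgroundRate = backgroundRate,
                 enrichmentFold = enrichmentFold,
                 flankOffset = flankOffset, summitSd = summitSd,
                 blockWidth = blockWidth,
                 fragmentLength = fragmentLength,
                 readLength = readLength,
                 nIntergenicSites = nIntergenicSites,
                 intergenicWidth = intergenicWidth,
                 depletionMax = depletionMax,
                 backgroundExcludesPromoters = backgroundExcludesPromoters,
                 seed = as.integer(seed)),
            class = "SimChromatinConfig")
}

#' Simulate the gene universe with chromatin-state labels
#'
#' Deterministic for a fixed config: every call (and every
#' \code{\link{simulateChip}} call on the same config) sees the same
#' genes and labels. Genes are spaced evenly with a small jitter so that
#' neighbouring genes stay at least 20 kb apart.
#'
#' @param config a \code{\link{simChromatinConfig}}.
#' @return gene \code{GRanges} (as from \code{\link{makeGeneTable}}) with
#'   an extra \code{state} metadata column.
#' @export
simulateGenes <- function(config) {
  withSeed(subSeed(config$seed, "genes"), {
    genome <- config$genome
    alloc <- round(config$nGenes * genome / sum(genome))
    alloc[length(alloc)] <- config$nGenes - sum(alloc[-length(alloc)])
    gene_id <- chrom <- character(0)
    tss <- tes <- numeric(0)
    strand <- character(0)
    for (ci in seq_along(genome)) {
      n <- alloc[ci]
      if (n <= 0) next
      len <- genome[ci]
      spacing <- floor(len / n)
      stopIfNot(spacing >= 35000,
                "genome too small for nGenes at >= 20 kb gene spacing")
      anchor <- round((seq_len(n) - 0.5) * spacing +
                      stats::runif(n, -2000, 2000))
      width <- round(stats::runif(n, 5000, 12000))
      st <- sample(c("+", "-"), n, replace = TRUE)
      g_tss <- ifelse(st == "+", anchor, anchor + width)
      g_tes <- ifelse(st == "+", anchor + width, anchor)
      gene_id <- c(gene_id, sprintf("g%s_%04d", names(genome)[ci],
                                    seq_len(n)))
      chrom <- c(chrom, rep(names(genome)[ci], n))
      tss <- c(tss, g_tss); tes <- c(tes, g_tes)
      strand <- c(strand, st)
    }
    genes <- makeGeneTable(gene_id, chrom, tss, tes, strand,
                           layout = genome)
    mcols(genes)$state <- sample(chromatinStates(), length(genes),
                                 replace = TRUE, prob = config$classProbs)
    genes
  })
}

# Centers of the planted intergenic H2A.Z sites: midpoints of a seeded
# subset of intergenic gaps wide enough to survive the 4-kb exclusion.
intergenicSiteCenters <- function(config, genes) {
  if (config$nIntergenicSites <= 0)
    return(GRanges())
  margin <- 4000 + 2500 + config$intergenicWidth
  cand <- gapCenters(config, genes, margin)
  stopIfNot(length(cand) >= config$nIntergenicSites,
            "not enough wide intergenic gaps for nIntergenicSites")
  withSeed(subSeed(config$seed, "intergenic"), {
    keep <- sort(sample(length(cand), config$nIntergenicSites))
    cand[keep]
  })
}

# Midpoints of intergenic gaps at least `margin` bp from both flanking
# gene bodies, as width-1 GRanges.
gapCenters <- function(config, genes, margin) {
  out <- GRanges()
  for (chr in names(config$genome)) {
    g <- genes[as.character(seqnames(genes)) == chr]
    b <- granges(g)
    strand(b) <- "*"
    b <- sort(b)
    bounds0 <- c(0, end0(b))
    bounds1 <- c(start0(b), config$genome[[chr]])
    w <- bounds1 - bounds0
    ok <- w >= 2 * margin
    if (!any(ok)) next
    centers <- floor((bounds0[ok] + bounds1[ok]) / 2)
    out <- c(out, gr0(chr, centers, centers + 1))
  }
  applyLayout(out, config$genome)
}

# Turn fragment midpoints into stranded reads such that
# assignFragments(reads, fragmentLength) recovers the midpoints exactly.
midpointsToReads <- function(chrom, mid0, config) {
  n <- length(mid0)
  st <- sample(c("+", "-"), n, replace = TRUE)
  half <- floor(config$fragmentLength / 2)
  rs0 <- ifelse(st == "+", mid0 - half, mid0 + half - config$readLength)
  gr0(chrom, rs0, rs0 + config$readLength, strand = st,
      layout = config$genome)
}

#' Simulate a ChIP-Seq read set for one mark
#'
#' Background fragment midpoints are placed uniformly at
#' \code{backgroundRate} reads/bp. Each gene whose chromatin state
#' carries the mark receives additional reads over its planted region so
#' the total midpoint density there is \code{enrichmentFold} times the
#' background. For H2A.Z the planted region is a pair of Gaussian
#' summits at TSS +/- \code{flankOffset} (the nucleosomes flanking the
#' nucleosome-free region) plus, genome-wide, \code{nIntergenicSites}
#' distal sites; for H3K4me3 / H3K27me3 it is a \code{blockWidth} block
#' over the promoter. Deterministic for a fixed config seed.
#'
#' @param config a \code{\link{simChromatinConfig}}.
#' @param mark \code{"H2A.Z"}, \code{"H3K4me3"} or \code{"H3K27me3"}.
#' @param expression optional named expression vector (from
#'   \code{\link{simulateExpression}}); with \code{depletionMax > 0},
#'   planted H2A.Z reads at a gene are thinned in proportion to its
#'   expression percentile, emulating elongation-coupled eviction.
#' @param statesWith optional character vector of states carrying the
#'   mark, overriding the built-in mark table.
#' @return list with \code{reads} (stranded \code{GRanges}) and
#'   \code{truth} (gene labels, planted intervals, per-gene planted read
#'   counts, config).
#' @export
simulateChip <- function(config, mark, expression = NULL,
                         statesWith = NULL) {
  stopIfNot(inherits(config, "SimChromatinConfig"),
            "config must come from simChromatinConfig()")
  genes <- simulateGenes(config)
  inStates <- if (is.null(statesWith)) statesWithMark(mark) else statesWith
  marked <- genes[mcols(genes)$state %in% inStates]
  igSites <- if (mark == "H2A.Z")
    intergenicSiteCenters(config, genes) else GRanges()

  # planted intervals (truth)
  planted <- GRanges()
  if (length(marked)) {
    t0 <- mcols(marked)$tss
    if (mark == "H2A.Z") {
      half <- config$flankOffset + 2 * config$summitSd
      pl <- gr0(as.character(seqnames(marked)), t0 - half, t0 + half,
                layout = config$genome)
    } else {
      up <- 500
      plus <- as.character(strand(marked)) == "+"
      s0 <- ifelse(plus, t0 - up, t0 - (config$blockWidth - up))
      pl <- gr0(as.character(seqnames(marked)), s0,
                s0 + config$blockWidth, layout = config$genome)
    }
    mcols(pl)$gene_id <- mcols(marked)$gene_id
    planted <- pl
  }
  if (length(igSites)) {
    s0 <- start0(igSites) - floor(config$intergenicWidth / 2)
    ig <- gr0(as.character(seqnames(igSites)), s0,
              s0 + config$intergenicWidth, layout = config$genome)
    mcols(ig)$gene_id <- sprintf("intergenic_%03d", seq_along(ig))
    planted <- c(planted, ig)
  }
  if (length(planted)) {
    if (any(start(planted) < 1) ||
        any(end(planted) > config$genome[as.character(seqnames(planted))]))
      stop("planted region exceeds chromosome bounds")
  }

  withSeed(subSeed(config$seed, paste0("reads_", mark)), {
    reads <- GRanges()
    # background
    promZones <- if (config$backgroundExcludesPromoters)
      promoterRegions(genes) else NULL
    edge <- config$fragmentLength + config$readLength
    for (chr in names(config$genome)) {
      len <- config$genome[[chr]]
      nbg <- stats::rpois(1, config$backgroundRate * len)
      mid0 <- round(stats::runif(nbg, edge, len - edge))
      if (!is.null(promZones)) {
        pz <- promZones[as.character(seqnames(promZones)) == chr]
        for (it in 1:100) {
          inside <- countOverlaps(gr0(chr, mid0, mid0 + 1), granges(pz)) > 0
          if (!any(inside)) break
          mid0[inside] <- round(stats::runif(sum(inside), edge, len - edge))
        }
      }
      reads <- c(reads, midpointsToReads(chr, mid0, config))
    }
    # planted enrichment
    extraRate <- (config$enrichmentFold - 1) * config$backgroundRate
    plantedCounts <- integer(length(planted))
    if (length(planted)) {
      depl <- rep(1, length(planted))
      if (mark == "H2A.Z" && config$depletionMax > 0 &&
          !is.null(expression)) {
        ids <- mcols(planted)$gene_id
        known <- ids %in% names(expression)
        pr <- rank(expression, ties.method = "average") /
          length(expression)
        depl[known] <- 1 - config$depletionMax * pr[ids[known]]
      }
      for (i in seq_along(planted)) {
        chr <- as.character(seqnames(planted)[i])
        w <- width(planted)[i]
        nx <- stats::rpois(1, extraRate * w * depl[i])
        plantedCounts[i] <- nx
        if (nx == 0) next
        isSummit <- mark == "H2A.Z" &&
          !startsWith(mcols(planted)$gene_id[i], "intergenic")
        if (isSummit) {
          t0 <- start0(planted)[i] + config$flankOffset +
            2 * config$summitSd
          side <- sample(c(-1, 1), nx, replace = TRUE)
          mid0 <- round(t0 + side * config$flankOffset +
                        stats::rnorm(nx, 0, config$summitSd))
        } else {
          mid0 <- round(stats::runif(nx, start0(planted)[i],
                                     end0(planted)[i] - 1))
        }
        len <- config$genome[[chr]]
        mid0 <- pmin(pmax(mid0, edge), len - edge)
        reads <- c(reads, midpointsToReads(chr, mid0, config))
      }
    }
    truth <- list(mark = mark, genes = genes,
                  plantedIntervals = planted,
                  plantedReadCounts = plantedCounts,
                  intergenicSites = igSites, config = config)
    list(reads = sort(reads), truth = truth)
  })
}

#' Simulate gene-expression values consistent with chromatin state
#'
#' H3K4me3-only genes receive log-normal expression spanning several
#' orders of magnitude (values are log-normal quantiles assigned to genes
#' in seeded random order, so the dynamic range is guaranteed); bivalent,
#' K27-only and no-mark genes receive values near zero, below the
#' positive floor of 1. Expression quartiles of the K4-only genes are
#' computed with \code{\link{expressionQuartiles}} (quartile 1 = lowest).
#'
#' @param genes gene \code{GRanges} with a \code{state} column (from
#'   \code{\link{simulateGenes}}), or a \code{simulateChip} truth list.
#' @param seed integer seed.
#' @param meanlog,sdlog log-normal parameters for expressed genes.
#' @return list with \code{expression} (named vector over all genes),
#'   \code{quartile} (named integer over K4-only genes) and
#'   \code{floor} (the positive-expression floor).
#' @export
simulateExpression <- function(genes, seed = 1, meanlog = 2, sdlog = 2) {
  if (is.list(genes) && !is(genes, "GRanges")) genes <- genes$genes
  state <- mcols(genes)$state
  stopIfNot(!is.null(state), "genes must carry a 'state' column")
  k4 <- mcols(genes)$gene_id[state == "K4-only"]
  withSeed(subSeed(seed, "expr"), {
    m <- length(k4)
    expr <- stats::setNames(rep(0, length(genes)), mcols(genes)$gene_id)
    if (m > 0) {
      vals <- stats::qlnorm(stats::ppoints(m), meanlog, sdlog)
      expr[k4] <- vals[sample.int(m)]
    }
    off <- names(expr)[!names(expr) %in% k4]
    expr[off] <- stats::runif(length(off), 0, 0.01)
    q <- if (m >= 4) expressionQuartiles(expr, k4) else
      stats::setNames(integer(0), character(0))
    list(expression = expr, quartile = q, floor = 1)
  })
}

#' Simulate multiple transcription-factor binding loci (MTLs)
#'
#' Plants MTL-like loci in intergenic space: a fraction at the centers of
#' the planted intergenic H2A.Z sites (occupied) and the rest in wide
#' gaps that carry no H2A.Z (unoccupied), so the intergenic MTL occupancy
#' pipeline has a known truth.
#'
#' @param config a \code{\link{simChromatinConfig}}.
#' @param nMtl number of loci.
#' @param fracOccupied fraction placed under planted H2A.Z sites.
#' @param mtlWidth raw locus width in bp.
#' @return list with \code{mtls} (\code{GRanges} with logical
#'   \code{occupied} truth column) and \code{fracOccupied} actually used.
#' @export
simulateMtls <- function(config, nMtl = 30, fracOccupied = 0.5,
                         mtlWidth = 200) {
  genes <- simulateGenes(config)
  sites <- intergenicSiteCenters(config, genes)
  nOcc <- round(nMtl * fracOccupied)
  stopIfNot(length(sites) >= nOcc,
            "not enough planted intergenic sites for occupied MTLs")
  margin <- 4000 + 2500 + config$intergenicWidth
  allGaps <- gapCenters(config, genes, margin)
  free <- allGaps[countOverlaps(allGaps, sites) == 0]
  stopIfNot(length(free) >= nMtl - nOcc,
            "not enough free gaps for unoccupied MTLs")
  withSeed(subSeed(config$seed, "mtl"), {
    sel <- c(sites[sort(sample(length(sites), nOcc))],
             free[sort(sample(length(free), nMtl - nOcc))])
    half <- floor(mtlWidth / 2)
    centers0 <- start0(sel)
    mtls <- gr0(as.character(seqnames(sel)), centers0 - half,
                centers0 - half + mtlWidth, layout = config$genome)
    mcols(mtls)$occupied <- rep(c(TRUE, FALSE),
                                c(nOcc, length(sel) - nOcc))
    mtls <- mtls[order(as.character(seqnames(mtls)), start(mtls))]
    list(mtls = mtls, fracOccupied = nOcc / nMtl)
  })
}
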