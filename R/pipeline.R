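#' Full-run configuration with the analysis defaults
#'
#' Bundles every stage parameter. The defaults are the analysis
#' constants used throughout: 1-kb sliding windows at a 200-bp step,
#' per-window threshold P < 1e-4, 2-kb merge distance, promoters
#' -0.5/+2 kb around the TSS, 4-kb intergenic exclusion, 200-bp profile
#' bins over +/-5 kb (+/-2.5 kb for quartile composites), 2-kb MTL
#' extension and 200-bp fragment extension.
#'
#' @param seed master seed for all synthetic stages.
#' @param chromatin a \code{\link{simChromatinConfig}}; defaults to one
#'   derived from \code{seed} with elongation-coupled depletion enabled.
#' @param windowSize,step,alpha,mergeGap enrichment-calling parameters.
#' @param nullMode,nRandomizations null-model choice.
#' @param promoterUp,promoterDown promoter geometry (bp).
#' @param intergenicExclusion intergenic distance rule (bp).
#' @param span,bin heatmap profile geometry (bp).
#' @param quartileSpan span of the expression-quartile composites (bp).
#' @param quartileBin bin width of the quartile composites (bp); 100 so
#'   that the +/-2.5 kb span tiles evenly.
#' @param mtlExtension MTL extension (bp).
#' @param fragmentLength fragment extension for midpoint assignment (bp).
#' @param nMtl,mtlFracOccupied synthetic MTL design.
#' @return a config list of class \code{RunConfig}.
#' @export
runConfig <- function(seed = 1,
                      chromatin = simChromatinConfig(seed = seed,
                                                     depletionMax = 0.6),
                      windowSize = 1000, step = 200, alpha = 1e-4,
                      mergeGap = 2000, nullMode = "poisson",
                      nRandomizations = 10,
                      promoterUp = 500, promoterDown = 2000,
                      intergenicExclusion = 4000,
                      span = 5000, bin = 200, quartileSpan = 2500,
                      quartileBin = 100,
                      mtlExtension = 2000, fragmentLength = 200,
                      nMtl = 30, mtlFracOccupied = 0.5) {
  structure(as.list(environment()), class = "RunConfig")
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates the gene universe, expression and reads for H2A.Z, H3K4me3
#' and H3K27me3; calls enriched intervals per mark; classifies promoter
#' chromatin states; builds the state-organised heatmap matrix and the
#' expression-quartile composites; computes interval overlaps and
#' intergenic MTL occupancy; runs the MS arm on emulated scenarios
#' (ubiquitin-site split 0.6/0.3/0.1 over K120/K121/K125, precursor
#' acetyl forms, mono- and diacetyl spectra, KO comparison). Writes BED
#' intervals, a bedGraph track, the promoter table, the heatmap TSV and
#' a machine-readable summary JSON to \code{outDir}. Deterministic for a
#' fixed config.
#'
#' @param config a \code{\link{runConfig}}.
#' @param outDir output directory (created if needed).
#' @return the summary list, invisibly.
#' @export
runAll <- function(config = runConfig(), outDir = tempfile("zedscape_")) {
  stopIfNot(inherits(config, "RunConfig"),
            "config must come from runConfig()")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cc <- config$chromatin
  layout <- cc$genome
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genes <- stage("simulate-genes", simulateGenes(cc))
  exprs <- stage("simulate-expression",
                 simulateExpression(genes, seed = cc$seed))
  writeGeneTable(genes, file.path(outDir, "genes.tsv"))
  writeExpressionTable(exprs$expression,
                       file.path(outDir, "expression.tsv"))
  writeGenomeLayout(layout, file.path(outDir, "genome.tsv"))

  marks <- c("H2A.Z", "H3K4me3", "H3K27me3")
  calls <- list()
  pointsByMark <- list()
  for (mk in marks) {
    sim <- stage(paste0("simulate-", mk),
                 simulateChip(cc, mk, expression = exprs$expression))
    pts <- stage("assign-fragments",
                 assignFragments(sim$reads, layout,
                                 config$fragmentLength))
    scan <- stage("scan-windows",
                  scanWindows(pts, layout, config$windowSize,
                              config$step))
    null <- stage("null-model",
                  nullRate(pts, layout, config$windowSize,
                           mode = config$nullMode,
                           nRandomizations = config$nRandomizations,
                           seed = cc$seed))
    scan <- scoreWindows(scan, null)
    ews <- stage("call-enriched",
                 callEnriched(scan, config$alpha, config$mergeGap,
                              mark = mk))
    calls[[mk]] <- ews
    pointsByMark[[mk]] <- pts
    safe <- gsub("[^A-Za-z0-9]", "_", mk)
    writeBed(enrichedIntervals(ews),
             file.path(outDir, paste0(safe, "_intervals.bed")))
    writeBedGraph(windowTrack(scan, rpm = TRUE),
                  file.path(outDir, paste0(safe, "_track.bedGraph")))
  }

  promoters <- stage("classify-promoters",
                     classifyPromoters(genes, calls[["H3K4me3"]],
                                       calls[["H3K27me3"]],
                                       up = config$promoterUp,
                                       down = config$promoterDown))
  utils::write.table(
    data.frame(gene_id = mcols(promoters)$gene_id,
               chrom = as.character(seqnames(promoters)),
               start = start0(promoters), end = end0(promoters),
               strand = as.character(strand(promoters)),
               k4 = mcols(promoters)$k4, k27 = mcols(promoters)$k27,
               state = as.character(mcols(promoters)$state)),
    file.path(outDir, "promoters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  pm <- stage("profile-matrix",
              profileMatrix(pointsByMark[["H2A.Z"]], genes,
                            span = config$span, bin = config$bin))
  states <- stats::setNames(as.character(mcols(promoters)$state),
                            mcols(promoters)$gene_id)
  heatmapExport(pm, states, file.path(outDir, "h2az_heatmap.tsv"))

  k4only <- names(states)[states == "K4-only"]
  quart <- expressionQuartiles(exprs$expression, k4only)
  pmQ <- stage("quartile-profiles",
               profileMatrix(pointsByMark[["H2A.Z"]], genes,
                             span = config$quartileSpan,
                             bin = config$quartileBin))
  centerBins <- abs(binCenters(pmQ)) <= 500
  quartileTss <- vapply(1:4, function(q) {
    cp <- composite(pmQ, names(quart)[quart == q])
    mean(compositeMean(cp)[centerBins])
  }, 0)

  venn <- stage("overlap",
                overlapFraction(calls[["H3K4me3"]], calls[["H2A.Z"]]))
  mtlSim <- stage("simulate-mtls",
                  simulateMtls(cc, nMtl = config$nMtl,
                               fracOccupied = config$mtlFracOccupied))
  mtl <- stage("mtl-occupancy",
               mtlOccupancy(mtlSim$mtls, genes, calls[["H2A.Z"]],
                            extension = config$mtlExtension,
                            exclusion = config$intergenicExclusion))

  # MS arm: emulated scenarios with known truth
  ub <- simulateXic(simMSConfig(
    weights = c(K120 = 0.6, K121 = 0.3, K125 = 0.1),
    noiseSdFraction = 0.05, seed = cc$seed))
  ubQuant <- isomerFractions(ub$chromatograms)
  writeChromatograms(ub$chromatograms,
                     file.path(outDir, "ub_isomers_xic.csv"))
  prec <- simulateXic(simMSConfig(
    weights = c("0ac" = 0.79, "1ac" = 0.16, "2ac" = 0.04,
                "3ac" = 0.008, "4ac" = 0.002),
    noiseSdFraction = 0.01, seed = cc$seed + 1))
  precQuant <- precursorAcetylDistribution(prec$chromatograms)
  mono <- simulateCompositeSpectrum(
    c(K4 = 0.2, K7 = 0.4, K11 = 0.3, K13 = 0.05, K15 = 0.05),
    noiseSdFraction = 0.01, seed = cc$seed)
  monoOcc <- monoacetylSiteOccupancy(mono$spectrum)
  di <- simulateCompositeSpectrum(
    c("K4+K7" = 0.5, "K7+K11" = 0.5),
    noiseSdFraction = 0.01, seed = cc$seed)
  diDec <- diacetylDeconvolution(di$spectrum)
  ko <- simulateXic(simMSConfig(
    weights = c(K120 = 0.6, K121 = 0.3, K125 = 0.1),
    totalIonCurrent = 1e5, noiseSdFraction = 0.05,
    seed = cc$seed + 2))
  koRatio <- koAbundanceRatio(ub$chromatograms, ko$chromatograms)

  summary <- list(
    seed = cc$seed,
    nGenes = length(genes),
    librarySizes = lapply(pointsByMark, length),
    nIntervals = lapply(calls, function(x)
      length(enrichedIntervals(x))),
    promoterStateCounts = as.list(stateCounts(promoters)),
    k4OverlapWithH2az = venn@fractionA,
    mtlOccupancy = mtl$fraction,
    quartileTssSignal = as.list(stats::setNames(
      quartileTss, paste0("Q", 1:4))),
    ubIsomerFractions = as.list(isomerFractionsOf(ubQuant)),
    precursorAcetyl = as.list(precQuant$fractions),
    anyAcetyl = precQuant$anyAcetyl,
    monoacetylOccupancy = as.list(monoOcc$occupancy),
    diacetylMarginals = as.list(diDec$marginals),
    koAbundanceRatio = koRatio$ratio)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
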