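test_that("the chromatin generator is deterministic under a fixed seed", {
  cc <- simChromatinConfig(genome = c(chrS = 1e6), nGenes = 20,
                           nIntergenicSites = 4, seed = 13)
  a <- simulateChip(cc, "H2A.Z")
  b <- simulateChip(cc, "H2A.Z")
  expect_identical(start(a$reads), start(b$reads))
  expect_identical(end(a$reads), end(b$reads))
  expect_identical(as.character(strand(a$reads)),
                   as.character(strand(b$reads)))
  expect_identical(mcols(simulateGenes(cc))$state,
                   mcols(simulateGenes(cc))$state)
})

test_that("fold = 1 yields statistically uniform reads with Poisson window counts", {
  cc <- simChromatinConfig(genome = c(chrS = 2e6), nGenes = 40,
                           enrichmentFold = 1, nIntergenicSites = 0,
                           seed = 5)
  sim <- simulateChip(cc, "H2A.Z")
  pts <- assignFragments(sim$reads, cc$genome, cc$fragmentLength)
  scan <- scanWindows(pts, cc$genome, 1000, 1000)  # tiles
  counts <- windowCounts(scan)
  lambda <- cc$backgroundRate * 1000
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 4 * se)
  # Poisson goodness of fit at alpha = 0.01 (pool upper tail)
  brk <- 0:11
  obs <- tabulate(pmin(counts, 11) + 1, nbins = 12)
  pr <- dpois(brk, lambda); pr[12] <- 1 - ppois(10, lambda)
  gof <- suppressWarnings(chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("planted windows reach fold x background while distal windows stay at background", {
  # single gene, fold 10, background 0.005 reads/bp: a 1-kb window inside
  # the planted promoter block averages ~50 midpoints vs ~5 distally
  plantedMeans <- distalMeans <- numeric(100)
  for (s in 1:100) {
    cc <- simChromatinConfig(genome = c(chrS = 1e5), nGenes = 1,
                             classProbs = c("K4-only" = 1, "bivalent" = 0,
                                            "K27-only" = 0, "no-mark" = 0),
                             enrichmentFold = 10, nIntergenicSites = 0,
                             seed = 1000 + s)
    sim <- simulateChip(cc, "H3K4me3")
    pts <- assignFragments(sim$reads, cc$genome, cc$fragmentLength)
    pl <- sim$truth$plantedIntervals[1]
    inPlanted <- GRanges("chrS", IRanges(start(pl), start(pl) + 999))
    tss <- mcols(simulateGenes(cc))$tss[1]
    distal0 <- if (tss > 5e4) 1e4 else 8e4
    distal <- GRanges("chrS", IRanges(distal0 + 1, distal0 + 1000))
    plantedMeans[s] <- countOverlaps(inPlanted, pts)
    distalMeans[s] <- countOverlaps(distal, pts)
  }
  expect_lt(abs(mean(plantedMeans) - 50), 3.5 * sqrt(50 / 100))
  expect_lt(abs(mean(distalMeans) - 5), 3.5 * sqrt(5 / 100))
})

test_that("expression spans quartiles evenly and respects chromatin state", {
  g <- statefulGenes(c(rep("K4-only", 8), rep("no-mark", 4)))
  ex <- simulateExpression(g, seed = 3)
  expect_identical(as.integer(table(ex$quartile)), rep(2L, 4))
  k4 <- mcols(g)$gene_id[mcols(g)$state == "K4-only"]
  expect_gt(max(ex$expression[k4]) / min(ex$expression[k4]), 1)
  off <- setdiff(names(ex$expression), k4)
  expect_true(all(ex$expression[off] < ex$floor))
  # fixed seed reproduces the table
  ex2 <- simulateExpression(g, seed = 3)
  expect_identical(ex2$expression, ex$expression)
  # all genes unmarked: everything below the positive floor
  g0 <- statefulGenes(rep("no-mark", 6))
  ex0 <- simulateExpression(g0, seed = 3)
  expect_true(all(ex0$expression < ex0$floor))
})

test_that("expressed K4-only genes span at least three orders of magnitude", {
  cc <- simChromatinConfig(seed = 21)
  g <- simulateGenes(cc)
  ex <- simulateExpression(g, seed = 21)
  v <- ex$expression[names(ex$quartile)]
  expect_gt(log10(max(v) / min(v)), 3)
})

test_that("synthetic XICs carry their designed areas", {
  # pure species, no noise: trapezoid recovers the total ion current
  x <- simulateXic(simMSConfig(c(a = 1, b = 0, c = 0), seed = 2))
  areas <- vapply(x$chromatograms, function(ch)
    suppressWarnings(integratePeak(ch)), 0)
  expect_lt(abs(areas[["a"]] - 1e6) / 1e6, 1e-3)
  expect_equal(unname(areas[c("b", "c")]), c(0, 0))
  # the ubiquitin-site scenario at zero noise: ratios 6:3:1 within 0.5%
  x2 <- simulateXic(simMSConfig(c(K120 = 0.6, K121 = 0.3, K125 = 0.1),
                                seed = 2))
  fr <- isomerFractionsOf(isomerFractions(x2$chromatograms))
  expect_lt(max(abs(fr - c(0.6, 0.3, 0.1))), 0.005)
})

test_that("XIC area recovery stays within 5% at 5% multiplicative noise", {
  errs <- vapply(1:100, function(s) {
    x <- simulateXic(simMSConfig(c(a = 0.5, b = 0.5),
                                 noiseSdFraction = 0.05, rtStep = 0.01,
                                 seed = s))
    a <- integratePeak(x$chromatograms[["a"]])
    abs(a - x$truth$areas[["a"]]) / x$truth$areas[["a"]]
  }, 0)
  expect_lt(max(errs), 0.05)
})

test_that("composite-spectrum generator reproduces designed marginals", {
  m <- simulateCompositeSpectrum(c(K7 = 1), seed = 1)
  expect_equal(unname(m$truth$marginals), c(0, 1, 0, 0, 0))
  occ <- monoacetylSiteOccupancy(m$spectrum)$occupancy
  expect_equal(unname(occ), c(0, 1, 0, 0, 0))

  pairs <- combn(c("K4", "K7", "K11", "K13", "K15"), 2,
                 paste, collapse = "+")
  w <- setNames(rep(0.1, 10), pairs)
  d <- simulateCompositeSpectrum(w, seed = 1)
  expect_equal(unname(d$truth$marginals), rep(0.4, 5))

  d2 <- simulateCompositeSpectrum(c("K4+K11" = 1), seed = 1)
  expect_equal(unname(d2$truth$marginals), c(1, 0, 1, 0, 0))

  expect_error(simulateCompositeSpectrum(c(K7 = 1), acetylCount = 2),
               "inconsistent")
  expect_error(simulateCompositeSpectrum(c(K9 = 1)), "site")
})

test_that("planted regions never exceed chromosome bounds", {
  cc <- simChromatinConfig(genome = c(chrS = 1e6), nGenes = 20,
                           nIntergenicSites = 0, seed = 9)
  sim <- simulateChip(cc, "H3K4me3")
  pl <- sim$truth$plantedIntervals
  expect_true(all(start(pl) >= 1))
  expect_true(all(end(pl) <= 1e6))
})
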