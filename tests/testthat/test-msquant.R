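test_that("peak integration recovers known areas and is linear", {
  rect <- rectTrace(height = 10, from = 5, to = 7)
  expect_equal(integratePeak(rect), 20, tolerance = 1e-2)
  # Gaussian with unit analytic area, densely sampled
  rt <- seq(0, 20, by = 0.002)
  gauss <- chromatogram("g", rt, dnorm(rt, 10, 0.2))
  expect_equal(integratePeak(gauss), 1, tolerance = 1e-3)
  # linearity
  g3 <- chromatogram("g3", rt, 3.7 * dnorm(rt, 10, 0.2))
  expect_equal(integratePeak(g3), 3.7 * integratePeak(gauss),
               tolerance = 1e-9)
  # explicit bounds restrict the integral
  half <- integratePeak(gauss, bounds = c(0, 10))
  expect_equal(half, 0.5, tolerance = 1e-3)
  expect_error(integratePeak(gauss, bounds = c(-5, 10)), "extent")
  # all-zero trace warns and returns 0
  zero <- chromatogram("z", rt, rep(0, length(rt)))
  expect_warning(a <- integratePeak(zero), "all-zero")
  expect_equal(a, 0)
})

test_that("auto bounds are valley-to-valley and exclude neighbouring peaks", {
  rt <- seq(0, 30, by = 0.005)
  two <- chromatogram("two", rt,
                      dnorm(rt, 10, 0.2) + 0.5 * dnorm(rt, 14, 0.2))
  # integrating the dominant peak only: area ~1, not ~1.5
  expect_equal(integratePeak(two), 1, tolerance = 5e-3)
})

test_that("isomer fractions normalize integrated areas", {
  mk <- function(sp, area, center)
    chromatogram(sp, seq(0, 30, 0.005),
                 area * dnorm(seq(0, 30, 0.005), center, 0.15))
  chroms <- list(mk("K120", 6, 10), mk("K121", 3, 14), mk("K125", 1, 18))
  fr <- isomerFractionsOf(isomerFractions(chroms))
  expect_equal(unname(fr), c(0.6, 0.3, 0.1), tolerance = 1e-3)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  single <- isomerFractions(chroms[[1]])
  expect_equal(unname(isomerFractionsOf(single)), 1)
  rt <- seq(0, 10, 0.01)
  allzero <- list(chromatogram("a", rt, rt * 0),
                  chromatogram("b", rt, rt * 0))
  expect_error(isomerFractions(allzero), "zero")
})

test_that("XIC recovery stays within 0.05 of truth at 5% noise over 100 seeds", {
  worst <- 0
  for (s in 1:100) {
    x <- simulateXic(simMSConfig(c(K120 = 0.6, K121 = 0.3, K125 = 0.1),
                                 noiseSdFraction = 0.05, rtStep = 0.01,
                                 seed = s))
    fr <- isomerFractionsOf(isomerFractions(x$chromatograms))
    worst <- max(worst, max(abs(fr - x$truth$weights)))
  }
  expect_lt(worst, 0.05)
})

test_that("precursor acetyl distribution reports per-form and any-acetyl fractions", {
  mk <- function(sp, area, center) {
    rt <- seq(0, 30, 0.005)
    chromatogram(sp, rt, area * dnorm(rt, center, 0.15))
  }
  chroms <- list(mk("0ac", 87, 8), mk("1ac", 9, 12), mk("2ac", 4, 16),
                 mk("3ac", 0, 20), mk("4ac", 0, 24))
  r <- precursorAcetylDistribution(chroms)
  expect_equal(unname(r$fractions[c("1ac", "2ac")]), c(0.09, 0.04),
               tolerance = 1e-3)
  expect_equal(r$anyAcetyl, 0.13, tolerance = 1e-3)
  expect_error(precursorAcetylDistribution(chroms[-2]), "1ac")
  only0 <- list(mk("0ac", 1, 8), mk("1ac", 0, 12), mk("2ac", 0, 16),
                mk("3ac", 0, 20), mk("4ac", 0, 24))
  expect_equal(precursorAcetylDistribution(only0)$anyAcetyl, 0)
})

test_that("precursor recovery is within 0.01 of truth at 1% noise", {
  truth <- c("0ac" = 0.79, "1ac" = 0.16, "2ac" = 0.04,
             "3ac" = 0.008, "4ac" = 0.002)
  for (s in 1:20) {
    x <- simulateXic(simMSConfig(truth, noiseSdFraction = 0.01,
                                 rtStep = 0.01, seed = 100 + s))
    r <- precursorAcetylDistribution(x$chromatograms)
    expect_lt(max(abs(r$fractions - truth)), 0.01)
  }
})

test_that("monoacetyl occupancies renormalize b-ion proxies", {
  spec <- compositeSpectrum(c("K4", "K7", "K11", "K13", "K15"),
                            acetylCurrent = c(0, 5e5, 0, 0, 0),
                            propionylCurrent = c(1e6, 5e5, 1e6, 1e6, 1e6))
  occ <- monoacetylSiteOccupancy(spec)
  expect_equal(unname(occ$occupancy), c(0, 1, 0, 0, 0))
  even <- compositeSpectrum(paste0("K", 1:5), rep(2e5, 5), rep(8e5, 5))
  expect_equal(unname(monoacetylSiteOccupancy(even)$occupancy),
               rep(0.2, 5))
  m <- simulateCompositeSpectrum(c(K4 = 0.2, K7 = 0.4, K11 = 0.3,
                                   K13 = 0.05, K15 = 0.05), seed = 2)
  expect_equal(unname(monoacetylSiteOccupancy(m$spectrum)$occupancy),
               c(0.2, 0.4, 0.3, 0.05, 0.05), tolerance = 1e-9)
  dead <- compositeSpectrum(c("K4", "K7"), c(0, 1), c(0, 1))
  expect_error(monoacetylSiteOccupancy(dead), "K4")
})

test_that("diacetyl deconvolution recovers pure and mixed isomer sets", {
  pure <- simulateCompositeSpectrum(c("K4+K7" = 1), seed = 1)
  d <- diacetylDeconvolution(pure$spectrum)
  expect_equal(unname(d$weights["K4+K7"]), 1, tolerance = 1e-6)
  expect_equal(unname(d$marginals), c(1, 1, 0, 0, 0), tolerance = 1e-6)
  mixed <- simulateCompositeSpectrum(c("K4+K7" = 0.5, "K7+K11" = 0.5),
                                     noiseSdFraction = 0.01, seed = 4)
  dm <- diacetylDeconvolution(mixed$spectrum)
  expect_lt(max(abs(dm$marginals - c(0.5, 1, 0.5, 0, 0))), 0.02)
  allzero <- compositeSpectrum(paste0("K", 1:5), rep(0, 5), rep(1, 5))
  expect_error(diacetylDeconvolution(allzero), "infeasible")
})

test_that("the least-squares solver matches the simplex grid oracle", {
  sites <- c("K4", "K7", "K11", "K13", "K15")
  pairs <- combn(5, 2)
  A <- matrix(0, 5, 10)
  for (p in 1:10) A[pairs[, p], p] <- 1
  # uniform spectrum: every site's acetyl fraction 0.4
  spec <- compositeSpectrum(sites, rep(4e5, 5), rep(6e5, 5))
  d <- diacetylDeconvolution(spec)
  expect_lt(max(abs(d$marginals - 0.4)), 0.02)
  expect_lte(d$objective, gridOracleObjective(A, rep(0.4, 5)) + 1e-6)
  expect_true(d$nonUnique)
  # a noisy asymmetric instance
  set.seed(44)
  f <- c(0.7, 0.9, 0.3, 0.1, 0.0) + runif(5, 0, 0.02)
  spec2 <- compositeSpectrum(sites, f * 1e6, (1 - f) * 1e6)
  d2 <- diacetylDeconvolution(spec2)
  expect_lte(d2$objective, gridOracleObjective(A, f) + 1e-6)
})

test_that("diacetyl marginal recovery: median error <= 0.03 over 100 noisy instances", {
  pairNames <- combn(c("K4", "K7", "K11", "K13", "K15"), 2,
                     paste, collapse = "+")
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    w <- rexp(10); w <- setNames(w / sum(w), pairNames)
    sim <- simulateCompositeSpectrum(w, noiseSdFraction = 0.05,
                                     seed = s)
    d <- diacetylDeconvolution(sim$spectrum)
    median(abs(d$marginals - sim$truth$marginals))
  }, 0)
  expect_lte(median(errs), 0.03)
})

test_that("KO/WT abundance ratios compare total ubiquityl areas", {
  wt <- simulateXic(simMSConfig(c(K120 = 0.6, K121 = 0.3, K125 = 0.1),
                                noiseSdFraction = 0.05, rtStep = 0.01,
                                seed = 7))
  expect_equal(koAbundanceRatio(wt$chromatograms,
                                wt$chromatograms)$ratio, 1)
  ko <- simulateXic(simMSConfig(c(K120 = 0.6, K121 = 0.3, K125 = 0.1),
                                totalIonCurrent = 1e5,
                                noiseSdFraction = 0.05, rtStep = 0.01,
                                seed = 8))
  r <- koAbundanceRatio(wt$chromatograms, ko$chromatograms)
  expect_equal(r$ratio, 0.1, tolerance = 0.02)
  expect_true(r$reduced)
  rt <- seq(0, 10, 0.01)
  zeroKo <- list(chromatogram("a", rt, rt * 0))
  expect_equal(koAbundanceRatio(wt$chromatograms, zeroKo)$ratio, 0)
  expect_error(koAbundanceRatio(zeroKo, zeroKo), "zero")
})

test_that("chromatogram and spectrum CSV dialects round-trip", {
  x <- simulateXic(simMSConfig(c(a = 0.7, b = 0.3), rtStep = 0.05,
                               seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  writeChromatograms(x$chromatograms, f)
  back <- readChromatograms(f)
  expect_equal(names(back), c("a", "b"))
  expect_equal(back$a@intensity, x$chromatograms$a@intensity,
               tolerance = 1e-6)
  spec <- simulateCompositeSpectrum(c(K7 = 1), seed = 1)$spectrum
  writeCompositeSpectrum(spec, f)
  spec2 <- readCompositeSpectrum(f)
  expect_equal(spec2@acetylCurrent, spec@acetylCurrent, tolerance = 1e-6)
  expect_identical(spec2@sites, spec@sites)
})

test_that("acetyl stoichiometry assembles the MS arm into one object", {
  prec <- simulateXic(simMSConfig(c("0ac" = 0.79, "1ac" = 0.16,
                                    "2ac" = 0.04, "3ac" = 0.008,
                                    "4ac" = 0.002),
                                  noiseSdFraction = 0.01, rtStep = 0.01,
                                  seed = 5))
  mono <- simulateCompositeSpectrum(c(K7 = 0.6, K11 = 0.4), seed = 5)
  di <- simulateCompositeSpectrum(c("K4+K7" = 0.5, "K7+K11" = 0.5),
                                  seed = 5)
  st <- acetylStoichiometry(prec$chromatograms, mono$spectrum,
                            di$spectrum)
  expect_s4_class(st, "AcetylStoichiometry")
  expect_equal(st@anyAcetyl, 0.21, tolerance = 0.01)
  expect_equal(sum(st@monoOccupancy), 1, tolerance = 1e-9)
  expect_equal(sum(st@diMarginals), 2, tolerance = 1e-6)
})
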