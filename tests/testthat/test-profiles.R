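test_that("profile matrices have the documented shape and bin assignment", {
  anchors <- makeGeneTable(c("a", "b"), c("chr1", "chr1"),
                           c(20000, 40000), c(25000, 35000), c("+", "-"))
  empty <- profileMatrix(GPos(character(0), integer(0)), anchors,
                         librarySize = 1)
  expect_equal(dim(profileValues(empty)), c(2L, 50L))
  expect_true(all(profileValues(empty) == 0))

  # one point at TSS+100 of the plus-strand anchor
  pt <- GPos("chr1", 20101)  # 0-based 20100
  pm <- profileMatrix(pt, anchors, librarySize = 1e6)
  hit <- which(profileCounts(pm)["a", ] > 0)
  expect_equal(hit, 26L)  # bin covering offsets [0, 200)
  expect_equal(binCenters(pm)[hit], 100)
  # the mirrored point on the minus-strand anchor lands in the same bin
  ptm <- GPos("chr1", 39901)  # 0-based 39900 = tss - 100
  pmm <- profileMatrix(ptm, anchors, librarySize = 1e6)
  expect_equal(which(profileCounts(pmm)["b", ] > 0), 26L)
})

test_that("strand flipping is an exact mirror of the count matrix", {
  set.seed(9)
  offs <- sample(-4999:4999, 200, replace = TRUE)
  plus <- makeGeneTable("p", "chr1", 50000, 55000, "+")
  minus <- makeGeneTable("m", "chr1", 50000, 45000, "-")
  ptsPlus <- GPos("chr1", 50000 + offs + 1)
  ptsMinus <- GPos("chr1", 50000 - offs + 1)
  a <- profileCounts(profileMatrix(ptsPlus, plus, librarySize = 200))
  b <- profileCounts(profileMatrix(ptsMinus, minus, librarySize = 200))
  expect_identical(unname(a), unname(b))
})

test_that("counts are conserved for anchors away from chromosome edges", {
  set.seed(10)
  anchors <- makeGeneTable("a", "chr1", 100000, 105000, "+")
  p0 <- 100000 + sample(-5000:4999, 300, replace = TRUE)
  pm <- profileMatrix(GPos("chr1", p0 + 1), anchors, librarySize = 300)
  expect_equal(sum(profileCounts(pm)), 300L)
})

test_that("bins off the chromosome end are NA but the row is kept", {
  lay <- c(chr1 = 30000)
  anchors <- makeGeneTable("edge", "chr1", 2000, 9000, "+",
                           layout = lay)
  pm <- profileMatrix(GPos("chr1", 2500, seqinfo = Seqinfo("chr1", 30000)),
                      anchors, librarySize = 1)
  v <- profileValues(pm)
  expect_equal(nrow(v), 1L)
  expect_true(all(is.na(v[1, binCenters(pm) < -2000])))
  expect_true(all(!is.na(v[1, binCenters(pm) > -1800])))
})

test_that("composites average rows, ignore NA bins, and are permutation-invariant", {
  anchors <- makeGeneTable(c("a", "b"), c("chr1", "chr1"),
                           c(20000, 60000), c(25000, 65000), c("+", "+"))
  pts <- GPos("chr1", c(20101, 20101, 60101))
  pm <- profileMatrix(pts, anchors, librarySize = 3)
  one <- composite(pm, "a")
  expect_equal(compositeMean(one), profileValues(pm)["a", ],
               ignore_attr = TRUE)
  both <- composite(pm)
  expect_equal(compositeMean(both),
               colMeans(profileValues(pm)), ignore_attr = TRUE)
  perm <- composite(pm, c("b", "a"))
  expect_equal(compositeMean(perm), compositeMean(both))
  expect_error(composite(pm, integer(0)), "empty")
  expect_error(composite(pm, "zz"), "unknown")
})

test_that("synthetic H2A.Z composites are bimodal around the TSS", {
  cc <- simChromatinConfig(genome = c(chrS = 2e6), nGenes = 40,
                           enrichmentFold = 20, nIntergenicSites = 0,
                           seed = 31)
  sim <- simulateChip(cc, "H2A.Z")
  pts <- assignFragments(sim$reads, cc$genome, cc$fragmentLength)
  g <- simulateGenes(cc)
  marked <- mcols(g)$state %in% c("K4-only", "bivalent")
  pm <- profileMatrix(pts, g, span = 5000, bin = 100)
  m <- compositeMean(composite(pm, which(marked)))
  bc <- binCenters(pm)
  left <- which.max(m[bc < 0])
  right <- which(bc > 0)[which.max(m[bc > 0])]
  mid <- bc > bc[left] & bc < bc[right]
  expect_lt(min(m[mid]), m[left])
  expect_lt(min(m[mid]), m[right])
  expect_lte(abs(bc[left] + 150), 100)
  expect_lte(abs(bc[right] - 150), 100)
})

test_that("expression quartile assignment is balanced, stable and monotone", {
  ex <- c(a = 5, b = 1, c = 9, d = 3, e = 7, f = 2, g = 8, h = 4)
  q <- expressionQuartiles(ex)
  expect_equal(as.integer(table(q)), rep(2L, 4))
  expect_equal(unname(q[c("b", "f")]), c(1L, 1L))
  expect_equal(unname(q[c("c", "g")]), c(4L, 4L))
  # ties: sizes still differ by at most one, assignment stable in order
  tied <- setNames(rep(1, 7), letters[1:7])
  qt <- expressionQuartiles(tied)
  expect_lte(diff(range(table(qt))), 1)
  expect_equal(unname(qt["a"]), 1L)
  # quartile means are monotone non-decreasing
  set.seed(6)
  for (i in 1:20) {
    v <- setNames(rlnorm(23), paste0("x", 1:23))
    qq <- expressionQuartiles(v)
    mu <- tapply(v, qq, mean)
    expect_true(all(diff(mu) >= 0))
  }
  expect_error(expressionQuartiles(ex, c("a", "zz")), "zz")
})

test_that("heatmap export groups by state, sorts by signal, and round-trips", {
  anchors <- makeGeneTable(c("lo", "hi", "biv"), rep("chr1", 3),
                           c(20000, 60000, 100000),
                           c(25000, 65000, 105000), rep("+", 3))
  pts <- GPos("chr1", c(rep(60101, 5), 20101, 100101))
  pm <- profileMatrix(pts, anchors, librarySize = 7)
  states <- c(lo = "K4-only", hi = "K4-only", biv = "bivalent")
  f <- withr::local_tempfile(fileext = ".tsv")
  msgs <- capture_messages(out <- heatmapExport(pm, states, f))
  expect_match(msgs, "omitted")
  # group order first (both K4-only before bivalent), then signal desc
  expect_equal(out$region_id, c("hi", "lo", "biv"))
  expect_equal(attr(out, "emptyGroups"), c("K27-only", "no-mark"))
  back <- readHeatmapTable(f)
  expect_equal(back$region_id, out$region_id)
  numeric_cols <- as.matrix(back[, -(1:2)])
  expect_identical(unname(numeric_cols),
                   unname(as.matrix(out[, -(1:2)])))
  # within-group order swaps when the signals swap
  pts2 <- GPos("chr1", c(rep(20101, 5), 60101, 100101))
  pm2 <- profileMatrix(pts2, anchors, librarySize = 7)
  out2 <- suppressMessages(heatmapExport(pm2, states, f))
  expect_equal(out2$region_id, c("lo", "hi", "biv"))
})
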