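test_that("depth filter requires the minimum in every sample, boundary inclusive", {
  cov <- rbind(c(12L, 9L, 30L, 15L),
               c(10L, 10L, 10L, 10L),
               c(50L, 50L, 50L, 9L))
  mc <- makeCounts(matrix(0L, 3, 4), cov, pos = c(100L, 200L, 300L),
                   group = c("a", "a", "b", "b"))
  kept <- filterByDepth(mc, 10L)
  expect_equal(GenomicRanges::start(kept), 200L)   # {12,9,30,15} and {..,9} dropped
  expect_equal(nrow(filterByDepth(mc, 0L)), 3L)    # minDepth 0 is the identity
})

test_that("blacklist exclusion is containment with half-open BED semantics", {
  # BED [50,150) covers 1-based positions 51..150
  bed <- withr::local_tempfile(lines = "chr1\t50\t150")
  bl <- readBed(bed)
  mc <- makeCounts(matrix(0L, 2, 2), matrix(10L, 2, 2), pos = c(101L, 151L))
  kept <- filterBlacklist(mc, bl)
  expect_equal(GenomicRanges::start(kept), 151L)
  expect_equal(nrow(filterBlacklist(mc, GenomicRanges::GRanges())), 2L)
})

test_that("normalisation scales to the median of per-sample medians", {
  cov <- cbind(rep(20L, 5), rep(40L, 5))
  meth <- cbind(rep(10L, 5), rep(20L, 5))
  mc <- makeCounts(meth, cov, pos = 1:5 * 100L)
  out <- normalizeCoverage(mc)
  sf <- S4Vectors::metadata(out)$scaleFactors
  expect_equal(unname(sf), c(1.5, 0.75))           # medians {20,40} -> m*=30

  same <- normalizeCoverage(makeCounts(meth, cbind(rep(20L, 5), rep(20L, 5)),
                                       pos = 1:5 * 100L))
  expect_equal(unname(S4Vectors::metadata(same)$scaleFactors), c(1, 1))
  expect_identical(totalCounts(same), matrix(20L, 5, 2,
    dimnames = dimnames(totalCounts(same))))
})

test_that("normalisation preserves methylation proportions", {
  # sample medians {20, 40} -> target 30, factors {1.5, 0.75};
  # the 8/10 site under factor 1.5 -> 15 reads, 12 methylated
  cov <- cbind(c(10L, 20L, 20L), c(30L, 40L, 40L))
  meth <- cbind(c(8L, 5L, 0L), c(15L, 9L, 30L))
  mc <- makeCounts(meth, cov, pos = c(100L, 200L, 300L))
  out <- normalizeCoverage(mc)
  expect_equal(unname(S4Vectors::metadata(out)$scaleFactors), c(1.5, 0.75))
  expect_equal(unname(totalCounts(out)[1, 1]), 15L)
  expect_equal(unname(methCounts(out)[1, 1]), 12L)
  expect_true(all(methCounts(out) <= totalCounts(out)))

  zed <- makeCounts(matrix(0L, 2, 2), matrix(0L, 2, 2), pos = c(1L, 2L))
  expect_error(normalizeCoverage(zed), "zero median")
})

test_that("window membership follows the sliding-window arithmetic", {
  # CpG at 1-based 301 belongs to windows starting (0-based) 125 and 250
  mc <- makeCounts(matrix(2L, 1, 2), matrix(10L, 1, 2), pos = 301L)
  tiles <- tileCounts(mc)
  expect_equal(GenomicRanges::start(tiles), c(126L, 251L))
  expect_equal(GenomicRanges::end(tiles), c(375L, 500L))

  # near the chromosome start only the window at 0 is valid
  mc2 <- makeCounts(matrix(2L, 1, 2), matrix(10L, 1, 2), pos = 101L)
  expect_equal(GenomicRanges::start(tileCounts(mc2)), 1L)
})

test_that("tile counts are sums over member CpGs", {
  # two CpGs (8/10 and 2/10) in one tile for one sample
  mc <- makeCounts(cbind(c(8L, 2L)), cbind(c(10L, 10L)),
                   pos = c(10L, 20L), group = "a")
  # single-sample container is disallowed by merge, but tiling accepts any
  tiles <- tileCounts(mc)
  expect_equal(methCounts(tiles)[1, 1], 10L)
  expect_equal(totalCounts(tiles)[1, 1], 20L)
  expect_equal(SummarizedExperiment::rowData(tiles)$n_cpgs[1], 2L)
})

test_that("tiling conserves per-sample coverage and respects minCpgs", {
  set.seed(3)
  n <- 60
  cov <- matrix(rpois(n * 3, 25) + 10L, n, 3)
  meth <- matrix(rbinom(n * 3, cov, 0.4), n, 3)
  mc <- makeCounts(meth, cov, pos = sort(sample(5000, n)),
                   group = c("a", "a", "b"))
  tiles <- tileCounts(mc)
  # every CpG feeds exactly 2 windows except those within 125 bp of start
  nEarly <- sum(GenomicRanges::start(mc) <= 125)
  expect_equal(colSums(totalCounts(tiles)),
               2 * colSums(totalCounts(mc)) - colSums(totalCounts(mc)[
                 GenomicRanges::start(mc) <= 125, , drop = FALSE]))
  # with step = size each CpG belongs to exactly one tile
  flat <- tileCounts(mc, tilingParams(tileSize = 250, stepSize = 250))
  expect_equal(colSums(totalCounts(flat)), colSums(totalCounts(mc)))
  expect_equal(sum(SummarizedExperiment::rowData(flat)$n_cpgs), n)
  # minCpgs filters windows
  strict <- tileCounts(mc, tilingParams(minCpgs = 3))
  expect_true(all(SummarizedExperiment::rowData(strict)$n_cpgs >= 3))
})

test_that("tile count is monotone non-increasing in the depth threshold", {
  set.seed(4)
  n <- 80
  cov <- matrix(rpois(n * 4, 15), n, 4)
  meth <- matrix(rbinom(n * 4, cov, 0.5), n, 4)
  mc <- makeCounts(meth, cov, pos = sort(sample(20000, n)),
                   group = c("a", "a", "b", "b"))
  sizes <- vapply(c(0L, 5L, 10L, 15L), function(d)
    nrow(tileCounts(suppressWarnings(filterByDepth(mc, d)))), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("promoter restriction is strand-aware interval overlap", {
  tp <- tilingParams()
  gPlus <- makeGene(tss = 10001L, strand = "+")   # promoter [8001, 10201]
  tiles <- makeTiles(starts = c(7901L, 10251L), ends = c(8150L, 10500L))
  kept <- restrictToPromoters(tiles, gPlus, tp)
  expect_equal(GenomicRanges::start(kept), 7901L)  # overlaps; second dropped
  expect_equal(unlist(SummarizedExperiment::rowData(kept)$genes), "GeneX")

  gMinus <- makeGene(tss = 10001L, strand = "-")  # promoter [9801, 12001]
  keptM <- restrictToPromoters(tiles, gMinus, tp)
  expect_equal(GenomicRanges::start(keptM), 10251L)

  unstranded <- gPlus
  GenomicRanges::strand(unstranded) <- "*"
  expect_error(restrictToPromoters(tiles, unstranded, tp), "strand")
})

test_that("a tile overlapping two promoters carries both gene symbols", {
  # GeneA (-, TSS 5001): promoter [4801, 7001]; GeneB (+, TSS 5600):
  # promoter [3600, 5800]; the tile [5301, 5550] overlaps both
  g2 <- c(makeGene(5001L, "-", "GeneA"), makeGene(5600L, "+", "GeneB"))
  tiles <- makeTiles(starts = 5301L, ends = 5550L)
  kept <- restrictToPromoters(tiles, g2, tilingParams())
  expect_setequal(unlist(SummarizedExperiment::rowData(kept)$genes),
                  c("GeneA", "GeneB"))
})
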