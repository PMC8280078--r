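test_that("identical groups give zero difference and p = 1", {
  r <- logisticDMTest(c(6L, 4L), c(10L, 10L), c(6L, 4L), c(10L, 10L))
  expect_equal(r$methDiff, 0)
  expect_equal(r$pValue, 1)

  # pooled 60/100 vs 80/100 -> +20 percentage points
  r2 <- logisticDMTest(c(30L, 30L), c(50L, 50L), c(40L, 40L), c(50L, 50L))
  expect_equal(r2$methDiff, 20)
  expect_gt(r2$logOddsRatio, 0)
})

test_that("the LRT and log odds ratio match a glm fit on per-sample observations", {
  set.seed(21)
  for (i in 1:25) {
    nCtl <- sample(2:4, 1); nExp <- sample(2:4, 1)
    tCtl <- rpois(nCtl, 40) + 10L; tExp <- rpois(nExp, 40) + 10L
    mCtl <- rbinom(nCtl, tCtl, runif(1, 0.2, 0.8))
    mExp <- rbinom(nExp, tExp, runif(1, 0.2, 0.8))
    if (sum(mCtl) == 0 || sum(mExp) == 0 ||
        sum(mCtl) == sum(tCtl) || sum(mExp) == sum(tExp)) next
    r <- logisticDMTest(mCtl, tCtl, mExp, tExp)
    g <- rep(c(0, 1), c(nCtl, nExp))
    fit <- glm(cbind(c(mCtl, mExp), c(tCtl - mCtl, tExp - mExp)) ~ g,
               family = binomial())
    pGlm <- pchisq(fit$null.deviance - fit$deviance, df = 1,
                   lower.tail = FALSE)
    expect_equal(r$pValue, pGlm, tolerance = 1e-8)
    expect_equal(r$logOddsRatio, unname(coef(fit)[2]), tolerance = 1e-6)
  }
})

test_that("swapping group labels negates the effect and keeps p", {
  set.seed(22)
  for (i in 1:10) {
    t1 <- rpois(3, 30) + 10L; t2 <- rpois(4, 30) + 10L
    m1 <- rbinom(3, t1, 0.3); m2 <- rbinom(4, t2, 0.5)
    a <- logisticDMTest(m1, t1, m2, t2)
    b <- logisticDMTest(m2, t2, m1, t1)
    expect_equal(a$methDiff, -b$methDiff)
    expect_equal(a$logOddsRatio, -b$logOddsRatio)
    expect_equal(a$pValue, b$pValue)
  }
})

test_that("degenerate tiles take the separation-safe path", {
  r0 <- logisticDMTest(c(0L, 0L), c(10L, 12L), c(0L, 0L), c(9L, 11L))
  expect_equal(r0$pValue, 1)
  expect_equal(r0$logOddsRatio, 0)
  r1 <- logisticDMTest(c(10L, 12L), c(10L, 12L), c(9L, 11L), c(9L, 11L))
  expect_equal(r1$pValue, 1)
  expect_equal(r1$logOddsRatio, 0)
  # full separation still yields a finite log OR and a small p
  rs <- logisticDMTest(c(0L, 0L), c(20L, 20L), c(20L, 20L), c(20L, 20L))
  expect_true(is.finite(rs$logOddsRatio))
  expect_lt(rs$pValue, 1e-6)
  expect_error(logisticDMTest(0L, 0L, 5L, 10L), "zero total")
})

test_that("sliding-linear-model pi0 is near 1 under the uniform null", {
  set.seed(101)
  pi0 <- slimPi0(runif(10000))
  expect_gte(pi0, 0.9)
  expect_lte(pi0, 1)
})

test_that("q-values are order-preserving, bounded, and BH-equivalent at pi0 = 1", {
  set.seed(31)
  p <- c(runif(400), rbeta(100, 0.2, 1))
  q <- slimAdjust(p)
  expect_true(all(q >= 0 & q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  # forcing pi0 = 1 reduces exactly to Benjamini-Hochberg
  expect_equal(as.numeric(slimAdjust(p, pi0 = 1)), p.adjust(p, "BH"))
  # BH mode matches the independent step-up oracle exactly
  expect_equal(as.numeric(slimAdjust(p, method = "BH")), directBH(p))
  # boundary: all p = 1
  expect_equal(as.numeric(slimAdjust(rep(1, 20))), rep(1, 20))
  expect_length(slimAdjust(numeric(0)), 0)
  expect_error(slimAdjust(c(0.5, 1.2)), "within")
})

test_that("status calls follow the strict q-and-difference rule", {
  df <- data.frame(meth_diff = c(6, 4, -12, -4.9),
                   q_value = c(0.05, 0.001, 5e-9, 0.2))
  out <- callStatus(df, dmParams())
  expect_equal(out$status,
               c("hyper", "not_significant", "hypo", "not_significant"))
  expect_equal(out$robust, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("planted effects are recovered with the right sign and direction", {
  # power check: >= 15% effects at ~30x coverage should mostly be called
  p <- simParams(nGenes = 80, fracInjuryTiles = 0.3,
                 injuryEffectRange = c(15, 30), seed = 55)
  g <- simulateGenome(p)
  sim <- simulateCounts(p, g)
  mc <- normalizeCoverage(filterByDepth(sim$counts, 10))
  tiles <- restrictToPromoters(tileCounts(mc), g$genes)
  res <- calculateDiffMeth(tiles, "Sham-Vehicle", "SNI-Vehicle")
  # evaluate on tiles exactly matching a planted effect unit
  key <- paste(res$chrom, res$start)
  truth <- sim$truth[sim$truth$label != "null", ]
  idx <- match(paste(truth$chrom, truth$start), key)
  hit <- !is.na(idx)
  called <- res$status[idx[hit]]
  wantHyper <- truth$injury_effect[hit] > 0
  correct <- (called == "hyper" & wantHyper) | (called == "hypo" & !wantHyper)
  expect_gte(mean(correct), 0.8)
})
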