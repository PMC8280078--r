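test_that("exact-key pairing keeps only tiles DM in both contrasts", {
  inj <- rbind(contrastRow("chr1", 1, 250, 12, 0.01, "hyper", "GeneA"),
               contrastRow("chr1", 251, 500, -8, 0.02, "hypo", "GeneB"),
               contrastRow("chr1", 501, 750, 9, 0.03, "hyper", "GeneC"),
               contrastRow("chr1", 751, 1000, 2, 0.5, "not_significant"))
  trt <- rbind(contrastRow("chr1", 1, 250, -9, 0.01, "hypo", "GeneA"),
               contrastRow("chr1", 251, 500, -7, 0.04, "hypo", "GeneB"),
               contrastRow("chr1", 751, 1000, 8, 0.01, "hyper"))
  pairs <- overlapContrasts(inj, trt)
  expect_equal(nrow(pairs), 2L)                 # GeneC injury-only; 751 trt-only
  expect_equal(attr(pairs, "injuryOnly"), 1L)
  expect_equal(attr(pairs, "treatmentOnly"), 1L)

  empty <- overlapContrasts(inj, trt[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("coordinate-system mismatch is a hard error", {
  inj <- do.call(rbind, lapply(0:9, function(i)
    contrastRow("chr1", i * 250 + 1, i * 250 + 250, 10, 0.01, "hyper")))
  trt <- inj
  trt$start <- trt$start + 125; trt$end <- trt$end + 125  # offset grid
  expect_error(overlapContrasts(inj, trt), "tiling")
})

test_that("reversal classes follow the sign rule and partition the pairs", {
  inj <- rbind(contrastRow("chr1", 1, 250, 12, 0.01, "hyper", "GeneA"),
               contrastRow("chr1", 251, 500, -8, 0.02, "hypo", "GeneB"),
               contrastRow("chr1", 501, 750, -7, 0.02, "hypo", "GeneB"),
               contrastRow("chr1", 751, 1000, 11, 0.01, "hyper", "GeneC"))
  trt <- rbind(contrastRow("chr1", 1, 250, -9, 0.01, "hypo", "GeneA"),
               contrastRow("chr1", 251, 500, 7, 0.03, "hyper", "GeneB"),
               contrastRow("chr1", 501, 750, -7, 0.04, "hypo", "GeneB"),
               contrastRow("chr1", 751, 1000, 9, 0.01, "hyper", "GeneC"))
  rv <- classifyReversal(overlapContrasts(inj, trt))
  expect_equal(rv$records$reversal_class,
               c("reversal_of_hypermethylation", "reversal_of_hypomethylation",
                 "no_reversal", "no_reversal"))
  s <- rv$summary
  expect_equal(Reduce(`+`, s$counts), s$n_pairs)         # partition
  expect_equal(s$reversing_tiles, 2L)
  expect_equal(s$reversing_percent, 50)
  expect_equal(s$genes$no_reversal, 2L)                  # GeneB and GeneC
  expect_equal(s$reversing_genes, 2L)                    # GeneA, GeneB
})

test_that("relabelling hyper<->hypo in both contrasts swaps the reversal classes", {
  set.seed(61)
  n <- 40
  injStat <- sample(c("hyper", "hypo"), n, replace = TRUE)
  trtStat <- sample(c("hyper", "hypo"), n, replace = TRUE)
  mk <- function(stat) ifelse(stat == "hyper", 10, -10)
  inj <- do.call(rbind, lapply(seq_len(n), function(i)
    contrastRow("chr1", i * 250 + 1, i * 250 + 250, mk(injStat[i]), 0.01,
                injStat[i])))
  trt <- do.call(rbind, lapply(seq_len(n), function(i)
    contrastRow("chr1", i * 250 + 1, i * 250 + 250, mk(trtStat[i]), 0.01,
                trtStat[i])))
  a <- classifyReversal(overlapContrasts(inj, trt))$records$reversal_class
  flip <- function(x) ifelse(x == "hyper", "hypo", "hyper")
  injF <- inj; injF$status <- flip(inj$status); injF$meth_diff <- -inj$meth_diff
  trtF <- trt; trtF$status <- flip(trt$status); trtF$meth_diff <- -trt$meth_diff
  b <- classifyReversal(overlapContrasts(injF, trtF))$records$reversal_class
  swap <- c(reversal_of_hypermethylation = "reversal_of_hypomethylation",
            reversal_of_hypomethylation = "reversal_of_hypermethylation",
            no_reversal = "no_reversal")
  expect_equal(b, unname(swap[a]))
})

test_that("overlap matching marks conflicting treatment evidence as unclear", {
  inj <- contrastRow("chr1", 1001, 1250, 12, 0.01, "hyper", "GeneA")
  trt <- rbind(contrastRow("chr1", 876, 1125, -8, 0.02, "hypo"),
               contrastRow("chr1", 1126, 1375, 9, 0.02, "hyper"))
  pairs <- overlapContrasts(inj, trt, mode = "overlap")
  expect_equal(pairs$treatment_status, "conflicting")
  rv <- classifyReversal(pairs)
  expect_equal(rv$records$reversal_class, "unclear")
  # agreeing overlaps classify normally
  trt2 <- rbind(contrastRow("chr1", 876, 1125, -8, 0.02, "hypo"),
                contrastRow("chr1", 1126, 1375, -9, 0.02, "hypo"))
  rv2 <- classifyReversal(overlapContrasts(inj, trt2, mode = "overlap"))
  expect_equal(rv2$records$reversal_class, "reversal_of_hypermethylation")
})

test_that("gene summaries average tiles with a standard error when n >= 2", {
  rec <- data.frame(
    genes = c("GeneA", "GeneA", "GeneB", "GeneB,GeneC"),
    injury_diff = c(10, 20, 5, 8),
    treatment_diff = c(-8, -12, -6, -7))
  gs <- summarizeGenes(rec)
  a <- gs[gs$gene == "GeneA", ]
  expect_equal(a$injury_mean, 15)
  expect_equal(a$injury_se, 5)          # sd(c(10,20))/sqrt(2)
  c_ <- gs[gs$gene == "GeneC", ]
  expect_equal(c_$n_tiles, 1L)
  expect_true(is.na(c_$injury_se))      # single tile: no SE
  b <- gs[gs$gene == "GeneB", ]
  expect_equal(b$n_tiles, 2L)           # shared tile counts for both genes
  expect_equal(b$injury_mean, 6.5)
})
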