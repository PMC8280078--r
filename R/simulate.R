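# Seeded generator of synthetic four-group bisulfite count data.
#
# A toy chromosome carries regularly spaced genes; CpGs are laid down at
# exponential spacing inside each promoter. Methylation effects are
# planted on disjoint 250 bp "effect units" aligned to the tiling grid,
# so the tiling stage is the natural recovery unit: every CpG in a unit
# shares its group-level methylation mean. The two sham groups share the
# baseline; the injury group is shifted on a configurable fraction of
# units; the treated-injury group either moves back past the baseline
# (reversing units) or keeps drifting in the injury direction.

.effectUnitWidth <- 250L

.streamSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629)
}

#' Parameters of the synthetic bisulfite experiment
#'
#' Defaults emulate the four-group injury-by-treatment design (sham and
#' injured animals, each vehicle- or methyl-donor-treated; n = 3, 3, 4,
#' 4) with promoter-localised CpGs, negative-binomial coverage around 30
#' reads, beta-distributed baseline methylation, beta-binomial count
#' noise, a hyper-skewed injury effect and 92.7% of injury-affected
#' units reversing under treatment.
#'
#' @param nGenes number of genes on the toy chromosome.
#' @param chromLength chromosome length in bp (default `5000 * nGenes`).
#' @param cpgSpacingMean mean CpG spacing inside promoters, bp.
#' @param groupSizes named integer vector of four group sizes, in order:
#'   reference, treated-reference, injured, injured-treated. Each must be
#'   at least 2.
#' @param coverageMean,coverageDispersion negative-binomial coverage mean
#'   and size (smaller size = more overdispersed).
#' @param baselineMethAlpha,baselineMethBeta beta shape parameters of the
#'   baseline unit methylation level.
#' @param methOverdispersion beta-binomial intra-tile correlation: each
#'   CpG's own methylation mean is a Beta draw around its unit's group
#'   mean with this correlation parameter, shared across samples, so
#'   counts within a tile are overdispersed relative to a binomial at
#'   the tile mean (0 = all CpGs sit exactly at the unit mean).
#' @param fracInjuryTiles fraction of effect units given an injury effect.
#' @param injuryEffectRange absolute injury effect range in percent; the
#'   lower bound must be at least 5 so planted effects clear the DM
#'   threshold.
#' @param hyperFraction fraction of injury effects that are positive
#'   (hypermethylating).
#' @param reversalFraction fraction of injury-affected units whose
#'   treated-injury mean moves back past the baseline (default 0.927).
#' @param seed integer seed; identical seed and parameters give
#'   byte-identical outputs.
#' @return A named list of class `simParams`.
#' @export
simParams <- function(nGenes = 60L, chromLength = NULL, cpgSpacingMean = 50,
                      groupSizes = c("Sham-Vehicle" = 3L, "Sham-SAM" = 3L,
                                     "SNI-Vehicle" = 4L, "SNI-SAM" = 4L),
                      coverageMean = 30, coverageDispersion = 5,
                      baselineMethAlpha = 2, baselineMethBeta = 5,
                      methOverdispersion = 0.05,
                      fracInjuryTiles = 0.2, injuryEffectRange = c(15, 30),
                      hyperFraction = 0.6, reversalFraction = 0.927,
                      seed = 1L) {
  .assertPositive(nGenes, "nGenes")
  if (is.null(chromLength)) chromLength <- 5000 * nGenes
  .assertPositive(cpgSpacingMean, "cpgSpacingMean")
  if (length(groupSizes) != 4L || is.null(names(groupSizes)))
    .stopf("'groupSizes' must be a named vector of 4 group sizes")
  if (any(groupSizes < 2L))
    .stopf("every group needs at least 2 samples")
  .assertPositive(coverageMean, "coverageMean")
  .assertPositive(coverageDispersion, "coverageDispersion")
  .assertProportion(methOverdispersion, "methOverdispersion")
  .assertProportion(fracInjuryTiles, "fracInjuryTiles")
  .assertProportion(hyperFraction, "hyperFraction")
  .assertProportion(reversalFraction, "reversalFraction")
  if (length(injuryEffectRange) != 2L ||
      injuryEffectRange[1] > injuryEffectRange[2])
    .stopf("'injuryEffectRange' must be c(low, high) with low <= high")
  if (injuryEffectRange[1] < 5)
    .stopf("injuryEffectRange low must be >= 5 (plantable above the DM threshold)")
  structure(list(nGenes = as.integer(nGenes),
                 chromLength = as.integer(chromLength),
                 cpgSpacingMean = cpgSpacingMean,
                 groupSizes = groupSizes,
                 coverageMean = coverageMean,
                 coverageDispersion = coverageDispersion,
                 baselineMethAlpha = baselineMethAlpha,
                 baselineMethBeta = baselineMethBeta,
                 methOverdispersion = methOverdispersion,
                 fracInjuryTiles = fracInjuryTiles,
                 injuryEffectRange = injuryEffectRange,
                 hyperFraction = hyperFraction,
                 reversalFraction = reversalFraction,
                 seed = as.integer(seed)),
            class = "simParams")
}

#' @export
print.simParams <- function(x, ...) {
  cat(sprintf("simParams: %d genes on a %d bp chromosome (seed %d)\n",
              x$nGenes, x$chromLength, x$seed))
  cat("groups:", paste(sprintf("%s=%d", names(x$groupSizes), x$groupSizes),
                       collapse = ", "), "\n")
  cat(sprintf("coverage NB(mu=%g, size=%g); baseline Beta(%g, %g); rho=%g\n",
              x$coverageMean, x$coverageDispersion, x$baselineMethAlpha,
              x$baselineMethBeta, x$methOverdispersion))
  cat(sprintf("injury on %g%% of units, |effect| in [%g, %g]%%, %g%% hyper; reversal %g%%\n",
              100 * x$fracInjuryTiles, x$injuryEffectRange[1],
              x$injuryEffectRange[2], 100 * x$hyperFraction,
              100 * x$reversalFraction))
  invisible(x)
}

#' Simulate the toy genome: genes, TSSs and promoter CpGs
#'
#' Genes are placed on equal-width slots of one chromosome with random
#' strand; CpGs are laid down inside each promoter (TSS -2000/+200,
#' strand-aware) at exponential spacing.
#'
#' @param params a [simParams] list.
#' @return A list with `genes` (named stranded `GRanges`) and `cpgs`
#'   (`GRanges` with `gene` and effect-`unit` metadata columns).
#' @export
simulateGenome <- function(params = simParams()) {
  stopifnot(inherits(params, "simParams"))
  slot <- params$chromLength %/% params$nGenes
  if (slot < 4400L)
    .stopf("chromLength %d too small for %d non-overlapping promoters; need at least %d bp",
           params$chromLength, params$nGenes, params$nGenes * 4400L)
  set.seed(.streamSeed(params$seed, 0L))
  n <- params$nGenes
  tss <- (seq_len(n) - 1L) * slot + slot %/% 2L
  str <- sample(c("+", "-"), n, replace = TRUE)
  genes <- GRanges("chrS",
                   IRanges(ifelse(str == "+", tss, tss - 1000L),
                           ifelse(str == "+", tss + 1000L, tss)),
                   strand = str)
  names(genes) <- sprintf("Gene%04d", seq_len(n))
  genes$name <- names(genes)
  cpgPos <- vector("list", n)
  for (i in seq_len(n)) {
    winStart <- if (str[i] == "+") tss[i] - 2000L else tss[i] - 200L
    winEnd <- if (str[i] == "+") tss[i] + 200L else tss[i] + 2000L
    gaps <- pmax(2, round(rexp(ceiling(2200 / params$cpgSpacingMean * 4) + 10,
                               rate = 1 / params$cpgSpacingMean)))
    pos <- winStart + cumsum(gaps)
    cpgPos[[i]] <- pos[pos <= winEnd]
  }
  nPer <- lengths(cpgPos)
  pos <- unlist(cpgPos)
  cpgs <- GRanges("chrS", IRanges(pos, width = 1L))
  cpgs$gene <- rep(names(genes), nPer)
  cpgs$unit <- (pos - 1L) %/% .effectUnitWidth
  list(genes = genes, cpgs = cpgs)
}

# draw a baseline mean from the (possibly truncated) baseline beta so the
# planted shifts stay inside (0.01, 0.99); empty feasible interval falls
# back to an untruncated draw, later clamped and recorded
.truncBeta <- function(u, a, b, lo, hi) {
  qbeta(pbeta(lo, a, b) + u * (pbeta(hi, a, b) - pbeta(lo, a, b)), a, b)
}

#' Simulate four-group bisulfite counts with planted effects
#'
#' Per CpG and sample, coverage is negative binomial (with a per-sample
#' log-normal depth multiplier, sigma = 0.2, so coverage normalisation
#' has real work to do) and the methylated count is binomial at the
#' CpG's group-specific mean — the unit's group mean plus a CpG-level
#' Beta deviation shared across samples, making tile counts
#' beta-binomially overdispersed. Group means pushed outside
#' (0.01, 0.99) are clamped there and the clamping recorded in the
#' ground truth.
#'
#' @param params a [simParams] list.
#' @param genome output of [simulateGenome()].
#' @return A list with `counts` (a CpG-level [MethylCounts-class]) and
#'   `truth` (a data frame with one row per effect unit: coordinates,
#'   gene, achieved injury and treatment effects in percent, `label`
#'   among `reversal`/`no_reversal`/`null`, and a `clamped` flag).
#' @export
simulateCounts <- function(params = simParams(), genome = simulateGenome(params)) {
  stopifnot(inherits(params, "simParams"))
  cpgs <- genome$cpgs
  units <- sort(unique(cpgs$unit))
  nU <- length(units)
  uIdx <- match(cpgs$unit, units)
  uGene <- cpgs$gene[match(units, cpgs$unit)]

  ## ground truth: unit-level group means
  set.seed(.streamSeed(params$seed, 1L))
  a <- params$baselineMethAlpha; b <- params$baselineMethBeta
  uBase <- runif(nU)
  injury <- runif(nU) < params$fracInjuryTiles
  sgn <- ifelse(runif(nU) < params$hyperFraction, 1, -1)
  mag <- runif(nU, params$injuryEffectRange[1],
               params$injuryEffectRange[2]) / 100
  reversal <- injury & (runif(nU) < params$reversalFraction)
  extra <- runif(nU, params$injuryEffectRange[1],
                 params$injuryEffectRange[2]) / 100
  overshoot <- 0.3

  eff <- ifelse(injury, sgn * mag, 0)
  # feasible baseline interval keeping all planted means inside (0.01, 0.99)
  lo <- pmax(0.01, ifelse(eff > 0, 0.01 + overshoot * eff, 0.01 - eff + extra))
  hi <- pmin(0.99, ifelse(eff > 0, 0.99 - eff - extra, 0.99 + overshoot * eff))
  feasible <- lo < hi
  mu <- ifelse(feasible, .truncBeta(uBase, a, b, lo, hi), qbeta(uBase, a, b))

  mSham <- mu
  mInj <- mu + eff
  mTrt <- ifelse(reversal, mu - overshoot * eff,
                 ifelse(injury, mInj + sign(eff) * extra, mu))
  clamp <- function(x) pmin(pmax(x, 0.01), 0.99)
  clamped <- mSham != clamp(mSham) | mInj != clamp(mInj) | mTrt != clamp(mTrt)
  mSham <- clamp(mSham); mInj <- clamp(mInj); mTrt <- clamp(mTrt)

  # intra-tile heterogeneity: each CpG's own mean deviates from its unit
  # mean via a Beta draw with correlation rho; the deviation is a property
  # of the CpG (one draw, shared by every sample), so marginal methylated
  # counts are beta-binomial while group contrasts stay calibrated
  rho <- params$methOverdispersion
  nC <- length(cpgs)
  cpgDelta <- if (rho > 0) {
    mu0 <- pmin(pmax(mSham[uIdx], 0.02), 0.98)
    rbeta(nC, mu0 * (1 - rho) / rho, (1 - mu0) * (1 - rho) / rho) - mu0
  } else rep(0, nC)

  truth <- data.frame(
    chrom = "chrS",
    start = units * .effectUnitWidth + 1L,
    end = (units + 1L) * .effectUnitWidth,
    gene = uGene,
    injury_effect = 100 * (mInj - mSham),
    treatment_effect = 100 * (mTrt - mInj),
    clamped = clamped)
  # labels reflect the achieved (post-clamp) effects so they stay
  # consistent even when clamping shrank a planted shift
  truth$label <- with(truth, ifelse(
    injury_effect == 0, "null",
    ifelse(sign(treatment_effect) == -sign(injury_effect) &
             treatment_effect != 0, "reversal", "no_reversal")))

  ## per-sample counts
  gs <- params$groupSizes
  groups <- rep(names(gs), gs)
  sampleIds <- unlist(lapply(seq_along(gs), function(g)
    paste0(names(gs)[g], "_", seq_len(gs[g]))))
  # per-CpG methylation mean for each of the four groups (in order):
  # unit-level group mean plus the CpG's own deviation, kept inside (0,1)
  gmByUnit <- cbind(mSham, mSham, mInj, mTrt)
  pByGroup <- pmin(pmax(gmByUnit[uIdx, , drop = FALSE] + cpgDelta, 0.01),
                   0.99)
  meth <- matrix(0L, nC, length(sampleIds))
  total <- matrix(0L, nC, length(sampleIds))
  for (s in seq_along(sampleIds)) {
    set.seed(.streamSeed(params$seed, 1L + s))
    mult <- rlnorm(1L, meanlog = 0, sdlog = 0.2)
    cov <- rnbinom(nC, mu = params$coverageMean * mult,
                   size = params$coverageDispersion)
    gCol <- match(groups[s], names(gs))
    meth[, s] <- rbinom(nC, cov, pByGroup[, gCol])
    total[, s] <- cov
  }
  counts <- MethylCounts(meth, total, GRanges(seqnames(cpgs), IRanges::ranges(cpgs)),
                         group = groups, sampleIds = sampleIds)
  rowData(counts)$gene <- cpgs$gene
  metadata(counts)$simParams <- params
  list(counts = counts, truth = truth)
}

#' Simulate a full experiment, optionally writing it to disk
#'
#' Convenience wrapper: [simulateGenome()] + [simulateCounts()]. When
#' `dir` is given, writes one Bismark coverage file per sample, the gene
#' table as BED6, the ground truth as TSV, and a `samples.tsv` sheet
#' (file, sample, group) ready for [runPipeline()].
#'
#' @param params a [simParams] list.
#' @param dir optional output directory.
#' @return A list with `genome`, `counts`, `truth` and (if written)
#'   `files`.
#' @export
simulateExperiment <- function(params = simParams(), dir = NULL) {
  genome <- simulateGenome(params)
  sim <- simulateCounts(params, genome)
  out <- list(genome = genome, counts = sim$counts, truth = sim$truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    covs <- writeBismarkCoverage(sim$counts, dir)
    genesBed <- file.path(dir, "genes.bed")
    g <- genome$genes
    bed <- data.frame(as.character(seqnames(g)), start(g) - 1L, end(g),
                      names(g), 0L, as.character(strand(g)))
    write.table(bed, genesBed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    truthTsv <- file.path(dir, "ground_truth.tsv")
    writeResultsTsv(sim$truth, truthTsv)
    sheet <- file.path(dir, "samples.tsv")
    writeResultsTsv(data.frame(file = basename(covs),
                               sample = colnames(sim$counts),
                               group = sampleGroups(sim$counts)), sheet)
    out$files <- list(coverage = covs, genes = genesBed, truth = truthTsv,
                      samples = sheet)
  }
  out
}
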