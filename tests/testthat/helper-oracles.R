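# Independent oracles and small in-code fixtures shared across tests.

# Benjamini-Hochberg step-up, written directly from the definition
# (independent of slimAdjust's cummin implementation):
# q_i = min over j with p_j >= p_i of m * p_j / rank_j, capped at 1.
directBH <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- m * p[o] / seq_len(m)
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(r[i:m]))
  q[order(o)]
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# choose(N, n) draws (feasible for N <= 12): population of N genes, K of
# them in the set, draw n, probability of >= k overlaps.
enumHypergeom <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  inSet <- seq_len(K)
  hits <- apply(draws, 2L, function(d) sum(d %in% inSet))
  mean(hits >= k)
}

# Likelihood-ratio chi-square (G-statistic) of a pooled 2x2 table
# (methylated/unmethylated x control/experimental), computed from the
# textbook observed/expected formula.
g2Pvalue <- function(mCtl, tCtl, mExp, tExp) {
  obs <- c(mCtl, tCtl - mCtl, mExp, tExp - mExp)
  rowTot <- c(tCtl, tExp)
  colTot <- c(mCtl + mExp, tCtl - mCtl + tExp - mExp)
  expd <- c(rowTot[1] * colTot / sum(rowTot), rowTot[2] * colTot / sum(rowTot))
  g2 <- 2 * sum(ifelse(obs > 0, obs * log(obs / expd), 0))
  stats::pchisq(g2, df = 1, lower.tail = FALSE)
}

# Pearson chi-square on the same table, no continuity correction.
pearsonPvalue <- function(mCtl, tCtl, mExp, tExp) {
  suppressWarnings(stats::prop.test(c(mCtl, mExp), c(tCtl, tExp),
                                    correct = FALSE))$p.value
}

# Small CpG-level MethylCounts built in code: `cov` and `meth` are
# site-by-sample matrices, positions 1-based.
makeCounts <- function(meth, cov, pos, chrom = "chr1",
                       group = rep(c("ctl", "exp"),
                                   length.out = ncol(as.matrix(cov)))) {
  cov <- as.matrix(cov); meth <- as.matrix(meth)
  MethylCounts(meth, cov,
               GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1)),
               group = group)
}

# Tile-level MethylCounts with explicit ranges (for promoter tests).
makeTiles <- function(starts, ends, chrom = "chr1", nSamples = 2) {
  n <- length(starts)
  mc <- MethylCounts(matrix(5L, n, nSamples), matrix(10L, n, nSamples),
                     GenomicRanges::GRanges(chrom,
                                            IRanges::IRanges(starts, ends)),
                     group = rep("g", nSamples))
  SummarizedExperiment::rowData(mc)$n_cpgs <- rep(1L, n)
  mc
}

# One stranded gene whose TSS sits at `tss` (1-based).
makeGene <- function(tss, strand = "+", name = "GeneX", chrom = "chr1") {
  g <- GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(if (strand == "+") tss else tss - 1000L,
                     if (strand == "+") tss + 1000L else tss),
    strand = strand)
  names(g) <- name
  g$name <- name
  g
}

# Contrast-table row constructor for reversal tests.
contrastRow <- function(chrom, start, end, diff, q, status, gene = "") {
  data.frame(chrom = chrom, start = start, end = end, genes = gene,
             meth_diff = diff, q_value = q, status = status)
}
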