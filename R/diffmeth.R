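# Per-tile differential methylation: binomial logistic regression with a
# single two-level group factor, tested by likelihood ratio against
# chi-squared(1).
#
# The MLE of that model is the pooled methylation proportion within each
# group (the per-sample binomial log-likelihood depends on the data only
# through the pooled counts), so the fit and the LRT statistic are
# computed in closed form and vectorised over tiles. stats::glm on the
# per-sample observations gives identical results and serves as a
# cross-check in the test suite.

.xlogy <- function(x, y) ifelse(x > 0, x * log(y), 0)

.binomLL <- function(m, t, p) .xlogy(m, p) + .xlogy(t - m, 1 - p)

# proportions clamped away from 0/1 by half a read for a finite log-odds
# on separated tiles
.safeProp <- function(m, t) pmin(pmax(m / t, 0.5 / t), 1 - 0.5 / t)

.dmTestPooled <- function(mCtl, tCtl, mExp, tExp) {
  if (any(tCtl == 0) || any(tExp == 0))
    .stopf("a group has zero total coverage in %d tile(s)",
           sum(tCtl == 0 | tExp == 0))
  pCtl <- mCtl / tCtl
  pExp <- mExp / tExp
  pAll <- (mCtl + mExp) / (tCtl + tExp)
  stat <- 2 * (.binomLL(mCtl, tCtl, pCtl) + .binomLL(mExp, tExp, pExp) -
                 .binomLL(mCtl + mExp, tCtl + tExp, pAll))
  stat <- pmax(stat, 0)                     # guard tiny negative round-off
  pval <- pchisq(stat, df = 1L, lower.tail = FALSE)
  sCtl <- .safeProp(mCtl, tCtl)
  sExp <- .safeProp(mExp, tExp)
  lor <- log(sExp / (1 - sExp)) - log(sCtl / (1 - sCtl))
  degenerate <- (pCtl == pExp) & (pCtl == 0 | pCtl == 1)
  lor[degenerate] <- 0
  pval[degenerate] <- 1
  list(methDiff = 100 * (pExp - pCtl), logOddsRatio = lor,
       pValue = pval, statistic = stat)
}

#' Logistic-regression differential-methylation test for one tile
#'
#' Fits the binomial logistic model `logit(pi_i) = b0 + b1 * group_i`
#' over the per-sample (methylated, total) observations of a tile and
#' tests `b1 = 0` by likelihood ratio against chi-squared(1). The
#' reported methylation difference is the pooled experimental proportion
#' minus the pooled control proportion, in percent (control is the
#' reference point); the log odds ratio is the fitted `b1`.
#'
#' @param methCtl,totalCtl per-sample methylated and total counts in the
#'   control group.
#' @param methExp,totalExp per-sample counts in the experimental group.
#' @return A list with `methDiff` (percent), `logOddsRatio`, `pValue`,
#'   and the LRT `statistic`.
#' @examples
#' logisticDMTest(c(30, 28), c(50, 50), c(40, 41), c(50, 50))
#' @export
logisticDMTest <- function(methCtl, totalCtl, methExp, totalExp) {
  stopifnot(length(methCtl) == length(totalCtl),
            length(methExp) == length(totalExp))
  if (any(methCtl > totalCtl) || any(methExp > totalExp))
    .stopf("methylated count exceeds total")
  if (sum(totalCtl) == 0 || sum(totalExp) == 0)
    .stopf("a group has zero total coverage")
  r <- .dmTestPooled(sum(methCtl), sum(totalCtl), sum(methExp), sum(totalExp))
  lapply(r, as.numeric)
}

#' Per-tile differential methylation between two groups
#'
#' Runs the logistic-regression likelihood-ratio test (see
#' [logisticDMTest()]) on every tile, adjusts p-values (SLIM pi0-scaled
#' FDR or Benjamini-Hochberg, per `params$adjust`), and calls each tile
#' hypermethylated, hypomethylated or not significant.
#'
#' @param tiles a tile-level [MethylCounts-class] (typically from
#'   [restrictToPromoters()]).
#' @param control,experimental group labels; the control group is the
#'   reference point, so positive differences mean higher methylation in
#'   the experimental group.
#' @param params a [dmParams] list.
#' @return A data frame (one row per tile) with tile coordinates, gene
#'   symbols, `meth_diff` (percent), `log_odds_ratio`, `p_value`,
#'   `q_value`, `status` (`hyper`/`hypo`/`not_significant`) and `robust`.
#'   Attributes record the contrast, adjustment method and estimated pi0.
#' @export
calculateDiffMeth <- function(tiles, control, experimental,
                              params = dmParams()) {
  stopifnot(is(tiles, "MethylCounts"), inherits(params, "dmParams"))
  ctl <- .groupSamples(tiles, control)
  exp <- .groupSamples(tiles, experimental)
  meth <- methCounts(tiles); total <- totalCounts(tiles)
  r <- .dmTestPooled(rowSums(meth[, ctl, drop = FALSE]),
                     rowSums(total[, ctl, drop = FALSE]),
                     rowSums(meth[, exp, drop = FALSE]),
                     rowSums(total[, exp, drop = FALSE]))
  q <- slimAdjust(r$pValue, method = params$adjust)
  genes <- rowData(tiles)$genes
  out <- data.frame(
    chrom = as.character(seqnames(tiles)),
    start = start(tiles), end = end(tiles),
    genes = if (is.null(genes)) "" else vapply(genes, paste, "",
                                               collapse = ","),
    n_cpgs = if (is.null(rowData(tiles)$n_cpgs)) NA_integer_ else
      rowData(tiles)$n_cpgs,
    meth_diff = r$methDiff,
    log_odds_ratio = r$logOddsRatio,
    p_value = r$pValue,
    q_value = as.numeric(q))
  rownames(out) <- NULL
  out <- callStatus(out, params)
  attr(out, "contrast") <- c(control = control, experimental = experimental)
  attr(out, "adjust") <- params$adjust
  attr(out, "pi0") <- attr(q, "pi0")
  out
}

#' Call hyper/hypo status from effect size and adjusted p-value
#'
#' A tile is hypermethylated when `q_value < qThreshold` and
#' `meth_diff > diffThreshold`, hypomethylated when
#' `q_value < qThreshold` and `meth_diff < -diffThreshold`, otherwise
#' not significant — all inequalities strict. The robust flag marks
#' `q_value < robustThreshold`.
#'
#' @param results data frame with `meth_diff` and `q_value` columns.
#' @param params a [dmParams] list.
#' @return `results` with `status` and `robust` columns (re)computed.
#' @export
callStatus <- function(results, params = dmParams()) {
  stopifnot(inherits(params, "dmParams"),
            all(c("meth_diff", "q_value") %in% names(results)))
  sig <- results$q_value < params$qThreshold
  results$status <- ifelse(
    sig & results$meth_diff > params$diffThreshold, "hyper",
    ifelse(sig & results$meth_diff < -params$diffThreshold, "hypo",
           "not_significant"))
  results$robust <- results$q_value < params$robustThreshold
  results
}
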