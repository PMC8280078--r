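#' Tiling and filtering parameters
#'
#' Defaults follow the standard promoter-tiling workflow for bisulfite
#' capture data: 250 bp windows advancing in 125 bp steps, a minimum depth
#' of 10 reads in every sample, and promoters defined as 2000 bp upstream
#' to 200 bp downstream of the TSS (strand-aware).
#'
#' @param tileSize window width in bp.
#' @param stepSize window step in bp; must not exceed `tileSize`.
#' @param minDepth minimum per-sample read depth for a CpG to be analysed.
#' @param minCpgs minimum number of covered CpGs for a window to become a
#'   tile.
#' @param promoterUpstream,promoterDownstream promoter extent around the
#'   TSS, in bp.
#' @return A named list of class `tilingParams`.
#' @examples
#' tilingParams(tileSize = 500, stepSize = 250)
#' @export
tilingParams <- function(tileSize = 250L, stepSize = 125L, minDepth = 10L,
                         minCpgs = 1L, promoterUpstream = 2000L,
                         promoterDownstream = 200L) {
  .assertPositive(tileSize, "tileSize")
  .assertPositive(stepSize, "stepSize")
  .assertPositive(minDepth, "minDepth", strict = FALSE)
  .assertPositive(minCpgs, "minCpgs")
  .assertPositive(promoterUpstream, "promoterUpstream", strict = FALSE)
  .assertPositive(promoterDownstream, "promoterDownstream", strict = FALSE)
  if (stepSize > tileSize)
    .stopf("stepSize (%d) must not exceed tileSize (%d)", stepSize, tileSize)
  structure(list(tileSize = as.integer(tileSize),
                 stepSize = as.integer(stepSize),
                 minDepth = as.integer(minDepth),
                 minCpgs = as.integer(minCpgs),
                 promoterUpstream = as.integer(promoterUpstream),
                 promoterDownstream = as.integer(promoterDownstream)),
            class = "tilingParams")
}

#' Differential-methylation calling parameters
#'
#' A tile is called differentially methylated when its adjusted p-value is
#' below `qThreshold` *and* the absolute pooled methylation difference
#' exceeds `diffThreshold` percent (both strict inequalities); tiles
#' passing the much smaller `robustThreshold` are additionally flagged as
#' robust.
#'
#' @param qThreshold adjusted-p cutoff for calling (default 0.1).
#' @param diffThreshold methylation-difference cutoff in percent
#'   (default 5).
#' @param robustThreshold adjusted-p cutoff for the robust flag
#'   (default 1e-7).
#' @param adjust multiple-testing adjustment: `"SLIM"` (sliding-linear-model
#'   pi0-scaled FDR) or `"BH"`.
#' @return A named list of class `dmParams`.
#' @export
dmParams <- function(qThreshold = 0.1, diffThreshold = 5,
                     robustThreshold = 1e-7, adjust = c("SLIM", "BH")) {
  adjust <- match.arg(adjust)
  .assertProportion(qThreshold, "qThreshold")
  .assertPositive(diffThreshold, "diffThreshold", strict = FALSE)
  .assertPositive(robustThreshold, "robustThreshold")
  if (!(robustThreshold < qThreshold))
    .stopf("robustThreshold must be smaller than qThreshold")
  structure(list(qThreshold = qThreshold, diffThreshold = diffThreshold,
                 robustThreshold = robustThreshold, adjust = adjust),
            class = "dmParams")
}

#' @export
print.tilingParams <- function(x, ...) {
  cat(sprintf(
    "tiling: %d bp windows / %d bp step; depth >= %d in every sample; >= %d CpG(s)/tile\npromoter: TSS -%d / +%d bp\n",
    x$tileSize, x$stepSize, x$minDepth, x$minCpgs,
    x$promoterUpstream, x$promoterDownstream))
  invisible(x)
}

#' @export
print.dmParams <- function(x, ...) {
  cat(sprintf(
    "DM call: q < %g and |diff| > %g%%; robust: q < %g; adjustment: %s\n",
    x$qThreshold, x$diffThreshold, x$robustThreshold, x$adjust))
  invisible(x)
}
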