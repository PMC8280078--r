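#' @import methods
#' @importFrom stats median pchisq p.adjust rbeta rbinom rnbinom rlnorm
#'   rexp runif dhyper phyper qbeta pbeta coef glm binomial sd setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Methylated-count accessor
#'
#' @param x a [MethylCounts] object.
#' @return Integer matrix of methylated read counts (sites/tiles x samples).
#' @export
setGeneric("methCounts", function(x) standardGeneric("methCounts"))

#' Total-coverage accessor
#'
#' @param x a [MethylCounts] object.
#' @return Integer matrix of total read counts (sites/tiles x samples).
#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))

#' Per-sample group labels
#'
#' @param x a [MethylCounts] object.
#' @return Character vector of group labels, one per sample.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname sampleGroups
#' @param value character vector of group labels, one per sample.
#' @export
setGeneric("sampleGroups<-",
           function(x, value) standardGeneric("sampleGroups<-"))

#' Methylation proportion matrix
#'
#' @param x a [MethylCounts] object.
#' @return Numeric matrix of per-sample methylation proportions
#'   (`NaN` where coverage is zero).
#' @export
setGeneric("methLevels", function(x) standardGeneric("methLevels"))

#' Per-sample depth filter
#'
#' Keeps only rows (CpG sites or tiles) whose total coverage reaches
#' `minDepth` in every sample.
#'
#' @param x a [MethylCounts] object.
#' @param minDepth minimum read depth required in each sample (default 10).
#' @return A filtered [MethylCounts].
#' @export
setGeneric("filterByDepth",
           function(x, minDepth = 10L) standardGeneric("filterByDepth"))

#' Blacklist filter
#'
#' Removes rows overlapping a set of excluded regions (e.g. an ENCODE-style
#' blacklist of anomalous-signal regions).
#'
#' @param x a [MethylCounts] object.
#' @param blacklist a `GRanges` of regions to exclude.
#' @return A filtered [MethylCounts].
#' @export
setGeneric("filterBlacklist",
           function(x, blacklist) standardGeneric("filterBlacklist"))

#' Median-based coverage normalisation
#'
#' @param x a [MethylCounts] object.
#' @return A [MethylCounts] with rescaled counts; scale factors in
#'   `metadata(x)$scaleFactors`.
#' @export
setGeneric("normalizeCoverage",
           function(x) standardGeneric("normalizeCoverage"))

#' Sliding-window tiling of CpG counts
#'
#' @param x a [MethylCounts] of CpG sites.
#' @param params a [tilingParams] list.
#' @return A [MethylCounts] of tiles with `n_cpgs` in `rowData`.
#' @export
setGeneric("tileCounts",
           function(x, params = tilingParams()) standardGeneric("tileCounts"))
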